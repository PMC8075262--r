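# Synthetic tuning-curve cohorts and bifurcation fixtures.
#
# The cohort generator emulates the structure of pooled auditory-nerve
# rate-intensity recordings: many fibers across animals, each measured on a
# fixed dB-level grid, sigmoidal mean rates with heterogeneous spontaneous
# rates, dynamic ranges and thresholds, negative correlation between
# normalized spontaneous rate and dynamic range, positive correlation
# between dynamic range and threshold, and homoscedastic Gaussian
# measurement noise on the rates (clipped at zero). Ground-truth parameters
# are returned so fitting and classification can be scored. All generators
# are pure functions of (spec, seed).

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Cohort specification
#'
#' Parameters of the synthetic tuning-curve cohort. The defaults mirror the
#' two fiber types recovered from real auditory-nerve populations: a
#' high-spontaneous-rate type with a narrow dynamic range and low threshold,
#' and a low-spontaneous-rate type with a broad dynamic range and high
#' threshold, with the empirically observed cross-parameter correlation
#' signs.
#'
#' @param n_fibers total number of fibers.
#' @param n_animals number of animals the fibers are spread over.
#' @param type_means data frame with one row per type and columns `rho`
#'   (normalized spontaneous rate), `sigma` (dynamic range, standardized
#'   units), `theta` (threshold, standardized units), `r_m` (maximal rate,
#'   Hz).
#' @param type_sds within-type standard deviations for the same columns.
#' @param correlations correlation matrix (3 x 3, order `rho`, `sigma`,
#'   `theta`) of the within-type parameter variation; must be positive
#'   semi-definite. Default: corr(rho, sigma) = -0.5,
#'   corr(sigma, theta) = +0.5, corr(rho, theta) = -0.25.
#' @param levels_db dB SPL measurement grid.
#' @param rate_noise_sd Gaussian rate noise (Hz; default 5).
#' @param noise_model `"gaussian"` (default) or `"poisson"` (counts over a
#'   50 ms window).
#' @param seed integer seed making the cohort reproducible.
#' @return a list of class `pc_cohort_spec`.
#' @export
cohort_spec <- function(n_fibers = 60, n_animals = 12,
                        type_means = data.frame(
                          rho = c(0.159, 0.036),
                          sigma = c(0.337, 0.534),
                          theta = c(-0.35, 0.55),
                          r_m = c(276, 276)),
                        type_sds = data.frame(
                          rho = c(0.05, 0.02),
                          sigma = c(0.08, 0.10),
                          theta = c(0.30, 0.30),
                          r_m = c(40, 40)),
                        correlations = rbind(c(1, -0.5, -0.25),
                                             c(-0.5, 1, 0.5),
                                             c(-0.25, 0.5, 1)),
                        levels_db = seq(0, 80, by = 5),
                        rate_noise_sd = 5,
                        noise_model = c("gaussian", "poisson"),
                        seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(nrow(type_means) == nrow(type_sds),
            all(c("rho", "sigma", "theta", "r_m") %in% names(type_means)))
  if (any(unlist(type_sds) < 0)) stop("all SDs must be non-negative")
  if (rate_noise_sd < 0) stop("`rate_noise_sd` must be non-negative")
  ev <- eigen(correlations, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) stop("correlation matrix is not positive semi-definite")
  structure(list(n_fibers = n_fibers, n_animals = n_animals,
                 type_means = type_means, type_sds = type_sds,
                 correlations = correlations, levels_db = levels_db,
                 rate_noise_sd = rate_noise_sd, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "pc_cohort_spec")
}

#' Generate a synthetic tuning-curve cohort
#'
#' Samples per-fiber parameters from a truncated multivariate normal within
#' each type (honouring the sign constraints `0 <= rho < 1`, `sigma > 0`,
#' `r_m > 0`), then samples measured rates at every level of the dB grid as
#' sigmoid mean plus noise, clipped at zero.
#'
#' @param spec a [cohort_spec()].
#' @param transform a [level_transform()] (the inverse is used to place the
#'   standardized parameters on the dB axis).
#' @return a list: `curves` (data frame `fiber_id`, `animal_id`,
#'   `level_db`, `rate_hz`) and `truth` (data frame of ground-truth
#'   per-fiber parameters plus the generating `type`).
#' @export
generate_cohort <- function(spec, transform = level_transform()) {
  stopifnot(inherits(spec, "pc_cohort_spec"))
  n_types <- nrow(spec$type_means)
  with_seed(spec$seed, {
    type <- rep(seq_len(n_types), length.out = spec$n_fibers)
    animal <- sample(rep(seq_len(spec$n_animals),
                         length.out = spec$n_fibers))
    pars <- matrix(NA_real_, spec$n_fibers, 3L,
                   dimnames = list(NULL, c("rho", "sigma", "theta")))
    for (t in seq_len(n_types)) {
      idx <- which(type == t)
      mu <- unlist(spec$type_means[t, c("rho", "sigma", "theta")])
      sd_ <- unlist(spec$type_sds[t, c("rho", "sigma", "theta")])
      Sig <- diag(sd_) %*% spec$correlations %*% diag(sd_)
      got <- 0L
      draws <- matrix(NA_real_, length(idx), 3L)
      while (got < length(idx)) {
        m <- MASS::mvrnorm(2L * (length(idx) - got) + 8L, mu, Sig)
        ok <- m[, 1] >= 0 & m[, 1] < 0.95 & m[, 2] > 0.02
        m <- m[ok, , drop = FALSE]
        take <- min(nrow(m), length(idx) - got)
        if (take > 0) {
          draws[got + seq_len(take), ] <- m[seq_len(take), , drop = FALSE]
          got <- got + take
        }
      }
      pars[idx, ] <- draws
    }
    r_m <- pmax(rnorm(spec$n_fibers,
                      spec$type_means$r_m[type],
                      spec$type_sds$r_m[type]), 50)
    truth <- data.frame(fiber_id = sprintf("f%03d", seq_len(spec$n_fibers)),
                        animal_id = sprintf("a%02d", animal),
                        type = type,
                        r = pars[, "rho"] * r_m, r_m = r_m,
                        rho = pars[, "rho"],
                        theta = pars[, "theta"], sigma = pars[, "sigma"])
    s <- standardize_level(spec$levels_db, transform)
    curves <- do.call(rbind, lapply(seq_len(spec$n_fibers), function(i) {
      H <- pnorm((s - truth$theta[i]) / truth$sigma[i])
      mu_rate <- truth$r[i] + (truth$r_m[i] - truth$r[i]) * H
      rate <- if (spec$noise_model == "gaussian") {
        pmax(mu_rate + rnorm(length(s), 0, spec$rate_noise_sd), 0)
      } else {
        rpois(length(s), mu_rate * 0.05) / 0.05
      }
      data.frame(fiber_id = truth$fiber_id[i],
                 animal_id = truth$animal_id[i],
                 level_db = spec$levels_db, rate_hz = rate)
    }))
    list(curves = curves, truth = truth)
  })
}

#' Write a cohort to a TSV file
#'
#' Plain-text serialization in the schema [fit_cohort()] reads.
#'
#' @param curves the `curves` data frame of [generate_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(curves, path) {
  utils::write.table(curves, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Synthetic bifurcation series
#'
#' Ground-truth order-parameter series for exercising the criticality
#' tools: a supercritical pitchfork `dtheta = max(x - x_c, 0)^exponent`
#' (continuous; optional Gaussian noise on the nonzero part) or a `jump`
#' series with a step discontinuity at `x_c`.
#'
#' @param kind `"pitchfork"` or `"jump"`.
#' @param x_c critical value.
#' @param exponent pitchfork exponent (> 0, default 0.5).
#' @param noise_sd Gaussian noise SD on the order parameter (default 0).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param x evaluation grid (default 201 points on `[x_c - 1, x_c + 1]`).
#' @return data frame with columns `x` and `dtheta`.
#' @export
generate_bifurcation_fixture <- function(kind = c("pitchfork", "jump"),
                                         x_c = 1, exponent = 0.5,
                                         noise_sd = 0, seed = 1L,
                                         x = NULL) {
  kind <- match.arg(kind)
  if (exponent <= 0) stop("`exponent` must be positive")
  if (is.null(x)) x <- seq(x_c - 1, x_c + 1, length.out = 201L)
  dtheta <- if (kind == "pitchfork") {
    pmax(x - x_c, 0)^exponent
  } else {
    ifelse(x > x_c, 0.6 + 0.1 * (x - x_c), 0)
  }
  if (noise_sd > 0) {
    dtheta <- with_seed(seed, {
      pos <- dtheta > 0
      dtheta[pos] <- pmax(dtheta[pos] + rnorm(sum(pos), 0, noise_sd), 0)
      dtheta
    })
  }
  data.frame(x = x, dtheta = dtheta)
}
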
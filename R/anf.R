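# Auditory-nerve-fiber application: sigmoidal rate-intensity curves with
# spontaneous rates.
#
# Each fiber is a binary neuron with rate levels {r, r_m} and Gaussian input
# noise of size sigma_i, giving the effective rate-intensity curve
#   nu_i(s) = r_i + (r_m,i - r_i) H_i(s),  H_i(s) = Phi((s - theta_i)/sigma_i)
# on the standardized intensity axis. Because the spontaneous rate is
# nonzero, spike counts carry information beyond the binary silent/active
# split, so the channel here uses full Poisson counts: conditional on the
# (binary, noise-mixed) rate level, k_i ~ Poisson(rate * dT), i.e.
#   P(k | s) = (1 - H(s)) Pois(k; R rho) + H(s) Pois(k; R),   rho = r / r_m.
# Sound levels in dB SPL are standardized by the affine transform
# (level - mean) / sd of the assumed Gaussian level distribution.

#' Sound-level standardization transform
#'
#' @param mean_db mean of the assumed Gaussian sound-level distribution
#'   (default 30 dB SPL).
#' @param sd_db its standard deviation (default 12.5 dB).
#' @return a list of class `pc_level_transform`.
#' @export
level_transform <- function(mean_db = 30, sd_db = 12.5) {
  if (sd_db <= 0) stop("`sd_db` must be positive")
  structure(list(mean_db = mean_db, sd_db = sd_db),
            class = "pc_level_transform")
}

#' @rdname level_transform
#' @param level_db numeric vector of sound levels (dB SPL).
#' @param transform a [level_transform()].
#' @export
standardize_level <- function(level_db, transform = level_transform()) {
  (level_db - transform$mean_db) / transform$sd_db
}

#' Fit a sigmoidal rate-intensity curve
#'
#' Nonlinear least squares of
#' `rate = r + (r_m - r) * pnorm((s - theta) / sigma)` on standardized
#' levels, multistarted from data-driven initial guesses. A fit is flagged
#' low-confidence when the samples do not span both the spontaneous floor
#' and the saturation plateau.
#'
#' @param level_db numeric vector of sound levels (dB SPL).
#' @param rate_hz matching firing rates (Hz).
#' @param transform a [level_transform()] mapping dB to standardized units.
#' @return an object of class `pc_sigmoid_fit`: `r`, `r_m`, `theta`,
#'   `sigma` (standardized units), `rss`, `converged`, `low_confidence`.
#'   Degenerate input (a flat curve) yields `converged = FALSE` rather than
#'   an error.
#' @export
fit_sigmoid <- function(level_db, rate_hz, transform = level_transform()) {
  keep <- is.finite(level_db) & is.finite(rate_hz)
  level_db <- level_db[keep]; rate_hz <- rate_hz[keep]
  if (length(level_db) < 5L) stop("need at least 5 samples to fit a fiber")
  o <- order(level_db)
  s <- standardize_level(level_db[o], transform)
  y <- rate_hz[o]
  fail <- function() structure(list(r = NA_real_, r_m = NA_real_,
                                    theta = NA_real_, sigma = NA_real_,
                                    rss = NA_real_, converged = FALSE,
                                    low_confidence = TRUE),
                               class = "pc_sigmoid_fit")
  rng <- diff(range(y))
  if (rng < max(1e-8, 1e-3 * max(abs(y), 1))) return(fail())  # flat curve
  r0 <- max(min(y), 0)
  rm0 <- max(y)
  # level of half rise and 10-90% span for initial theta and sigma
  yn <- (y - r0) / (rm0 - r0)
  theta0 <- tryCatch(stats::approx(yn, s, xout = 0.5, ties = mean)$y,
                     error = function(e) NA_real_)
  if (!is.finite(theta0)) theta0 <- stats::median(s)
  s10 <- tryCatch(stats::approx(yn, s, xout = 0.1, ties = mean)$y,
                  error = function(e) NA_real_)
  s90 <- tryCatch(stats::approx(yn, s, xout = 0.9, ties = mean)$y,
                  error = function(e) NA_real_)
  sigma0 <- if (is.finite(s10) && is.finite(s90) && s90 > s10)
    (s90 - s10) / 2.563 else diff(range(s)) / 4
  best <- NULL
  for (sg in unique(pmax(c(sigma0, sigma0 / 3, sigma0 * 3, 0.3), 0.02))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ r + (rm - r) * pnorm((s - theta) / sigma),
        start = list(r = r0, rm = rm0, theta = theta0, sigma = sg),
        lower = c(r = 0, rm = 1e-6, theta = min(s) - 5, sigma = 1e-4),
        upper = c(r = max(y) + 1, rm = 2 * max(y) + 10,
                  theta = max(s) + 5, sigma = 10 * diff(range(s)) + 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(fail())
  cf <- coef(best$fit)
  if (cf[["rm"]] <= cf[["r"]] + 1e-6) return(fail())
  # span check: floor and plateau both visited
  H_lo <- pnorm((min(s) - cf[["theta"]]) / cf[["sigma"]])
  H_hi <- pnorm((max(s) - cf[["theta"]]) / cf[["sigma"]])
  structure(list(r = unname(cf["r"]), r_m = unname(cf["rm"]),
                 theta = unname(cf["theta"]), sigma = unname(cf["sigma"]),
                 rss = best$rss, converged = TRUE,
                 low_confidence = (H_lo > 0.1 || H_hi < 0.9)),
            class = "pc_sigmoid_fit")
}

#' @export
print.pc_sigmoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<sigmoid fit: FAILED>\n")
    return(invisible(x))
  }
  cat(sprintf("<sigmoid fit: r = %.2f Hz, r_m = %.2f Hz, theta = %.3f, sigma = %.3f%s>\n",
              x$r, x$r_m, x$theta, x$sigma,
              if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  invisible(x)
}

#' Fit every fiber of a tuning-curve table
#'
#' @param curves data frame with columns `fiber_id`, `animal_id`,
#'   `level_db`, `rate_hz` (one row per measurement; repeated measurements
#'   of the same fiber are pooled).
#' @param transform a [level_transform()].
#' @return a data frame with one row per fiber: `fiber_id`, `animal_id`,
#'   `r`, `r_m`, `rho` (= r / r_m), `theta`, `sigma`, `rss`, `converged`,
#'   `low_confidence`.
#' @export
fit_cohort <- function(curves, transform = level_transform()) {
  need <- c("fiber_id", "animal_id", "level_db", "rate_hz")
  if (!all(need %in% names(curves)))
    stop("`curves` must have columns ", paste(need, collapse = ", "))
  ids <- unique(curves$fiber_id)
  rows <- lapply(ids, function(id) {
    d <- curves[curves$fiber_id == id, ]
    ft <- fit_sigmoid(d$level_db, d$rate_hz, transform)
    data.frame(fiber_id = id, animal_id = d$animal_id[1],
               r = ft$r, r_m = ft$r_m, rho = ft$r / ft$r_m,
               theta = ft$theta, sigma = ft$sigma, rss = ft$rss,
               converged = ft$converged, low_confidence = ft$low_confidence)
  })
  do.call(rbind, rows)
}

#' Classify fibers into spontaneous-rate types
#'
#' Ranks each fiber by `D_i = F(rho_i) - F(sigma_i)`, the difference of the
#' empirical cumulative distribution values of its normalized spontaneous
#' rate and its dynamic range. With two types, `D_i > 0` is type 1 (high
#' normalized spontaneous rate, narrow dynamic range) and `D_i <= 0` type 2.
#' With three types the fibers are cut at the tertiles of `D_i`, type 1
#' being the highest tertile.
#'
#' @param fits data frame from [fit_cohort()] (columns `rho`, `sigma`,
#'   `theta`; non-converged rows are dropped).
#' @param n_types 2 or 3.
#' @param outlier_z if non-`NULL`, fibers with `|robust z| > outlier_z` on
#'   `rho` (median/MAD) are excluded before classification. Disabled by
#'   default.
#' @return a list: `assignments` (data frame with `fiber_id`, `type`, `D`),
#'   `centroids` (per-type means of `rho`, `sigma`, `theta`), `n_types`.
#' @export
classify_fibers <- function(fits, n_types = 2, outlier_z = NULL) {
  stopifnot(n_types %in% c(2, 3))
  f <- fits[fits$converged & is.finite(fits$rho) & is.finite(fits$sigma), ]
  if (nrow(f) < 2L) stop("need at least 2 converged fits")
  if (!is.null(outlier_z)) {
    z <- (f$rho - median(f$rho)) / mad(f$rho)
    f <- f[abs(z) <= outlier_z | !is.finite(z), ]
  }
  Frho <- ecdf(f$rho)(f$rho)
  Fsig <- ecdf(f$sigma)(f$sigma)
  D <- Frho - Fsig
  if (n_types == 2) {
    type <- ifelse(D > 0, 1L, 2L)
  } else {
    qs <- quantile(D, c(1 / 3, 2 / 3), type = 7)
    type <- ifelse(D > qs[2], 1L, ifelse(D > qs[1], 2L, 3L))
  }
  centroids <- do.call(rbind, lapply(sort(unique(type)), function(t) {
    d <- f[type == t, ]
    data.frame(type = t, rho = mean(d$rho), sigma = mean(d$sigma),
               theta = mean(d$theta), n = nrow(d))
  }))
  list(assignments = data.frame(fiber_id = f$fiber_id, type = type, D = D),
       centroids = centroids, n_types = n_types)
}

#' Parameter correlations across a fitted cohort
#'
#' The two structural correlations of auditory-nerve populations: dynamic
#' range against normalized spontaneous rate (negative in data) and dynamic
#' range against threshold (positive).
#'
#' @param fits data frame from [fit_cohort()].
#' @return named numeric vector `c(sigma_rho, sigma_theta)` of Pearson
#'   correlations over the converged fits.
#' @export
cohort_correlations <- function(fits) {
  f <- fits[fits$converged, ]
  c(sigma_rho = cor(f$sigma, f$rho),
    sigma_theta = cor(f$sigma, f$theta))
}

#' Representative neuron parameters
#'
#' Small helper building the parameter table [mi_anf()] expects.
#'
#' @param rho normalized spontaneous rates `r / r_m` (one per neuron).
#' @param sigma dynamic ranges (standardized units, > 0).
#' @return data frame with columns `rho`, `sigma`.
#' @export
#' @examples
#' anf_neurons(c(0.159, 0.036), c(0.337, 0.534))  # the two-type model
anf_neurons <- function(rho, sigma) {
  if (length(rho) != length(sigma)) stop("`rho` and `sigma` lengths differ")
  if (any(rho < 0 | rho >= 1)) stop("`rho` must be in [0, 1)")
  if (any(sigma < 0)) stop("`sigma` must be non-negative")
  data.frame(rho = rho, sigma = sigma)
}

# Per-neuron full-count kernels over the quadrature nodes:
# a list of (k_max + 1) x G matrices P(k | s).
anf_kernels <- function(theta, neurons, R, s, k_max) {
  ks <- 0:k_max
  p_hi <- dpois(ks, R)
  lapply(seq_len(nrow(neurons)), function(i) {
    H <- effective_tuning_curve(theta[i], s, input_noise(neurons$sigma[i]))
    p_lo <- dpois(ks, R * neurons$rho[i])
    outer(p_lo, 1 - H) + outer(p_hi, H)
  })
}

#' Mutual information of an ANF population (full spike counts)
#'
#' Independent-coding channel for up to three sigmoidal neurons with
#' spontaneous rates: conditional on the stimulus, each neuron's count is a
#' mixture of Poisson(`R * rho_i`) (below threshold) and Poisson(`R`)
#' (above), mixed by its tuning curve. Computed as output entropy minus
#' noise entropy with tail-truncated count sums; reported in nats.
#'
#' @param thresholds numeric vector of thresholds (standardized units), one
#'   per neuron.
#' @param neurons data frame from [anf_neurons()].
#' @param output an [output_noise()] model (expected count `R` at maximal
#'   rate in the coding window).
#' @param stimulus a [stimulus_model()] (standard normal by default).
#' @param k_tail_tol per-neuron Poisson tail tolerance fixing the count
#'   truncation (default `1e-10`, `k_max` about 45 at `R = 13.8`).
#' @param control a [quadrature_control()]; ANF dynamic ranges are broad, so
#'   the default 801-point rule is generous.
#' @return a `pc_channel_eval` in nats.
#' @export
#' @examples
#' \donttest{
#' two <- anf_neurons(c(0.159, 0.036), c(0.337, 0.534))
#' mi_anf(c(-0.35, 0.55), two, output_noise(13.8))
#' }
mi_anf <- function(thresholds, neurons, output,
                   stimulus = stimulus_model(), k_tail_tol = 1e-10,
                   control = quadrature_control()) {
  theta <- as.numeric(thresholds)
  N <- nrow(neurons)
  if (length(theta) != N) stop("one threshold per neuron is required")
  if (N > 3L) stop("supported up to N = 3 neurons")
  R <- output$R
  k_max <- poisson_k_max(R, k_tail_tol)
  quad <- build_quadrature(stimulus, theta, neurons$sigma, control)
  psw <- stimulus_pdf(quad$s, stimulus) * quad$w
  psw <- psw / sum(psw)
  A <- anf_kernels(theta, neurons, R, quad$s, k_max)
  # noise entropy: counts are conditionally independent given s
  h_cond <- Reduce(`+`, lapply(A, function(a) -colSums(xlogx(a))))
  noise_entropy <- sum(psw * h_cond)
  # output entropy from the joint count distribution
  out_entropy <- if (N == 1L) {
    pk <- as.numeric(A[[1]] %*% psw)
    -sum(xlogx(pk))
  } else if (N == 2L) {
    M <- (A[[1]] * rep(psw, each = k_max + 1L)) %*% t(A[[2]])
    -sum(xlogx(M))
  } else {
    tot <- 0
    for (k3 in 0:k_max) {
      w3 <- psw * A[[3]][k3 + 1L, ]
      M <- (A[[1]] * rep(w3, each = k_max + 1L)) %*% t(A[[2]])
      tot <- tot - sum(xlogx(M))
    }
    tot
  }
  new_channel_evaluation(out_entropy - noise_entropy, "nats", "independent",
                         N, truncation_k_max = as.integer(k_max),
                         quadrature_points = length(quad$s))
}

#' Mean spike count and information per spike
#'
#' Expected total spike count per coding window,
#' `E = integral P(s) sum_i nu_i(s) dT ds`, and the efficiency measure
#' `MI / E` in nats per spike.
#'
#' @inheritParams mi_anf
#' @return a list: `mi` (nats), `expected_spikes`, `info_per_spike`.
#' @export
mean_rate_and_info_per_spike <- function(thresholds, neurons, output,
                                         stimulus = stimulus_model(),
                                         k_tail_tol = 1e-10,
                                         control = quadrature_control()) {
  theta <- as.numeric(thresholds)
  ev <- mi_anf(theta, neurons, output, stimulus, k_tail_tol, control)
  quad <- build_quadrature(stimulus, theta, neurons$sigma, control)
  psw <- stimulus_pdf(quad$s, stimulus) * quad$w
  psw <- psw / sum(psw)
  lam <- Reduce(`+`, lapply(seq_len(nrow(neurons)), function(i) {
    H <- effective_tuning_curve(theta[i], quad$s, input_noise(neurons$sigma[i]))
    output$R * (neurons$rho[i] + (1 - neurons$rho[i]) * H)
  }))
  spikes <- sum(psw * lam)
  if (spikes <= 0) stop("expected spike count is zero; information per spike undefined")
  list(mi = ev$mi, expected_spikes = spikes, info_per_spike = ev$mi / spikes)
}

mirror_point <- function(theta, stimulus) 2 * stimulus$mean - theta

#' Coarse-to-fine search of the ANF information landscape
#'
#' Evaluates [mi_anf()] on a coarse threshold grid, keeps the local maxima,
#' and refines each by repeatedly halving the grid step (at least three
#' rounds), optionally polishing with Nelder-Mead. For a symmetric stimulus
#' the landscape is centrosymmetric, so only the half-space with
#' `theta_1 <= mean` is evaluated and maxima are completed by mirroring.
#'
#' @inheritParams mi_anf
#' @param bounds length-2 numeric: grid bounds on every threshold axis
#'   (default `c(-3, 3)`).
#' @param coarse_step coarse grid step (default 0.25, 0.3 for three
#'   neurons).
#' @param rounds number of halving refinement rounds (default 4).
#' @param polish logical: Nelder-Mead polish of each refined maximum
#'   (default TRUE).
#' @param top_k number of coarse-grid candidates kept before clustering.
#' @return a list: `maxima` (data frame of threshold columns and `mi`,
#'   sorted decreasing, mirror images included), `global` (row of the best),
#'   `n_evaluations`.
#' @export
landscape_search <- function(neurons, output, stimulus = stimulus_model(),
                             bounds = c(-3, 3), coarse_step = NULL,
                             rounds = 4L, polish = TRUE, top_k = 40L,
                             k_tail_tol = 1e-10,
                             control = quadrature_control()) {
  N <- nrow(neurons)
  if (is.null(coarse_step)) coarse_step <- if (N >= 3) 0.3 else 0.25
  ax <- seq(bounds[1], bounds[2], by = coarse_step)
  grid <- as.matrix(do.call(expand.grid, rep(list(ax), N)))
  colnames(grid) <- paste0("theta", seq_len(N))
  # both stimulus families are symmetric about their mean, so the landscape
  # is centrosymmetric and the half-space theta_1 <= mean suffices
  centro <- TRUE
  grid <- grid[grid[, 1] <= stimulus$mean + 1e-12, , drop = FALSE]
  evals <- 0L
  f <- function(th) {
    evals <<- evals + 1L
    mi_anf(th, neurons, output, stimulus, k_tail_tol, control)$mi
  }
  mi0 <- apply(grid, 1L, f)
  # candidate local maxima: top points, merged when closer than 1.5 steps
  o <- order(mi0, decreasing = TRUE)[seq_len(min(top_k, length(mi0)))]
  cand <- list()
  for (i in o) {
    p <- grid[i, ]
    if (!any(vapply(cand, function(c.) max(abs(c.$theta - p)) < 1.5 * coarse_step,
                    logical(1))))
      cand[[length(cand) + 1L]] <- list(theta = p, mi = mi0[i])
  }
  refine <- function(center, step) {
    best <- list(theta = center, mi = f(center))
    for (r in seq_len(rounds)) {
      step <- step / 2
      moves <- as.matrix(do.call(expand.grid, rep(list(c(-2, -1, 0, 1, 2)), N)))
      pts <- sweep(moves * step, 2L, best$theta, `+`)
      vals <- apply(pts, 1L, f)
      j <- which.max(vals)
      if (vals[j] > best$mi) best <- list(theta = pts[j, ], mi = vals[j])
    }
    if (polish) {
      op <- if (N == 1L) {
        optim(best$theta, function(th) -f(th), method = "Brent",
              lower = best$theta - 0.5, upper = best$theta + 0.5)
      } else {
        optim(best$theta, function(th) -f(th), method = "Nelder-Mead",
              control = list(reltol = 1e-11, maxit = 1500))
      }
      if (-op$value > best$mi) best <- list(theta = op$par, mi = -op$value)
    }
    best
  }
  # With nonzero spontaneous rates the landscape is centrosymmetric only up
  # to O(e^{-R rho}) corrections (mirroring swaps the two mixture
  # components, which is not an output relabeling), so mirrored candidates
  # are refined independently rather than copied.
  cand_all <- cand
  if (centro) {
    for (c. in cand) {
      cand_all[[length(cand_all) + 1L]] <-
        list(theta = mirror_point(c.$theta, stimulus), mi = NA_real_)
    }
  }
  refined <- lapply(cand_all, function(c.) refine(c.$theta, coarse_step))
  rows <- list()
  for (b in refined) {
    th <- as.numeric(b$theta)
    dup <- any(vapply(rows, function(r) max(abs(r$theta - th)) < 1e-3, logical(1)))
    if (!dup) rows[[length(rows) + 1L]] <- list(theta = th, mi = b$mi)
  }
  maxima <- do.call(rbind, lapply(rows, function(r)
    data.frame(t(setNames(r$theta, paste0("theta", seq_len(N)))), mi = r$mi)))
  maxima <- maxima[order(-maxima$mi), , drop = FALSE]
  rownames(maxima) <- NULL
  list(maxima = maxima, global = maxima[1, , drop = FALSE],
       n_evaluations = evals)
}
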
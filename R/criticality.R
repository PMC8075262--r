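# Bifurcation detection, phase-transition classification and critical
# exponents.
#
# As either noise source grows, the number of distinct information-optimal
# thresholds drops through bifurcations at critical noise levels. For the
# independent channel these are continuous (the threshold differences --
# the order parameters -- go to zero smoothly and the maximized information
# has a discontinuous second derivative: a second-order transition in the
# Ehrenfest sense); for the lumped channel at finite noise they are jumps
# between distinct local maxima (discontinuous first derivative:
# first-order). At a continuous merge of M thresholds the information
# landscape flattens along the (M-1)-dimensional ridge
# sum(theta_involved) = const, so M-1 Hessian eigenvalues approach zero.

#' Hessian of the information landscape
#'
#' Central finite differences with one step of Richardson extrapolation
#' (steps `h` and `h/2`), symmetrized, followed by an eigendecomposition.
#' `f` defaults to the channel mutual information in nats as a function of
#' the threshold vector.
#'
#' @param thresholds numeric vector: the point (usually an optimum).
#' @param channel `"independent"` or `"lumped"`; ignored when `f` is given.
#' @param stimulus,noise,output model objects, as in [channel_mi()].
#' @param f optional function `f(theta) -> scalar` overriding the channel
#'   information (used for testing against analytic surfaces).
#' @param fd_step base finite-difference step (default `1e-3`).
#' @param control a [quadrature_control()].
#' @param ... passed to [channel_mi()].
#' @return an object of class `pc_hessian`: `matrix`, `eigenvalues`
#'   (decreasing), `eigenvectors` (columns), `fd_step`.
#' @export
hessian_at <- function(thresholds, channel = c("independent", "lumped"),
                       stimulus = NULL, noise = NULL, output = NULL,
                       f = NULL, fd_step = 1e-3,
                       control = quadrature_control(), ...) {
  theta <- as_theta(thresholds)
  n <- length(theta)
  if (is.null(f)) {
    channel <- match.arg(channel)
    f <- function(th) channel_mi(th, channel, stimulus, noise, output,
                                 "nats", control = control, ...)$mi
  }
  if (fd_step <= 0) stop("`fd_step` must be positive")
  hess_fd <- function(h) {
    H <- matrix(0, n, n)
    f0 <- f(theta)
    for (i in seq_len(n)) {
      ei <- replace(numeric(n), i, h)
      H[i, i] <- (f(theta + ei) - 2 * f0 + f(theta - ei)) / h^2
      if (i < n) for (j in (i + 1):n) {
        ej <- replace(numeric(n), j, h)
        H[i, j] <- H[j, i] <-
          (f(theta + ei + ej) - f(theta + ei - ej) -
           f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h^2)
      }
    }
    H
  }
  H1 <- hess_fd(fd_step)
  H2 <- hess_fd(fd_step / 2)
  H <- (4 * H2 - H1) / 3
  H <- (H + t(H)) / 2
  e <- eigen(H, symmetric = TRUE)
  structure(list(matrix = H, eigenvalues = e$values,
                 eigenvectors = e$vectors, fd_step = fd_step),
            class = "pc_hessian")
}

#' @export
print.pc_hessian <- function(x, ...) {
  cat(sprintf("<information-landscape Hessian, %d x %d, fd step %g>\n",
              nrow(x$matrix), ncol(x$matrix), x$fd_step))
  cat("  eigenvalues:", format(x$eigenvalues, digits = 6), "\n")
  invisible(x)
}

#' Locate a critical noise level by bisection
#'
#' Takes a [scan_noise()] result that brackets a change in the number of
#' distinct optimal thresholds and bisects the noise axis, re-optimizing
#' the thresholds at every midpoint (warm-started from the bracket ends),
#' until the relative bracket width falls below `rel_tol`.
#'
#' @param scan a `pc_noise_scan`.
#' @param M optional number of thresholds involved: the bracket chosen is
#'   the first grid cell whose distinct-count change equals `M - 1` merges
#'   (e.g. `M = 2` for a pairwise merge). By default the first change along
#'   the scan is used.
#' @param rel_tol relative bracket-width tolerance (default `1e-4`).
#' @return the critical noise value (bracket midpoint), with the final
#'   bracket and the per-side solutions attached as attributes.
#' @export
detect_critical_noise <- function(scan, M = NULL, rel_tol = 1e-4) {
  stopifnot(inherits(scan, "pc_noise_scan"))
  dc <- scan$distinct_counts
  chg <- which(diff(dc) != 0)
  if (is.null(M)) {
    idx <- chg[1]
    if (is.na(idx)) stop("scan contains no change in the distinct-threshold count")
  } else {
    idx <- chg[abs(diff(dc))[chg] == (M - 1L)][1]
    if (is.na(idx)) stop("no bracket with a ", M, "-threshold merge in the scan")
  }
  lo <- scan$grid[idx]; hi <- scan$grid[idx + 1L]
  c_lo <- dc[idx]
  th_lo <- scan$results[[idx]]$thresholds
  th_hi <- scan$results[[idx + 1L]]$thresholds
  models <- function(v) {
    if (scan$axis == "R")
      list(noise = input_noise(scan$fixed_other), output = output_noise(v))
    else
      list(noise = input_noise(v), output = output_noise(scan$fixed_other))
  }
  while (abs(hi - lo) > rel_tol * max(abs(lo), abs(hi))) {
    mid <- (lo + hi) / 2
    m <- models(mid)
    starts <- rbind(th_lo, th_hi, start_grid(scan$N, scan$stimulus))
    res <- optimize_thresholds(scan$N, scan$channel, scan$stimulus,
                               m$noise, m$output, starts = starts,
                               method = scan$method, log_base = scan$log_base,
                               reltol = scan$reltol, control = scan$control)
    if (count_distinct(res$thresholds, scan$tol) == c_lo) {
      lo <- mid; th_lo <- res$thresholds
    } else {
      hi <- mid; th_hi <- res$thresholds
    }
  }
  structure((lo + hi) / 2, bracket = c(lo, hi),
            thresholds_lo = th_lo, thresholds_hi = th_hi)
}

one_sided_slope <- function(x, y, x0, side, k = 4L, deg = 1L) {
  sel <- if (side == "left") x < x0 else x > x0
  x <- x[sel]; y <- y[sel]
  o <- order(abs(x - x0))
  use <- o[seq_len(min(length(o), max(k, deg + 2L)))]
  d <- x[use] - x0
  fit <- lm(y[use] ~ poly(d, degree = deg, raw = TRUE))
  cf <- coef(fit)
  # suppressWarnings: summary.lm flags exact fits, which are fine here
  se <- suppressWarnings(sqrt(diag(vcov(fit)))[2])
  list(slope = unname(cf[2]),
       curv = if (deg >= 2) 2 * unname(cf[3]) else NA_real_,
       se = se,
       resid_sd = sqrt(mean(stats::residuals(fit)^2)))
}

#' Classify a phase transition from the maximized-information curve
#'
#' Estimates the first derivative of `MI*(noise)` from each side of the
#' critical value with one-sided polynomial fits. A jump in the first
#' derivative larger than `jump_tol` flags a first-order transition;
#' otherwise the jump in the second derivative is tested and the
#' transition is classified as second order. By default `jump_tol` is ten
#' times the finite-difference noise floor estimated from the fit standard
#' errors, so quadrature jitter is not mistaken for a genuine jump.
#'
#' @param noise numeric vector of noise values (either axis).
#' @param mi maximized information at each noise value.
#' @param critical_value the critical noise level separating the branches.
#' @param jump_tol optional absolute tolerance on the first-derivative jump.
#' @param k number of points used on each side (default 4).
#' @return a list: `order` (`"first"` or `"second"`), `d1_jump`, `d2_jump`,
#'   `jump_tol`, and the per-side slope fits.
#' @export
classify_transition <- function(noise, mi, critical_value, jump_tol = NULL,
                                k = 4L) {
  if (sum(noise < critical_value) < 3 || sum(noise > critical_value) < 3)
    stop("need at least 3 samples on each side of the critical value")
  L1 <- one_sided_slope(noise, mi, critical_value, "left", k, deg = 2L)
  R1 <- one_sided_slope(noise, mi, critical_value, "right", k, deg = 2L)
  d1_jump <- abs(L1$slope - R1$slope)
  d2_jump <- abs(L1$curv - R1$curv)
  if (is.null(jump_tol)) jump_tol <- 10 * max(L1$se, R1$se, 1e-12)
  ord <- if (d1_jump > jump_tol) "first" else "second"
  list(order = ord, d1_jump = d1_jump, d2_jump = d2_jump,
       jump_tol = jump_tol, left = L1, right = R1)
}

#' Fit a critical exponent by log-log regression
#'
#' Fits `quantity ~ |(x - x_c)/x_c|^exponent` on one side of the critical
#' value by least squares of `log(quantity)` against the log relative
#' distance, inside a relative-distance window.
#'
#' @param x noise values.
#' @param quantity positive order-parameter (threshold difference) or
#'   eigenvalue-magnitude values at `x`.
#' @param critical_value the critical noise level `x_c`.
#' @param side `"left"` (`x < x_c`) or `"right"` (`x > x_c`).
#' @param window relative-distance window `c(min, max)` (default
#'   `c(1e-3, 5e-2)`).
#' @return a list: `exponent`, `stderr`, `n`, `window`, `side`, `prefactor`.
#' @export
#' @examples
#' x <- seq(0.5, 0.99, length.out = 20)
#' fit_critical_exponent(x, sqrt(1 - x), 1, side = "left",
#'                       window = c(1e-3, 0.5))$exponent  # 0.5
fit_critical_exponent <- function(x, quantity, critical_value,
                                  side = c("left", "right"),
                                  window = c(1e-3, 5e-2)) {
  side <- match.arg(side)
  rel <- (x - critical_value) / abs(critical_value)
  sel <- if (side == "left") rel < 0 else rel > 0
  sel <- sel & abs(rel) >= window[1] & abs(rel) <= window[2] &
    is.finite(quantity) & quantity > 0
  if (sum(sel) < 4L)
    stop("fewer than 4 usable points inside the fit window")
  lx <- log(abs(rel[sel])); ly <- log(quantity[sel])
  fit <- lm(ly ~ lx)
  list(exponent = unname(coef(fit)[2]),
       stderr = suppressWarnings(sqrt(diag(vcov(fit)))[2]),
       n = sum(sel), window = window, side = side,
       prefactor = exp(unname(coef(fit)[1])))
}

#' Bifurcation summary record
#'
#' Bundles the critical value, transition order and exponent fits for one
#' bifurcation into a single record.
#'
#' @param axis `"R"` or `"sigma"`.
#' @param critical_value critical noise level.
#' @param M number of thresholds involved.
#' @param order `"first"` or `"second"`.
#' @param exponents named list of [fit_critical_exponent()] results.
#' @param window the fit window used.
#' @return an object of class `pc_bifurcation`.
#' @export
bifurcation_record <- function(axis, critical_value, M, order,
                               exponents = list(), window = c(1e-3, 5e-2)) {
  continuity <- if (order == "second") "continuous" else "discontinuous"
  structure(list(axis = axis, critical_value = as.numeric(critical_value),
                 thresholds_involved = as.integer(M), continuity = continuity,
                 transition_order = order, exponents = exponents,
                 window = window),
            class = "pc_bifurcation")
}

#' @export
print.pc_bifurcation <- function(x, ...) {
  cat(sprintf("<bifurcation on %s at %.6g: %d thresholds, %s (%s order)>\n",
              x$axis, x$critical_value, x$thresholds_involved,
              x$continuity, x$transition_order))
  for (nm in names(x$exponents))
    cat(sprintf("  %s = %.4f +/- %.4f\n", nm, x$exponents[[nm]]$exponent,
                x$exponents[[nm]]$stderr))
  invisible(x)
}
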
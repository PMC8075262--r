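# Information-maximizing thresholds and noise scans.
#
# The information landscape is multimodal (near-mirror optima for a
# symmetric stimulus at low output noise, and genuinely distinct local
# maxima for the lumped channel), so optimization is deterministic
# multistart local search:
# Nelder-Mead from a fixed grid of starting points built from stimulus
# quantiles, including replicated-threshold starts that sit on the merge
# manifolds. No randomness is used anywhere, so runs are reproducible
# without seeds.

start_grid <- function(N, stimulus) {
  q <- stimulus_quantile(seq_len(N) / (N + 1), stimulus)
  # all non-decreasing N-tuples over the quantile levels: includes the
  # all-distinct start and every replicated (all-equal, pairwise-equal) start
  idx <- do.call(expand.grid, rep(list(seq_len(N)), N))
  keep <- apply(idx, 1L, function(r) all(diff(r) >= 0))
  starts <- as.matrix(idx[keep, , drop = FALSE])
  starts <- matrix(q[starts], ncol = N)
  starts <- rbind(starts, rep(stimulus$mean, N))
  unname(starts[!duplicated(round(starts, 12)), , drop = FALSE])
}

#' Number of distinct thresholds
#'
#' Single-linkage clustering of the sorted thresholds: two neighbours belong
#' to the same cluster when their gap is at most `tol`.
#'
#' @param thresholds numeric vector or [threshold_vector()].
#' @param tol positive gap tolerance; defaults to the tolerance stored in a
#'   [threshold_vector()], else `1e-3`.
#' @return integer in `[1, N]`.
#' @export
#' @examples
#' count_distinct(c(0.1, 0.1004, 2), tol = 1e-3)  # 2
count_distinct <- function(thresholds, tol = NULL) {
  if (is.null(tol))
    tol <- if (inherits(thresholds, "pc_thresholds")) thresholds$tol else 1e-3
  if (tol <= 0) stop("`tol` must be positive")
  theta <- sort(as_theta(thresholds))
  1L + sum(diff(theta) > tol)
}

# Sorting is the only safe canonicalization: permuting thresholds is an
# exact symmetry, but the sign flip theta -> -theta is not (silent Poisson
# outputs are ambiguous, so mirrored landscapes differ at finite R; they
# coincide only as R -> infinity).
canonical_thresholds <- function(theta, stimulus) sort(theta)

#' Optimize population thresholds
#'
#' Maximizes the channel mutual information over the `N` thresholds
#' (deterministic multistart Nelder-Mead; optionally BFGS for the lumped
#' channel, whose Hessian stays well conditioned through its bifurcations).
#' Thresholds are reported sorted ascending; permutation is an exact
#' symmetry of both channels, so sorting loses nothing.
#'
#' @param N population size (`N <= 6` independent, `N <= 3` lumped).
#' @param channel `"independent"` or `"lumped"`.
#' @param stimulus a [stimulus_model()].
#' @param noise an [input_noise()] model.
#' @param output an [output_noise()] model.
#' @param starts optional matrix of starting points (rows = starts); by
#'   default a fixed grid of stimulus-quantile combinations.
#' @param method `"Nelder-Mead"` (default) or `"BFGS"`.
#' @param log_base `"bits"` or `"nats"`.
#' @param reltol relative convergence tolerance on the information.
#' @param maxit iteration cap per start.
#' @param control a [quadrature_control()].
#' @param ... passed on to [mi_independent()] / [mi_lumped()].
#' @return an object of class `pc_optim_result`: fields `thresholds`
#'   (sorted), `mi`, `log_base`, `channel`, `n_restarts`, `best_start`,
#'   `converged`, `start_values`.
#' @export
#' @examples
#' \donttest{
#' optimize_thresholds(2, "independent", stimulus_model(),
#'                     input_noise(0), output_noise(2.5))
#' }
optimize_thresholds <- function(N, channel = c("independent", "lumped"),
                                stimulus, noise, output, starts = NULL,
                                method = c("Nelder-Mead", "BFGS"),
                                log_base = c("bits", "nats"),
                                reltol = 1e-10, maxit = 2000,
                                control = quadrature_control(), ...) {
  channel <- match.arg(channel)
  method <- match.arg(method)
  log_base <- match.arg(log_base)
  N <- as.integer(N)
  if (N < 1L) stop("`N` must be at least 1")
  if (channel == "independent" && N > 6L)
    stop("independent channel supported up to N = 6")
  if (channel == "lumped" && N > 3L)
    stop("lumped channel supported up to N = 3")
  negmi <- function(th) -channel_mi(th, channel, stimulus, noise, output,
                                    log_base, control = control, ...)$mi
  if (is.null(starts)) starts <- start_grid(N, stimulus)
  starts <- matrix(starts, ncol = N)

  if (N == 1L) {
    sd_s <- sqrt(stimulus$variance)
    opt <- optimize(negmi, stimulus$mean + c(-10, 10) * sd_s, tol = 1e-9)
    theta <- canonical_thresholds(opt$minimum, stimulus)
    return(structure(list(thresholds = theta, mi = -opt$objective,
                          log_base = log_base, channel = channel,
                          n_restarts = 1L, best_start = 1L, converged = TRUE,
                          start_values = starts),
                     class = "pc_optim_result"))
  }

  best <- NULL
  vals <- rep(NA_real_, nrow(starts))
  conv <- logical(nrow(starts))
  for (i in seq_len(nrow(starts))) {
    o <- optim(starts[i, ], negmi, method = method,
               control = list(reltol = reltol, maxit = maxit))
    vals[i] <- -o$value
    conv[i] <- o$convergence == 0
    if (is.null(best) || o$value < best$value) {
      best <- o
      best$start <- i
    }
  }
  if (!any(conv) && best$convergence != 0)
    stop("no start converged; best value ", -best$value)
  # polish once from the incumbent
  o2 <- optim(best$par, negmi, method = method,
              control = list(reltol = reltol, maxit = maxit))
  if (o2$value < best$value) {
    o2$start <- best$start
    best <- o2
  }
  theta <- canonical_thresholds(best$par, stimulus)
  structure(list(thresholds = theta, mi = -best$value, log_base = log_base,
                 channel = channel, n_restarts = nrow(starts),
                 best_start = best$start,
                 converged = best$convergence == 0, start_values = vals),
            class = "pc_optim_result")
}

#' @export
print.pc_optim_result <- function(x, ...) {
  cat(sprintf("<optimal thresholds, %s channel, N = %d>\n",
              x$channel, length(x$thresholds)))
  cat("  theta* =", format(x$thresholds, digits = 6), "\n")
  cat(sprintf("  MI = %.6f %s (%d starts, converged: %s)\n",
              x$mi, x$log_base, x$n_restarts, x$converged))
  invisible(x)
}

#' Scan optimal thresholds along a noise axis
#'
#' Re-optimizes the thresholds at each grid value of one noise source while
#' the other is held fixed. Each point is started both from the full cold
#' multistart grid and from the neighbouring grid point's solution (warm
#' start), which tracks continuous branches while still catching the
#' discontinuous jumps between local maxima that the lumped channel shows.
#'
#' @param axis `"R"` or `"sigma"`: the noise source being swept.
#' @param grid strictly monotone numeric vector of noise values.
#' @param fixed_other the value of the other noise source (`sigma` when
#'   `axis = "R"`, `R` when `axis = "sigma"`).
#' @param N population size.
#' @inheritParams optimize_thresholds
#' @param tol distinctness tolerance for the reported cluster counts.
#' @return an object of class `pc_noise_scan`: `axis`, `grid`,
#'   `fixed_other`, `results` (list of `pc_optim_result`), `thresholds`
#'   (matrix, one row per grid point), `mi`, `distinct_counts`, plus the
#'   model objects needed to re-optimize (used by
#'   [detect_critical_noise()]).
#' @export
scan_noise <- function(axis = c("R", "sigma"), grid, fixed_other, N,
                       channel = c("independent", "lumped"),
                       stimulus = stimulus_model(),
                       method = c("Nelder-Mead", "BFGS"),
                       log_base = c("bits", "nats"),
                       reltol = 1e-10, tol = 1e-3,
                       control = quadrature_control(), ...) {
  axis <- match.arg(axis)
  channel <- match.arg(channel)
  method <- match.arg(method)
  log_base <- match.arg(log_base)
  if (length(grid) < 2L || any(diff(grid) == 0) ||
      !(all(diff(grid) > 0) || all(diff(grid) < 0)))
    stop("`grid` must be strictly monotone")
  models <- function(v) {
    if (axis == "R") list(noise = input_noise(fixed_other), output = output_noise(v))
    else list(noise = input_noise(v), output = output_noise(fixed_other))
  }
  results <- vector("list", length(grid))
  prev <- NULL
  for (i in seq_along(grid)) {
    m <- models(grid[i])
    starts <- start_grid(N, stimulus)
    if (!is.null(prev)) starts <- rbind(prev, starts)
    res <- optimize_thresholds(N, channel, stimulus, m$noise, m$output,
                               starts = starts, method = method,
                               log_base = log_base, reltol = reltol,
                               control = control, ...)
    results[[i]] <- res
    prev <- res$thresholds
  }
  theta_mat <- do.call(rbind, lapply(results, `[[`, "thresholds"))
  structure(list(axis = axis, grid = grid, fixed_other = fixed_other,
                 N = N, channel = channel, stimulus = stimulus,
                 method = method, log_base = log_base, reltol = reltol,
                 control = control,
                 results = results, thresholds = theta_mat,
                 mi = vapply(results, `[[`, numeric(1), "mi"),
                 distinct_counts = vapply(results, function(r)
                   count_distinct(r$thresholds, tol), integer(1)),
                 tol = tol),
            class = "pc_noise_scan")
}

#' @export
print.pc_noise_scan <- function(x, ...) {
  cat(sprintf("<noise scan along %s, %s channel, N = %d, other noise = %g>\n",
              x$axis, x$channel, x$N, x$fixed_other))
  df <- data.frame(x$grid, x$mi, x$distinct_counts)
  names(df) <- c(x$axis, "mi", "distinct")
  print(df)
  invisible(x)
}
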
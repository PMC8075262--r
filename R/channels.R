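# Mutual information of the independent- and lumped-coding channels.
#
# A population of N binary neurons (two rate levels {0, nu_max}) encodes a
# scalar stimulus. Input noise enters through the effective tuning curves
# H_i(s); output noise through Poisson spike generation with expected count
# R at maximal rate. The independent channel reads out the vector of
# per-neuron counts; because the underlying rates are binary, all counts
# k_i >= 1 carry the same evidence and can be collapsed to a single state,
# so each neuron contributes a Bernoulli output with
#   P(k_i = 0 | s) = (1 - H_i(s)) + e^{-R} H_i(s)  =: Q_i(s)
#   P(k_i >= 1 | s) = (1 - e^{-R}) H_i(s)          =: S_i(s).
# The lumped channel reads out the scalar sum k = sum_i k_i, whose kernel
# P(k | N, s) is built by the exact recursive convolution of the per-neuron
# full-count distributions.
#
# When sigma = 0 the tuning curves are steps and every stimulus integral
# reduces to a finite sum over the N + 1 inter-threshold regions; that exact
# path is used automatically.

#' Per-neuron silent/active probabilities
#'
#' Binary-collapsed output probabilities of one neuron at stimulus `s`:
#' `Q = P(k = 0 | s)` and `S = P(k >= 1 | s)`; `Q + S = 1` exactly.
#'
#' @param theta the neuron's threshold.
#' @param s numeric vector of stimulus values.
#' @param noise an [input_noise()] model.
#' @param output an [output_noise()] model.
#' @return a list with numeric vectors `Q` and `S`.
#' @export
spike_state_probs <- function(theta, s, noise, output) {
  stopifnot(inherits(output, "pc_output_noise"))
  H <- effective_tuning_curve(theta, s, noise)
  S <- (1 - exp(-output$R)) * H
  list(Q = 1 - S, S = S)
}

new_channel_evaluation <- function(mi, log_base, channel, n_neurons,
                                   truncation_k_max = NA_integer_,
                                   quadrature_points = NA_integer_) {
  structure(list(mi = max(mi, 0), log_base = log_base, channel = channel,
                 n_neurons = n_neurons,
                 truncation_k_max = truncation_k_max,
                 quadrature_points = quadrature_points),
            class = "pc_channel_eval")
}

#' @export
print.pc_channel_eval <- function(x, ...) {
  cat(sprintf("<%s-coding channel, N = %d>\n", x$channel, x$n_neurons))
  cat(sprintf("  MI = %.6f %s\n", x$mi, x$log_base))
  if (!is.na(x$truncation_k_max))
    cat(sprintf("  count truncation k_max = %d\n", x$truncation_k_max))
  if (!is.na(x$quadrature_points))
    cat(sprintf("  quadrature points = %d\n", x$quadrature_points))
  invisible(x)
}

# Smallest k whose Poisson(lambda) upper-tail mass is below tol.
poisson_k_max <- function(lambda, tol = 1e-10) {
  max(qpois(tol, lambda, lower.tail = FALSE), 2L)
}

# Region probabilities for the noiseless (sigma = 0) exact path: with sorted
# thresholds the stimulus axis splits into N + 1 regions; in region j
# exactly the j lowest-threshold neurons are active.
region_probs <- function(theta, stimulus) {
  cuts <- c(-Inf, sort(theta), Inf)
  diff(stimulus_cdf(cuts, stimulus))
}

mi_independent_noiseless <- function(theta, stimulus, output, factor) {
  N <- length(theta)
  p_region <- region_probs(theta, stimulus)      # length N + 1
  q <- exp(-output$R)
  # state probabilities depend only on how many neurons are active (j) and
  # on which of the active ones are silent; enumerate the 2^N states
  K <- as.matrix(expand.grid(rep(list(0:1), N)))  # 2^N x N, col i = neuron i (sorted)
  mi_nats <- 0
  Pk <- numeric(nrow(K))
  Pkj <- matrix(0, nrow(K), N + 1L)
  for (j in 0:N) {
    active <- seq_len(N) <= j
    # P(k | region j): active neurons fire with prob 1 - q; inactive are silent
    ok <- if (j < N) rowSums(K[, !active, drop = FALSE]) == 0 else rep(TRUE, nrow(K))
    n_act_fire <- if (j > 0) rowSums(K[, active, drop = FALSE]) else 0
    pk <- ifelse(ok, (1 - q)^n_act_fire * q^(j - n_act_fire), 0)
    Pkj[, j + 1L] <- pk
  }
  Pk <- as.numeric(Pkj %*% p_region)
  term1 <- sum(p_region * colSums(xlogx(Pkj)))
  mi_nats <- term1 - sum(xlogx(Pk))
  new_channel_evaluation(mi_nats * factor,
                         if (factor == 1) "nats" else "bits",
                         "independent", N)
}

mi_lumped_noiseless <- function(theta, stimulus, output, factor, k_tail_tol) {
  N <- length(theta)
  p_region <- region_probs(theta, stimulus)
  k_max <- poisson_k_max(N * output$R, k_tail_tol)
  # in region j the summed count is Poisson(j * R)
  Pkj <- vapply(0:N, function(j) dpois(0:k_max, j * output$R), numeric(k_max + 1L))
  Pk <- as.numeric(Pkj %*% p_region)
  mi_nats <- sum(p_region * colSums(xlogx(Pkj))) - sum(xlogx(Pk))
  new_channel_evaluation(mi_nats * factor,
                         if (factor == 1) "nats" else "bits",
                         "lumped", N, truncation_k_max = k_max)
}

#' Mutual information of the independent-coding channel
#'
#' Computes `I(k_1, ..., k_N ; s)` for binary neurons with the per-neuron
#' binary collapse of Poisson counts (exact for binary rate levels). With
#' `sigma = 0` the computation is exact (finite sum over inter-threshold
#' regions); otherwise the stimulus integral uses a fixed Simpson grid.
#'
#' @param thresholds numeric vector or [threshold_vector()].
#' @param stimulus a [stimulus_model()].
#' @param noise an [input_noise()] model shared by all neurons.
#' @param output an [output_noise()] model.
#' @param log_base `"bits"` (default) or `"nats"`.
#' @param control a [quadrature_control()].
#' @return a `pc_channel_eval` with the information in `$mi`.
#' @export
#' @examples
#' st <- stimulus_model()
#' mi_independent(c(-0.6, 0.6), st, input_noise(0), output_noise(2.5))
mi_independent <- function(thresholds, stimulus, noise, output,
                           log_base = c("bits", "nats"),
                           control = quadrature_control()) {
  log_base <- match.arg(log_base)
  factor <- log_base_factor(log_base)
  theta <- as_theta(thresholds)
  N <- length(theta)
  if (N < 1L) stop("at least one neuron is required")
  if (noise$sigma == 0)
    return(mi_independent_noiseless(theta, stimulus, output, factor))
  quad <- build_quadrature(stimulus, theta, rep(noise$sigma, N), control)
  psw <- stimulus_pdf(quad$s, stimulus) * quad$w
  psw <- psw / sum(psw)
  H <- vapply(theta, function(th) effective_tuning_curve(th, quad$s, noise),
              numeric(length(quad$s)))           # G x N
  S <- (1 - exp(-output$R)) * H
  Q <- 1 - S
  # H underflows to 0/1 far from a threshold when sigma is small; cap the
  # logs at a large negative value so 0-probability states stay finite in
  # the matrix product (they contribute exactly 0 to the information)
  logQ <- pmax(log(Q), -1e4); logS <- pmax(log(S), -1e4)
  K <- as.matrix(expand.grid(rep(list(0:1), N))) # 2^N x N
  LP <- K %*% t(logS) + (1 - K) %*% t(logQ)      # 2^N x G, log P(k | s)
  Pks <- exp(LP)
  Pk <- as.numeric(Pks %*% psw)
  mi_nats <- sum((Pks * LP) %*% psw) - sum(xlogx(Pk))
  ev <- new_channel_evaluation(mi_nats * factor, log_base, "independent", N,
                               quadrature_points = length(quad$s))
  ev
}

#' Spike-count kernel of the lumped-coding channel
#'
#' Probability vector `P(k | N, s)` for the summed count `k = 0, ..., k_max`,
#' built by recursive convolution of per-neuron count distributions
#' (Poisson counts at rate `R` when a neuron is active, a point mass at 0
#' when silent, mixed by the tuning curve `H_i(s)`).
#'
#' @inheritParams mi_independent
#' @param s numeric vector of stimulus values.
#' @param k_max truncation of the summed count; `NULL` (default) picks the
#'   smallest `k` whose Poisson(`N * R`) upper-tail mass is below
#'   `k_tail_tol`.
#' @param k_tail_tol tail-mass tolerance for the automatic `k_max`.
#' @return a `(k_max + 1) x length(s)` matrix; column sums are 1 up to the
#'   truncated tail mass (a warning is raised if the deficit exceeds
#'   `k_tail_tol` by more than a factor of ten).
#' @export
lumped_kernel <- function(thresholds, s, noise, output,
                          k_max = NULL, k_tail_tol = 1e-10) {
  theta <- as_theta(thresholds)
  N <- length(theta)
  R <- output$R
  if (is.null(k_max)) k_max <- poisson_k_max(N * R, k_tail_tol)
  ks <- 0:k_max
  pois <- dpois(ks, R)
  per_neuron <- lapply(theta, function(th) {
    H <- effective_tuning_curve(th, s, noise)
    P <- outer(pois, H)                  # (k_max+1) x G : Poisson part * H
    P[1, ] <- (1 - H) + pois[1] * H      # k = 0 also from the silent state
    P
  })
  T_ <- per_neuron[[1]]
  if (N > 1) for (i in 2:N) {
    P_i <- per_neuron[[i]]
    Tnew <- matrix(0, k_max + 1L, length(s))
    for (k in 0:k_max) {
      j <- 0:k
      Tnew[k + 1L, ] <- colSums(P_i[j + 1L, , drop = FALSE] *
                                T_[k - j + 1L, , drop = FALSE])
    }
    T_ <- Tnew
  }
  deficit <- max(abs(1 - colSums(T_)))
  if (deficit > 10 * k_tail_tol)
    warning(sprintf("lumped kernel truncated mass %.3g exceeds tolerance; increase k_max", deficit))
  T_
}

#' Mutual information of the lumped-coding channel
#'
#' Information between the stimulus and the scalar summed spike count.
#' Always bounded above by [mi_independent()] at the same parameters (the
#' sum is a function of the count vector). With `sigma = 0` the computation
#' is exact over inter-threshold regions.
#'
#' @inheritParams mi_independent
#' @inheritParams lumped_kernel
#' @return a `pc_channel_eval`.
#' @export
mi_lumped <- function(thresholds, stimulus, noise, output,
                      log_base = c("bits", "nats"),
                      control = quadrature_control(),
                      k_max = NULL, k_tail_tol = 1e-10) {
  log_base <- match.arg(log_base)
  factor <- log_base_factor(log_base)
  theta <- as_theta(thresholds)
  N <- length(theta)
  if (N < 1L) stop("at least one neuron is required")
  if (noise$sigma == 0)
    return(mi_lumped_noiseless(theta, stimulus, output, factor, k_tail_tol))
  quad <- build_quadrature(stimulus, theta, rep(noise$sigma, N), control)
  psw <- stimulus_pdf(quad$s, stimulus) * quad$w
  psw <- psw / sum(psw)
  if (is.null(k_max)) k_max <- poisson_k_max(N * output$R, k_tail_tol)
  Pks <- lumped_kernel(theta, quad$s, noise, output,
                       k_max = k_max, k_tail_tol = k_tail_tol)
  Pk <- as.numeric(Pks %*% psw)
  mi_nats <- sum(xlogx(Pks) %*% psw) - sum(xlogx(Pk))
  new_channel_evaluation(mi_nats * factor, log_base, "lumped", N,
                         truncation_k_max = as.integer(k_max),
                         quadrature_points = length(quad$s))
}

#' Channel dispatcher
#'
#' Convenience wrapper calling [mi_independent()] or [mi_lumped()].
#'
#' @inheritParams mi_independent
#' @param channel `"independent"` or `"lumped"`.
#' @param ... passed to the channel-specific function.
#' @return a `pc_channel_eval`.
#' @export
channel_mi <- function(thresholds, channel = c("independent", "lumped"),
                       stimulus, noise, output, log_base = c("bits", "nats"),
                       ...) {
  channel <- match.arg(channel)
  log_base <- match.arg(log_base)
  if (channel == "independent")
    mi_independent(thresholds, stimulus, noise, output, log_base, ...)
  else
    mi_lumped(thresholds, stimulus, noise, output, log_base, ...)
}
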
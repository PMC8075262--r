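# Stimulus / noise model constructors and the generalized normal density.
#
# Everything downstream works on a standardized stimulus axis: the stimulus
# distribution has mean 0 and unit variance unless the user asks otherwise,
# and input-noise sizes are quoted in stimulus standard deviations. Physical
# units (e.g. dB SPL) are mapped onto this axis by an affine level transform
# kept at the I/O boundary (see `level_transform()` in the anf module).

#' Generalized normal density
#'
#' Density of the generalized normal distribution (GND) with location `mu`,
#' scale `alpha` and shape `beta`:
#' \deqn{p(x) = \frac{\beta}{2\alpha\Gamma(1/\beta)}
#'   e^{-(|x-\mu|/\alpha)^\beta}.}
#' `beta = 2` recovers the Gaussian (with \eqn{\alpha = \sigma\sqrt{2}}),
#' `beta = 1` the Laplace distribution, and `beta -> Inf` approaches the
#' uniform on `mu + c(-alpha, alpha)`.
#'
#' @param x numeric vector of evaluation points.
#' @param alpha positive scale parameter.
#' @param beta positive shape parameter.
#' @param mu location (default 0).
#' @return numeric vector of densities.
#' @seealso [gnd_scale_for_variance()], [gnd_cdf()]
#' @export
#' @examples
#' gnd_pdf(0, alpha = sqrt(2), beta = 2)  # standard normal at 0
gnd_pdf <- function(x, alpha, beta, mu = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive number")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("`beta` must be a single positive number")
  z <- abs(x - mu) / alpha
  exp(log(beta) - log(2 * alpha) - lgamma(1 / beta) - z^beta)
}

#' Generalized normal cumulative distribution function
#'
#' Uses the regularized lower incomplete gamma function:
#' \eqn{F(x) = 1/2 + \mathrm{sign}(x-\mu)\,
#'   \gamma(1/\beta, (|x-\mu|/\alpha)^\beta) / (2\Gamma(1/\beta))}.
#'
#' @inheritParams gnd_pdf
#' @return numeric vector of probabilities.
#' @export
gnd_cdf <- function(x, alpha, beta, mu = 0) {
  if (alpha <= 0 || beta <= 0) stop("`alpha` and `beta` must be positive")
  z <- abs(x - mu) / alpha
  0.5 + sign(x - mu) * pgamma(z^beta, shape = 1 / beta) / 2
}

#' Variance of a generalized normal distribution
#'
#' \deqn{\sigma^2 = \alpha^2\,\Gamma(3/\beta)/\Gamma(1/\beta).}
#'
#' @inheritParams gnd_pdf
#' @return the variance.
#' @export
gnd_variance <- function(alpha, beta) {
  if (alpha <= 0 || beta <= 0) stop("`alpha` and `beta` must be positive")
  alpha^2 * exp(lgamma(3 / beta) - lgamma(1 / beta))
}

#' Scale parameter giving a target variance
#'
#' Inverts the GND variance relation for `alpha` at fixed shape `beta`.
#'
#' @param beta positive shape parameter.
#' @param variance positive target variance.
#' @return the scale `alpha` such that the GND with (`alpha`, `beta`) has
#'   the requested variance.
#' @export
#' @examples
#' gnd_scale_for_variance(2, 1)  # sqrt(2): the standard normal
gnd_scale_for_variance <- function(beta, variance) {
  if (beta <= 0) stop("`beta` must be positive")
  if (!is.numeric(variance) || variance <= 0) stop("`variance` must be positive")
  sqrt(variance * exp(lgamma(1 / beta) - lgamma(3 / beta)))
}

#' Stimulus distribution model
#'
#' The scalar stimulus is drawn from a symmetric unimodal distribution,
#' Gaussian by default or generalized normal when heavier or lighter tails
#' are wanted. The distribution is parameterized by its variance; for the
#' GND the scale `alpha` is derived from (`beta`, `variance`).
#'
#' @param family `"gaussian"` or `"generalized_normal"`.
#' @param mean location of the stimulus distribution (standardized units).
#' @param variance stimulus variance (default 1, the standardized convention).
#' @param beta GND shape; 2 is Gaussian, ignored for `family = "gaussian"`.
#' @return an object of class `pc_stimulus` with fields `family`, `mean`,
#'   `variance`, `beta`, `alpha`.
#' @export
#' @examples
#' stimulus_model()                                   # standard normal
#' stimulus_model("generalized_normal", beta = 1)     # unit-variance Laplace
stimulus_model <- function(family = c("gaussian", "generalized_normal"),
                           mean = 0, variance = 1, beta = 2) {
  family <- match.arg(family)
  if (variance <= 0) stop("`variance` must be positive")
  if (family == "gaussian") beta <- 2
  if (beta <= 0) stop("`beta` must be positive")
  alpha <- gnd_scale_for_variance(beta, variance)
  structure(list(family = family, mean = mean, variance = variance,
                 beta = beta, alpha = alpha),
            class = "pc_stimulus")
}

#' Stimulus density
#'
#' @param s numeric vector of stimulus values.
#' @param stimulus a [stimulus_model()].
#' @return density values.
#' @export
stimulus_pdf <- function(s, stimulus) {
  stopifnot(inherits(stimulus, "pc_stimulus"))
  if (stimulus$family == "gaussian")
    dnorm(s, stimulus$mean, sqrt(stimulus$variance))
  else
    gnd_pdf(s, stimulus$alpha, stimulus$beta, stimulus$mean)
}

#' Stimulus cumulative distribution function
#'
#' @inheritParams stimulus_pdf
#' @return probabilities.
#' @export
stimulus_cdf <- function(s, stimulus) {
  stopifnot(inherits(stimulus, "pc_stimulus"))
  if (stimulus$family == "gaussian")
    pnorm(s, stimulus$mean, sqrt(stimulus$variance))
  else
    gnd_cdf(s, stimulus$alpha, stimulus$beta, stimulus$mean)
}

#' Stimulus quantile function
#'
#' Inverts [stimulus_cdf()]; used e.g. for quantile-based starting points of
#' the threshold optimizer.
#'
#' @param p probabilities.
#' @param stimulus a [stimulus_model()].
#' @return quantiles.
#' @export
stimulus_quantile <- function(p, stimulus) {
  stopifnot(inherits(stimulus, "pc_stimulus"))
  if (stimulus$family == "gaussian")
    return(qnorm(p, stimulus$mean, sqrt(stimulus$variance)))
  vapply(p, function(pp) {
    if (pp <= 0) return(-Inf)
    if (pp >= 1) return(Inf)
    sd <- sqrt(stimulus$variance)
    uniroot(function(x) gnd_cdf(x, stimulus$alpha, stimulus$beta, stimulus$mean) - pp,
            lower = stimulus$mean - 20 * sd, upper = stimulus$mean + 20 * sd,
            tol = 1e-12)$root
  }, numeric(1))
}

#' Additive input-noise model
#'
#' Zero-mean noise added to the stimulus before the thresholding
#' nonlinearity. Its size is the standard deviation `sigma` in stimulus
#' units; `sigma = 0` is the noiseless limit in which the effective tuning
#' curve is a Heaviside step.
#'
#' @param sigma non-negative noise standard deviation.
#' @param family `"gaussian"` or `"generalized_normal"`.
#' @param beta GND shape of the noise distribution (2 = Gaussian).
#' @return an object of class `pc_input_noise` with fields `family`,
#'   `sigma`, `beta`, `alpha` (`alpha` is `NA` when `sigma = 0`).
#' @export
input_noise <- function(sigma, family = c("gaussian", "generalized_normal"),
                        beta = 2) {
  family <- match.arg(family)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("`sigma` must be a single non-negative number")
  if (family == "gaussian") beta <- 2
  if (beta <= 0) stop("`beta` must be positive")
  alpha <- if (sigma > 0) gnd_scale_for_variance(beta, sigma^2) else NA_real_
  structure(list(family = family, sigma = sigma, beta = beta, alpha = alpha),
            class = "pc_input_noise")
}

#' Poisson output-noise model
#'
#' Spike generation in a coding window of length `delta_t` is Poisson; the
#' noise level is summarized by `R = nu_max * delta_t`, the expected spike
#' count at maximal firing rate. Small `R` means high output noise.
#'
#' @param R positive expected spike count at maximal rate. May be omitted if
#'   both `nu_max` and `delta_t` are given.
#' @param nu_max optional maximal firing rate (Hz).
#' @param delta_t optional coding-window length (s).
#' @return an object of class `pc_output_noise` with fields `R`, `nu_max`,
#'   `delta_t`.
#' @export
#' @examples
#' output_noise(2.5)
#' output_noise(nu_max = 276, delta_t = 0.05)  # R = 13.8
output_noise <- function(R = NULL, nu_max = NULL, delta_t = NULL) {
  if (is.null(R)) {
    if (is.null(nu_max) || is.null(delta_t))
      stop("supply `R` or both `nu_max` and `delta_t`")
    R <- nu_max * delta_t
  } else if (!is.null(nu_max) && !is.null(delta_t) &&
             abs(nu_max * delta_t - R) >= 1e-12) {
    stop("`nu_max * delta_t` must equal `R`")
  }
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("`R` must be a single positive number")
  structure(list(R = R, nu_max = nu_max, delta_t = delta_t),
            class = "pc_output_noise")
}

#' Threshold vector
#'
#' The `N` firing thresholds of the population, stored sorted ascending
#' (the mutual information of both channels is invariant under permutations
#' of the thresholds, so sorting loses nothing). `tol` is the distinctness
#' tolerance used by [count_distinct()].
#'
#' @param theta numeric vector of thresholds (standardized stimulus units).
#' @param tol positive distinctness tolerance (default `1e-3`).
#' @return an object of class `pc_thresholds`.
#' @export
threshold_vector <- function(theta, tol = 1e-3) {
  if (!is.numeric(theta) || length(theta) < 1L || any(!is.finite(theta)))
    stop("`theta` must be a non-empty finite numeric vector")
  if (tol <= 0) stop("`tol` must be positive")
  structure(list(theta = sort(theta), n = length(theta), tol = tol),
            class = "pc_thresholds")
}

as_theta <- function(thresholds) {
  if (inherits(thresholds, "pc_thresholds")) thresholds$theta
  else as.numeric(thresholds)
}

#' Effective tuning curve under input noise
#'
#' Probability that stimulus plus input noise exceeds the threshold,
#' \eqn{H(s) = P(s + z \ge \theta)}. For Gaussian noise this is
#' \eqn{\frac{1}{2}\mathrm{erfc}\!\left(\frac{\theta - s}{\sqrt{2}\sigma}\right)},
#' i.e. a probit sigmoid; for generalized-normal noise it is expressed
#' through the regularized lower incomplete gamma function. With
#' `sigma = 0` the curve is the Heaviside step with the convention
#' `H(theta) = 0.5`.
#'
#' @param theta threshold (scalar).
#' @param s numeric vector of stimulus values.
#' @param noise an [input_noise()] model.
#' @return vector of probabilities in \[0, 1\], non-decreasing in `s`.
#' @export
#' @examples
#' effective_tuning_curve(0, 1, input_noise(1))  # pnorm(1)
effective_tuning_curve <- function(theta, s, noise) {
  stopifnot(inherits(noise, "pc_input_noise"))
  if (noise$sigma == 0) {
    h <- as.numeric(s > theta)
    h[s == theta] <- 0.5
    return(h)
  }
  if (noise$family == "gaussian" || noise$beta == 2)
    return(pnorm((s - theta) / noise$sigma))
  # P(z >= theta - s) for symmetric GND noise = 1 - F(theta - s) = F(s - theta)
  gnd_cdf(s - theta, noise$alpha, noise$beta)
}
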
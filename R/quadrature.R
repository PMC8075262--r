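# Fixed-grid quadrature for the stimulus integrals.
#
# All mutual-information integrands are smooth except on the scale of the
# smallest input-noise sigma, so a composite Simpson rule on a uniform grid
# spanning +/- range_sd stimulus standard deviations is accurate and -- being
# a fixed deterministic rule -- keeps the information a smooth function of
# the thresholds, which the optimizer and the criticality analysis rely on.
# When a sigma is small compared to the base grid spacing, extra uniform
# panels are inserted around each threshold (trapezoid on the merged grid).

#' Quadrature settings
#'
#' @param range_sd half-width of the integration interval in units of
#'   `max(stimulus sd, input-noise sd)` (default 8).
#' @param points odd number of base grid points for the Simpson rule
#'   (default 801).
#' @param refine logical; insert local panels around thresholds whose
#'   input-noise sigma is unresolved by the base grid (default TRUE).
#' @return a list of class `pc_quadrature`.
#' @export
quadrature_control <- function(range_sd = 8, points = 801, refine = TRUE) {
  points <- as.integer(points)
  if (points < 11L) stop("`points` must be at least 11")
  if (points %% 2L == 0L) points <- points + 1L
  structure(list(range_sd = range_sd, points = points, refine = refine),
            class = "pc_quadrature")
}

simpson_weights <- function(n, h) {
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  w * h / 3
}

# Build integration nodes and weights for a given stimulus model, threshold
# set and per-threshold input-noise sigmas. Returns list(s, w) where w
# already contains only the quadrature weights (not the stimulus density).
build_quadrature <- function(stimulus, theta, sigmas, control = quadrature_control()) {
  sd_s <- sqrt(stimulus$variance)
  half <- control$range_sd * max(sd_s, sigmas, na.rm = TRUE)
  lo <- stimulus$mean - half
  hi <- stimulus$mean + half
  n <- control$points
  s <- seq(lo, hi, length.out = n)
  h <- s[2] - s[1]
  need_refine <- control$refine && length(theta) > 0 &&
    any(sigmas > 0 & sigmas < 4 * h)
  if (!need_refine) {
    return(list(s = s, w = simpson_weights(n, h)))
  }
  # merge fine local windows around each under-resolved threshold
  extra <- unlist(lapply(seq_along(theta), function(i) {
    sg <- sigmas[min(i, length(sigmas))]
    if (sg > 0 && sg < 4 * h)
      seq(theta[i] - 10 * sg, theta[i] + 10 * sg, length.out = 201L)
    else numeric(0)
  }))
  s2 <- sort(unique(c(s, extra)))
  s2 <- s2[s2 >= lo & s2 <= hi]
  d <- diff(s2)
  w <- c(d, 0) / 2 + c(0, d) / 2  # trapezoid on the merged, non-uniform grid
  list(s = s2, w = w)
}

log_base_factor <- function(log_base = c("bits", "nats")) {
  log_base <- match.arg(log_base)
  if (log_base == "bits") 1 / log(2) else 1
}

# x * log(x) with the 0 log 0 := 0 convention; keeps dim attributes.
xlogx <- function(x) {
  out <- x
  out[] <- 0
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos])
  out
}
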
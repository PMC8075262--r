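# Shared model objects and independent oracles used across tests.

std_normal <- stimulus_model()

# Brute-force lumped-count kernel: enumerate the full joint count
# distribution of the independent channel (per-neuron mixture of a silent
# state and Poisson(R) counts) and marginalize onto the summed count.
# Deliberately written as plain loops, independent of lumped_kernel().
oracle_lumped_kernel <- function(theta, s, sigma, R, k_max) {
  ks <- 0:k_max
  per <- lapply(theta, function(th) {
    H <- if (sigma == 0) as.numeric(s > th) + 0.5 * (s == th)
         else pnorm((s - th) / sigma)
    p <- dpois(ks, R) * H
    p[1] <- (1 - H) + exp(-R) * H
    p
  })
  out <- numeric(k_max + 1)
  N <- length(theta)
  idx <- do.call(expand.grid, rep(list(ks), N))
  for (row in seq_len(nrow(idx))) {
    k <- sum(idx[row, ])
    if (k <= k_max) {
      p <- prod(vapply(seq_len(N), function(i) per[[i]][idx[row, i] + 1],
                       numeric(1)))
      out[k + 1] <- out[k + 1] + p
    }
  }
  out
}

# Discrete MI oracle for a finite input partition: p_region (input probs)
# and a kernel matrix P[k, region].
oracle_discrete_mi_bits <- function(p_region, kernel) {
  pk <- as.numeric(kernel %*% p_region)
  mi <- 0
  for (j in seq_along(p_region)) for (k in seq_len(nrow(kernel))) {
    p <- kernel[k, j]
    if (p > 0 && p_region[j] > 0)
      mi <- mi + p_region[j] * p * log2(p / pk[k])
  }
  mi
}
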
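# Independent- and lumped-coding channel information.

test_that("silent/active state probabilities behave and normalize", {
  onz <- output_noise(log(2))
  # saturated neuron with R = ln 2: P(no spike) = e^{-ln 2} = 1/2
  p <- spike_state_probs(0, 10, input_noise(0), onz)
  expect_equal(p$Q, 0.5)
  expect_equal(p$S, 0.5)
  # far sub-threshold: silent with certainty
  p <- spike_state_probs(0, -10, input_noise(0), onz)
  expect_equal(p$Q, 1)
  expect_equal(p$S, 0)
  # exact normalization everywhere
  s <- seq(-3, 3, by = 0.1)
  p <- spike_state_probs(0.3, s, input_noise(0.6), output_noise(2.5))
  expect_equal(p$Q + p$S, rep(1, length(s)))
})

test_that("noiseless independent channel reaches capacity and dies at R -> 0", {
  z0 <- input_noise(0)
  tert <- qnorm(c(1 / 3, 2 / 3))
  cap <- mi_independent(tert, std_normal, z0, output_noise(500))
  expect_equal(cap$mi, log2(3), tolerance = 0.01)
  # no spikes, no information
  tiny <- mi_independent(tert, std_normal, z0, output_noise(1e-6))
  expect_lt(tiny$mi, 1e-4)
  tiny_l <- mi_lumped(tert, std_normal, z0, output_noise(1e-6))
  expect_lt(tiny_l$mi, 1e-4)
})

test_that("noiseless independent MI equals a direct partition-channel oracle", {
  # with step tuning curves the channel is exactly a discrete channel over
  # the inter-threshold regions; rebuild it by hand and compare
  theta <- c(-0.8, 0.4)
  R <- 2.5
  p_region <- diff(pnorm(c(-Inf, theta, Inf)))
  q <- exp(-R)
  # states (k1, k2) over regions {below both, middle, above both}
  kernel <- rbind(
    c(1, q, q * q),            # (0,0)
    c(0, 1 - q, (1 - q) * q),  # (1,0)
    c(0, 0, q * (1 - q)),      # (0,1)
    c(0, 0, (1 - q)^2))        # (1,1)
  mi_oracle <- oracle_discrete_mi_bits(p_region, kernel)
  got <- mi_independent(theta, std_normal, input_noise(0), output_noise(R))
  expect_equal(got$mi, mi_oracle, tolerance = 1e-12)
})

test_that("MI is invariant under threshold permutation; sign flip only at low output noise", {
  st <- std_normal
  nz <- input_noise(0.4)
  a <- mi_independent(c(-0.5, 0.2, 1.1), st, nz, output_noise(2))$mi
  expect_equal(mi_independent(c(1.1, -0.5, 0.2), st, nz, output_noise(2))$mi,
               a, tolerance = 1e-12)
  b <- mi_lumped(c(-0.5, 0.2), st, nz, output_noise(2))$mi
  expect_equal(mi_lumped(c(0.2, -0.5), st, nz, output_noise(2))$mi, b,
               tolerance = 1e-12)
  # mirroring the thresholds is exact only when spike generation is nearly
  # deterministic (silent Poisson outputs break the symmetry at small R)
  hiR <- output_noise(30)
  expect_equal(mi_independent(-c(-0.5, 0.2, 1.1), st, nz, hiR)$mi,
               mi_independent(c(-0.5, 0.2, 1.1), st, nz, hiR)$mi,
               tolerance = 1e-9)
  lo <- mi_independent(c(-0.5, 0.2, 1.1), st, nz, output_noise(0.7))$mi
  lo_flip <- mi_independent(-c(-0.5, 0.2, 1.1), st, nz, output_noise(0.7))$mi
  expect_gt(abs(lo - lo_flip), 1e-3)   # genuine asymmetry, not jitter
})

test_that("lumped kernel base cases match closed forms", {
  onz <- output_noise(1.7)
  nz <- input_noise(0.5)
  s <- c(-1, 0.3, 2)
  # N = 1: the kernel is the per-neuron mixture directly
  K <- lumped_kernel(0.2, s, nz, onz, k_max = 30)
  H <- pnorm((s - 0.2) / 0.5)
  direct <- rbind((1 - H) + exp(-1.7) * H,
                  outer(1:30, H, function(k, h) dpois(k, 1.7) * h))
  expect_equal(K, direct, tolerance = 1e-12, ignore_attr = TRUE)
  # N = 2, deep saturation: sum of two Poisson(R) counts
  K2 <- lumped_kernel(c(-0.3, 0.1), 50, nz, onz, k_max = 40)
  expect_equal(as.numeric(K2), dpois(0:40, 2 * 1.7), tolerance = 1e-10)
  # normalization across a stimulus sweep
  K3 <- lumped_kernel(c(-0.6, 0, 0.9), seq(-3, 3, by = 0.5), nz, onz)
  expect_equal(colSums(K3), rep(1, 13), tolerance = 1e-9)
  expect_warning(lumped_kernel(c(-0.3, 0.1), 50, nz, onz, k_max = 3),
                 "truncated")
})

test_that("lumped kernel equals the brute-force marginalization oracle", {
  # 20 random draws, N <= 3, R <= 3, mixed input-noise levels
  set.seed(42)
  for (i in 1:20) {
    N <- sample(1:3, 1)
    theta <- sort(runif(N, -1.5, 1.5))
    sigma <- sample(c(0, 0.3, 0.8), 1)
    R <- runif(1, 0.2, 3)
    s <- runif(1, -2, 2)
    k_max <- 18L
    got <- lumped_kernel(theta, s, input_noise(sigma), output_noise(R),
                         k_max = k_max, k_tail_tol = 1)
    want <- oracle_lumped_kernel(theta, s, sigma, R, k_max)
    expect_equal(as.numeric(got), want, tolerance = 1e-8)
  }
})

test_that("one neuron carries the same information lumped or independent", {
  for (sigma in c(0, 0.5)) for (R in c(0.7, 4)) {
    a <- mi_independent(0.3, std_normal, input_noise(sigma), output_noise(R))$mi
    b <- mi_lumped(0.3, std_normal, input_noise(sigma), output_noise(R))$mi
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("lumping never gains information", {
  set.seed(7)
  for (i in 1:12) {
    N <- sample(2:3, 1)
    theta <- sort(runif(N, -2, 2))
    sigma <- runif(1, 0, 1.2)
    R <- runif(1, 0.3, 6)
    a <- mi_independent(theta, std_normal, input_noise(sigma), output_noise(R))$mi
    b <- mi_lumped(theta, std_normal, input_noise(sigma), output_noise(R))$mi
    expect_gte(a, b - 1e-9)
  }
})

test_that("quadrature at small sigma approaches the exact noiseless path from below", {
  # smoothing the steps destroys information near the thresholds at rate
  # O(sigma), so the small-sigma value must sit just below the exact one
  theta <- c(-0.7, 0.5)
  onz <- output_noise(2.5)
  exact <- mi_independent(theta, std_normal, input_noise(0), onz)$mi
  near <- mi_independent(theta, std_normal, input_noise(0.005), onz)$mi
  expect_lt(near, exact)
  expect_lt(exact - near, 0.01)
  near2 <- mi_independent(theta, std_normal, input_noise(0.001), onz)$mi
  expect_lt(exact - near2, 0.002)
  exact_l <- mi_lumped(theta, std_normal, input_noise(0), onz)$mi
  near_l <- mi_lumped(theta, std_normal, input_noise(0.005), onz)$mi
  expect_lt(near_l, exact_l)
  expect_lt(exact_l - near_l, 0.01)
})

test_that("channel evaluations carry their settings", {
  ev <- mi_lumped(c(-0.5, 0.5), std_normal, input_noise(0.4), output_noise(2))
  expect_s3_class(ev, "pc_channel_eval")
  expect_true(ev$mi >= 0)
  expect_lte(ev$mi, log2(ev$truncation_k_max + 1))
  expect_identical(ev$channel, "lumped")
  ev2 <- mi_independent(c(-0.5, 0.5), std_normal, input_noise(0.4),
                        output_noise(2), log_base = "nats")
  expect_lte(ev2$mi, log(4))
  expect_error(channel_mi(numeric(0), "independent", std_normal,
                          input_noise(0.1), output_noise(1)))
})
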
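# Sigmoid fitting, fiber typing, and the full-count ANF channel.

test_that("noiseless sigmoid samples are recovered to machine-level accuracy", {
  lt <- level_transform()
  levels <- seq(0, 80, by = 4)
  s <- standardize_level(levels, lt)
  truth <- list(r = 20, r_m = 250, theta = 0.3, sigma = 0.45)
  rate <- truth$r + (truth$r_m - truth$r) * pnorm((s - truth$theta) / truth$sigma)
  ft <- fit_sigmoid(levels, rate, lt)
  expect_true(ft$converged)
  expect_equal(ft$r, truth$r, tolerance = 1e-6)
  expect_equal(ft$r_m, truth$r_m, tolerance = 1e-6)
  expect_equal(ft$theta, truth$theta, tolerance = 1e-6)
  expect_equal(ft$sigma, truth$sigma, tolerance = 1e-6)
  expect_false(ft$low_confidence)
})

test_that("degenerate and truncated rate curves are flagged, not fatal", {
  levels <- seq(0, 80, by = 10)
  flat <- fit_sigmoid(levels, rep(120, length(levels)))
  expect_false(flat$converged)
  # curve that never saturates within the sampled range
  s <- standardize_level(levels)
  rising <- 10 + 300 * pnorm((s - 4.5) / 0.4)
  ft <- fit_sigmoid(levels, rising)
  expect_true(!ft$converged || ft$low_confidence)
  expect_error(fit_sigmoid(c(0, 10, 20), c(1, 2, 3)), "5 samples")
})

test_that("noisy recovery across a cohort meets the simulation benchmarks", {
  spec <- cohort_spec(n_fibers = 100, levels_db = seq(0, 76, by = 4),
                      rate_noise_sd = 5, seed = 11)
  coh <- generate_cohort(spec)
  fits <- fit_cohort(coh$curves)
  ok <- fits$converged
  expect_gt(mean(ok), 0.95)
  m <- merge(fits[ok, ], coh$truth, by = "fiber_id", suffixes = c("", ".true"))
  expect_lt(median(abs(m$theta - m$theta.true)), 0.1)
  expect_lt(median(abs(m$sigma - m$sigma.true)), 0.15)
  # structural correlations propagate through the fits
  cc <- cohort_correlations(fits)
  expect_lt(cc["sigma_rho"], 0)
  expect_gt(cc["sigma_theta"], 0)
})

test_that("two-type classification follows the cdf sign rule and recovers clusters", {
  # two hand-built fibers: high rho / narrow sigma vs low rho / broad sigma
  fits <- data.frame(fiber_id = c("a", "b"),
                     rho = c(0.2, 0.03), sigma = c(0.3, 0.55),
                     theta = c(-0.4, 0.6), converged = TRUE)
  cl <- classify_fibers(fits, 2)
  expect_identical(cl$assignments$type, c(1L, 2L))
  # a generated two-cluster cohort: >= 90% agreement with generating labels
  coh <- generate_cohort(cohort_spec(n_fibers = 80, seed = 3))
  fits2 <- fit_cohort(coh$curves)
  cl2 <- classify_fibers(fits2, 2)
  m <- merge(cl2$assignments, coh$truth, by = "fiber_id")
  expect_gte(mean(m$type.x == m$type.y), 0.9)
  # centroid invariant: type 1 has higher rho and narrower sigma
  cen <- cl2$centroids
  expect_gt(cen$rho[1], cen$rho[2])
  expect_lt(cen$sigma[1], cen$sigma[2])
})

test_that("three-type classification orders centroids along the type axis", {
  coh <- generate_cohort(cohort_spec(
    n_fibers = 90,
    type_means = data.frame(rho = c(0.180, 0.087, 0.019),
                            sigma = c(0.328, 0.398, 0.571),
                            theta = c(-0.6, 0.1, 0.8),
                            r_m = c(276, 276, 276)),
    type_sds = data.frame(rho = c(0.03, 0.02, 0.012),
                          sigma = c(0.05, 0.05, 0.07),
                          theta = c(0.25, 0.25, 0.25),
                          r_m = c(40, 40, 40)),
    seed = 5))
  fits <- fit_cohort(coh$curves)
  cl <- classify_fibers(fits, 3)
  cen <- cl$centroids
  expect_true(all(diff(cen$rho) < 0))
  expect_true(all(diff(cen$sigma) > 0))
})

test_that("centroids reproduce supplied cluster means", {
  # fits whose per-type means are exactly the two-type reference values
  fits <- data.frame(
    fiber_id = sprintf("f%02d", 1:8),
    rho = c(0.159 - 0.01, 0.159 + 0.01, 0.159 - 0.02, 0.159 + 0.02,
            0.036 - 0.005, 0.036 + 0.005, 0.036 - 0.01, 0.036 + 0.01),
    sigma = c(0.337 - 0.02, 0.337 + 0.02, 0.337 - 0.01, 0.337 + 0.01,
              0.534 - 0.03, 0.534 + 0.03, 0.534 - 0.015, 0.534 + 0.015),
    theta = rep(c(-0.35, 0.55), each = 4), converged = TRUE)
  cl <- classify_fibers(fits, 2)
  expect_equal(cl$centroids$rho, c(0.159, 0.036), tolerance = 1e-12)
  expect_equal(cl$centroids$sigma, c(0.337, 0.534), tolerance = 1e-12)
})

test_that("full-count channel reduces to the binary channel without spontaneous rate", {
  st <- stimulus_model()
  for (sg in c(0.05, 0.4)) {
    neurons <- anf_neurons(c(0, 0), c(sg, sg))
    a <- mi_anf(c(-0.4, 0.6), neurons, output_noise(3), st)$mi
    b <- mi_independent(c(-0.4, 0.6), st, input_noise(sg), output_noise(3),
                        log_base = "nats")$mi
    expect_equal(a, b, tolerance = 1e-4)
  }
})

test_that("ANF landscape is centrosymmetric up to spontaneous-rate corrections", {
  two <- anf_neurons(c(0.159, 0.036), c(0.337, 0.534))
  on <- output_noise(13.8)
  qc <- quadrature_control(points = 401)
  # near the optima the mirror mismatch is ~4e-4 nats; it grows away from
  # them but stays a small fraction of the information
  for (th in list(c(-0.35, 0.55), c(-1, 0.2), c(0.4, 1.1))) {
    a <- mi_anf(th, two, on, control = qc)$mi
    b <- mi_anf(-th, two, on, control = qc)$mi
    expect_equal(a, b, tolerance = 5e-3)
  }
  expect_equal(mi_anf(c(-0.35, 0.55), two, on, control = qc)$mi,
               mi_anf(c(0.35, -0.55), two, on, control = qc)$mi,
               tolerance = 1e-3)
  # without spontaneous rate the residual asymmetry is only the silent
  # Poisson ambiguity, of order exp(-R)
  z <- anf_neurons(c(0, 0), c(0.3, 0.5))
  expect_equal(mi_anf(c(-0.4, 0.7), z, on, control = qc)$mi,
               mi_anf(c(0.4, -0.7), z, on, control = qc)$mi,
               tolerance = 1e-5)
})

test_that("expected spikes approach the spontaneous floor for huge thresholds", {
  two <- anf_neurons(c(0.159, 0.036), c(0.337, 0.534))
  on <- output_noise(13.8)
  res <- mean_rate_and_info_per_spike(c(12, 12), two, on)
  expect_equal(res$expected_spikes, 13.8 * sum(two$rho), tolerance = 1e-6)
  expect_lt(res$mi, 1e-6)
})

test_that("coarse-to-fine search refines a known quadratic peak", {
  # single neuron: the landscape is unimodal and smooth
  one <- anf_neurons(0.1, 0.4)
  on <- output_noise(5)
  qc <- quadrature_control(points = 201)
  ls <- landscape_search(one, on, coarse_step = 0.5, rounds = 3,
                         control = qc)
  direct <- optimize(function(th) -mi_anf(th, one, on, control = qc)$mi,
                     c(-3, 3), tol = 1e-10)
  expect_equal(ls$global$mi, -direct$objective, tolerance = 1e-6)
  expect_equal(ls$global$theta1, direct$minimum, tolerance = 0.02)
})
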
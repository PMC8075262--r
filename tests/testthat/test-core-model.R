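# Distributions and effective tuning curves.

test_that("generalized normal density matches closed forms and is symmetric", {
  # beta = 2, alpha = sqrt(2): standard normal
  expect_equal(gnd_pdf(0, sqrt(2), 2), 1 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(gnd_pdf(1.3, sqrt(2), 2), dnorm(1.3), tolerance = 1e-12)
  # beta = 1, alpha = 1: Laplace with rate 1, density 1/2 at the mode
  expect_equal(gnd_pdf(0, 1, 1), 0.5, tolerance = 1e-12)
  # symmetry about the mean
  for (beta in c(0.8, 1, 2, 8)) {
    a <- gnd_scale_for_variance(beta, 1)
    d <- c(0.17, 0.9, 2.4)
    expect_equal(gnd_pdf(0.3 + d, a, beta, mu = 0.3),
                 gnd_pdf(0.3 - d, a, beta, mu = 0.3))
  }
  expect_error(gnd_pdf(0, -1, 2), "alpha")
  expect_error(gnd_pdf(0, 1, 0), "beta")
})

test_that("gnd density integrates to one and matches its cdf", {
  for (beta in c(0.8, 1, 2, 8)) {
    a <- gnd_scale_for_variance(beta, 1)
    total <- integrate(function(x) gnd_pdf(x, a, beta), -Inf, Inf,
                       rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
    # cdf consistency at a few points
    for (x0 in c(-1.2, 0, 0.4)) {
      num <- integrate(function(x) gnd_pdf(x, a, beta), -Inf, x0,
                       rel.tol = 1e-10)$value
      expect_equal(gnd_cdf(x0, a, beta), num, tolerance = 1e-8)
    }
  }
})

test_that("variance inversion round-trips and hits the Gaussian case", {
  expect_equal(gnd_scale_for_variance(2, 1), sqrt(2), tolerance = 1e-12)
  # beta = 1: Gamma(3)/Gamma(1) = 2, so alpha^2 * 2 = 1
  expect_equal(gnd_scale_for_variance(1, 1), 1 / sqrt(2), tolerance = 1e-12)
  for (v in c(0.25, 1, 4)) for (beta in c(0.8, 1, 2, 8)) {
    a <- gnd_scale_for_variance(beta, v)
    expect_equal(gnd_variance(a, beta), v, tolerance = 1e-10)
  }
})

test_that("stimulus model exposes a consistent pdf/cdf/quantile triplet", {
  for (st in list(stimulus_model(),
                  stimulus_model("generalized_normal", beta = 1),
                  stimulus_model("generalized_normal", beta = 4,
                                 variance = 2))) {
    expect_equal(integrate(stimulus_pdf, -Inf, Inf, stimulus = st,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
    p <- c(0.1, 1 / 3, 0.5, 0.9)
    q <- stimulus_quantile(p, st)
    expect_equal(stimulus_cdf(q, st), p, tolerance = 1e-8)
  }
  expect_error(stimulus_model(variance = -1), "variance")
})

test_that("effective tuning curve matches the probit oracle and its limits", {
  gn <- input_noise(1)
  expect_equal(effective_tuning_curve(0, 1, gn), pnorm(1), tolerance = 1e-12)
  s <- seq(-3, 3, by = 0.25)
  for (sigma in c(0.3, 1, 2.5)) for (theta in c(-0.7, 0, 1.2)) {
    expect_equal(effective_tuning_curve(theta, s, input_noise(sigma)),
                 pnorm((s - theta) / sigma), tolerance = 1e-12)
    # midpoint and monotonicity
    h <- effective_tuning_curve(theta, s, input_noise(sigma))
    expect_true(all(diff(h) >= 0))
    expect_equal(effective_tuning_curve(theta, theta, input_noise(sigma)), 0.5)
  }
  # noiseless limit is the Heaviside step with H(theta) = 0.5
  z0 <- input_noise(0)
  expect_equal(effective_tuning_curve(0.5, c(0, 0.5, 1), z0), c(0, 0.5, 1))
})

test_that("gnd tuning curve with beta = 2 equals the erfc form", {
  s <- seq(-4, 4, length.out = 41)
  for (sigma in c(0.2, 1, 3)) for (theta in c(-1, 0.4)) {
    gnd2 <- input_noise(sigma, "generalized_normal", beta = 2)
    # force the incomplete-gamma branch by pretending beta is not exactly 2
    h_gamma <- gnd_cdf(s - theta, gnd2$alpha, 2)
    h_erfc <- 0.5 * pracma::erfc((theta - s) / (sqrt(2) * sigma))
    expect_equal(h_gamma, h_erfc, tolerance = 1e-10)
    expect_equal(effective_tuning_curve(theta, s, gnd2), h_erfc,
                 tolerance = 1e-10)
  }
})

test_that("reflection identity holds for symmetric noise", {
  s <- seq(-3, 3, by = 0.5)
  for (nz in list(input_noise(0.7),
                  input_noise(0.7, "generalized_normal", beta = 1.3))) {
    for (theta in c(-0.4, 0.8)) {
      expect_equal(1 - effective_tuning_curve(theta, s, nz),
                   effective_tuning_curve(theta, 2 * theta - s, nz),
                   tolerance = 1e-12)
    }
  }
})

test_that("output noise and threshold containers validate their inputs", {
  expect_equal(output_noise(nu_max = 276, delta_t = 0.05)$R, 13.8)
  expect_error(output_noise(2, nu_max = 100, delta_t = 0.05), "equal")
  expect_error(output_noise(-1), "positive")
  tv <- threshold_vector(c(0.5, -0.5, 0))
  expect_equal(tv$theta, c(-0.5, 0, 0.5))
  expect_error(threshold_vector(numeric(0)))
})
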
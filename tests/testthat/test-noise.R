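test_that("rice_pdf matches closed forms and integrates to one", {
  # Rayleigh limit at A = 0
  expect_equal(rice_pdf(1, A = 0, sigma = 1), exp(-0.5), tolerance = 1e-12)
  # quadrature oracle: density integrates to 1
  for (ps in list(c(0, 1), c(3, 1), c(10, 2))) {
    v <- stats::integrate(function(m) rice_pdf(m, ps[1], ps[2]),
                          0, ps[1] + 10 * ps[2], rel.tol = 1e-9)$value
    expect_equal(v, 1, tolerance = 1e-6)
  }
  # Gaussian regime: at A/sigma = 10 the density is within 1% of the
  # Gaussian approximation centred at sqrt(A^2 + sigma^2)
  A <- 10; s <- 1
  M <- seq(A - 4 * s, A + 4 * s, length.out = 400)
  gauss <- stats::dnorm(M, sqrt(A^2 + s^2), s)
  err <- max(abs(rice_pdf(M, A, s) - gauss))
  expect_lt(err, 0.01 * max(rice_pdf(M, A, s)))
  expect_error(rice_pdf(1, 1, 0), "sigma")
})

test_that("add_rician produces magnitude noise with the Rice statistics", {
  cl <- volume(array(0.5, c(50, 50, 40)), intensity_scale = "unit_0_1")
  # zero field is the identity
  z <- add_rician(cl, sigma_field(0, 0, shape = dim(cl$data)), seed = 1)
  expect_identical(z$data, cl$data)
  # deterministic given the seed, non-negative
  n1 <- add_rician(cl, 0.05, seed = 42)
  n2 <- add_rician(cl, 0.05, seed = 42)
  expect_identical(n1$data, n2$data)
  expect_gte(min(n1$data), 0)
  # background (A = 0): Rayleigh mean sigma*sqrt(pi/2) within 3 SE
  bg <- volume(array(0, c(50, 50, 40)), intensity_scale = "unit_0_1")
  s <- 0.05
  nb <- add_rician(bg, s, seed = 7)
  m_theory <- s * sqrt(pi / 2)
  se <- s * sqrt(2 - pi / 2) / sqrt(length(nb$data))
  expect_lt(abs(mean(nb$data) - m_theory), 3 * se)
  # E[M^2] = A^2 + 2 sigma^2 on a constant patch
  expect_equal(mean(n1$data^2), 0.5^2 + 2 * s^2, tolerance = 2e-3)
  # KS against the Rice density oracle
  samp <- as.numeric(n1$data)
  ks <- stats::ks.test(samp, function(q) rice_cdf(q, 0.5, s))
  expect_gt(ks$p.value, 0.01)
  expect_error(add_rician(cl, array(0.05, c(2, 2, 2))), "shape")
})

test_that("the variable sigma field triples at the centre and is 1x at the boundary", {
  f <- variable_sigma_field(c(65, 65, 65), 0.09)
  expect_equal(max(f$data), 0.27, tolerance = 1e-12)
  # outermost voxels carry exactly the base sigma
  expect_equal(f$data[1, 1, 1], 0.09)
  expect_true(all(abs(f$data[1, , ] - 0.09) < 1e-12))
  expect_true(all(abs(f$data[, , 65] - 0.09) < 1e-12))
  # centre voxel of the odd grid is exactly 3x
  expect_equal(f$data[33, 33, 33], 0.27)
  expect_true(all(f$data >= 0.09))
  # mirror symmetry about each axis midplane
  expect_equal(f$data, f$data[65:1, , ])
  expect_equal(f$data, f$data[, 65:1, ])
  expect_equal(f$data, f$data[, , 65:1])
  expect_true(all(variable_sigma_field(c(5, 5, 5), 0)$data == 0))
})

test_that("training sigma samplers honor the regime bounds", {
  n <- 2e4
  std <- sample_training_sigma(noise_regime("standard"), seed = 1, n = n)
  expect_true(all(std >= 0 & std <= 0.09))
  expect_lt(min(std), 0.005)
  expect_gt(max(std), 0.085)
  lo <- sample_training_sigma(noise_regime("refine_low"), seed = 2, n = n)
  expect_true(all(lo <= 0.04))
  hi <- sample_training_sigma(noise_regime("refine_high"), seed = 3, n = n)
  expect_true(all(hi >= 0.04 & hi <= 0.09))
  # degenerate uniform
  r <- noise_regime("refine_low"); r$sigma_low <- 0.05; r$sigma_high <- 0.05
  expect_identical(sample_training_sigma(r, 4, 5L), rep(0.05, 5))
  # determinism
  expect_identical(std, sample_training_sigma(noise_regime("standard"), 1, n))
})
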
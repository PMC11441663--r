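test_that("pseudo-error generation degenerates correctly and has the right scale", {
  x <- matrix(rnorm(40), 20, 2)
  expect_identical(add_pseudo_error(x, 0, diag(2)), x)
  expect_identical(add_pseudo_error(x, 0.7, matrix(0, 2, 2)), x)
  expect_error(add_pseudo_error(x, -0.5, diag(2)), ">= 0")

  # added noise at psi = 1 has variance psi * sigma_e
  set.seed(13)
  x1 <- matrix(0, 20000, 1)
  out <- add_pseudo_error(x1, 1, matrix(0.25, 1, 1))
  expect_lt(abs(var(drop(out)) - 0.25) / 0.25, 0.05)
})

test_that("replicate contrasts are centered and normalized exactly", {
  set.seed(17)
  for (n_i in c(2, 3, 5, 9)) {
    cc <- replicate_contrasts(n_i)
    expect_equal(sum(cc), 0, tolerance = 1e-12)
    expect_equal(sum(cc^2), 1, tolerance = 1e-12)
  }
  # two replicates: the contrast is (+-1/sqrt(2), -+1/sqrt(2))
  cc2 <- replicate_contrasts(2)
  expect_equal(abs(cc2), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_error(replicate_contrasts(1), ">= 2")
})

test_that("replicate-contrast surrogates sit on the closed-form two-point line", {
  reps <- list(matrix(c(1, 5), 2, 1), matrix(c(-2, 0), 2, 1))
  expect_equal(replicate_surrogate(reps, 0), matrix(c(3, -1), 2, 1))

  # n_i = 2: output = mean +- sqrt(psi/2) * (a - b)/sqrt(2)
  set.seed(23)
  psi <- 0.8
  out <- replicate_surrogate(reps[1], psi)
  shift <- sqrt(psi / 2) * (1 - 5) / sqrt(2)
  expect_true(min(abs(out[1, 1] - (3 + c(-1, 1) * abs(shift)))) < 1e-12)

  expect_error(replicate_surrogate(list(matrix(1, 1, 1)), 0.5), "n_i >= 2")
})

test_that("replicate-contrast increments have covariance (psi/n_i) sigma_e", {
  set.seed(29)
  n <- 20000
  x <- rnorm(n)
  reps <- lapply(seq_len(n), function(i) matrix(x[i] + rnorm(2, sd = 0.5), 2, 1))
  means <- vapply(reps, mean, numeric(1))
  out <- replicate_surrogate(reps, 1)
  v <- var(drop(out) - means)
  expect_lt(abs(v - 0.125) / 0.125, 0.05)
})

test_that("zero error covariance reproduces the naive fit for polynomial extrapolants", {
  sim <- simulate_mev_data(mev_scenario(n = 300, sigma_e = 0), seed = 5)
  for (fam in c("linear", "quadratic", "cubic")) {
    sx <- simex_propensity(sim$data, sigma_e = matrix(0, 2, 2),
                           control = quick_control(extrapolant = fam))
    expect_lt(max(abs(sx$gamma - sx$naive$gamma)), 1e-6)
  }
})

test_that("px = 0 short-circuits to the naive estimate exactly", {
  sim <- simulate_mev_data(mev_scenario(n = 200, px = 0, pz = 3,
                                        gamma = c(0, 0.5, 0, 0),
                                        beta = c(0.5, 0, 0)),
                           seed = 6)
  sx <- simex_propensity(sim$data, control = quick_control())
  expect_identical(sx$gamma, sx$naive$gamma)
})

test_that("a SIMEX run is bit-reproducible under a fixed seed", {
  sim <- simulate_mev_data(mev_scenario(n = 250), seed = 8)
  a <- simex_propensity(sim$data, sigma_e = 0.25, control = quick_control(seed = 99))
  b <- simex_propensity(sim$data, sigma_e = 0.25, control = quick_control(seed = 99))
  expect_identical(a$estimates, b$estimates)
  expect_identical(a$gamma, b$gamma)
})

test_that("coefficient trajectories attenuate as noise grows", {
  sim <- simulate_mev_data(mev_scenario(), seed = 31)
  sx <- simex_propensity(sim$data, sigma_e = 0.25,
                         control = simex_control(k = 30, seed = 32))
  # attenuation: |gamma_x1(psi)| decreasing in psi (averaged trajectory)
  tr <- sx$estimates[, "x1"]
  expect_lt(tr[length(tr)], tr[1])
  expect_lt(cor(sx$psi, abs(tr)), 0)
  # and extrapolation undoes attenuation: corrected magnitudes exceed naive
  expect_gt(abs(sx$gamma[["x1"]]) + abs(sx$gamma[["x2"]]),
            abs(sx$naive$gamma[["x1"]]) + abs(sx$naive$gamma[["x2"]]))
})

test_that("the psi grid is validated", {
  expect_error(simex_control(psi = c(0.1, 0.5)), "must be 0")
  expect_error(simex_control(psi = c(0, -0.5, 1)), "non-negative|increasing")
  expect_error(simex_control(psi = c(0, 0.5, 0.5)), "increasing")
  expect_error(simex_control(k = 0), "positive")
})
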
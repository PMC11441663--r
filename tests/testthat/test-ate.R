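test_that("IPW estimators reproduce the worked hand examples", {
  expect_equal(ipw_naive(c(3, 1), c(1, 0), c(0.5, 0.5)), 2)
  expect_equal(ipw_naive(rep(0, 4), c(1, 1, 0, 0), rep(0.5, 4)), 0)

  fx <- ipw_fixture()
  expect_equal(ipw_naive(fx$y, fx$t, fx$pi), 0)        # 10/3 - 10/3
  expect_equal(ipw_stabilized(fx$y, fx$t, fx$pi), 0)   # 2.5 - 2.5

  # constant propensity: stabilized IPW is the difference of group means
  expect_equal(ipw_stabilized(c(2, 4, 1, 3), c(1, 1, 0, 0), rep(0.5, 4)), 1)
})

test_that("stabilized weights are normalized and invariant to arm-wise rescaling", {
  set.seed(101)
  for (i in 1:20) {
    n <- 40
    t <- rbinom(n, 1, 0.5)
    if (length(unique(t)) < 2) next
    y <- rnorm(n)
    pi <- runif(n, 0.1, 0.9)
    w1 <- (t / pi) / sum(t / pi)
    w0 <- ((1 - t) / (1 - pi)) / sum((1 - t) / (1 - pi))
    expect_equal(sum(w1), 1, tolerance = 1e-12)
    expect_equal(sum(w0), 1, tolerance = 1e-12)
    expect_equal(ipw_stabilized(y, t, pi), sum(w1 * y) - sum(w0 * y),
                 tolerance = 1e-12)

    # rescaling treated propensities by c rescales the treated weights only:
    # the stabilized estimate is unchanged, the naive one is not
    pi_c <- ifelse(t == 1, pi / 2, pi)
    expect_equal(ipw_stabilized(y, t, pi_c), ipw_stabilized(y, t, pi),
                 tolerance = 1e-12)
    expect_false(isTRUE(all.equal(ipw_naive(y, t, pi_c), ipw_naive(y, t, pi))))
  }
})

test_that("stabilized and naive IPW coincide when arm weights average to one", {
  # constructed so sum(t/pi) = n and sum((1-t)/(1-pi)) = n
  y <- c(5, -1, 2, 0)
  t <- c(1, 1, 0, 0)
  pi <- c(1 / 3, 1, 0.5, 0.5)     # 3 + 1 = 4; 2 + 2... adjust second arm
  pi <- c(1 / 3, 1 - 1e-12, 0.5, 0.5)
  expect_equal(sum(t / pi), 4, tolerance = 1e-9)
  expect_equal(ipw_stabilized(y, t, pi), ipw_naive(y, t, pi), tolerance = 1e-6)
})

test_that("propensities outside (0,1) and empty arms are rejected", {
  expect_error(ipw_naive(1:2, c(1, 0), c(0, 0.5)), "strictly inside")
  expect_error(ipw_stabilized(1:2, c(1, 1), c(0.5, 0.5)), "non-empty")
})

test_that("zero error covariance reduces the SIMEX ATE to plain stabilized IPW", {
  sim <- simulate_mev_data(mev_scenario(n = 400), seed = 15)
  ds <- sim$data
  at <- estimate_ate(ds, support = c(1, 2), sigma_e = matrix(0, 2, 2),
                     control = quick_control())
  w <- build_design(ds)[, c(1, 2, 3)]
  fit <- fit_treatment_model(ds[[2]], w)
  ref <- ipw_stabilized(ds[[1]], ds[[2]], predict_propensity(fit, w))
  expect_lt(abs(at$estimate - ref), 1e-6)
  expect_equal(at$naive_estimate, ref, tolerance = 1e-12)
})

test_that("an empty support yields the difference of arm means", {
  sim <- simulate_mev_data(mev_scenario(n = 300), seed = 16)
  ds <- sim$data
  at <- estimate_ate(ds, support = integer(0), sigma_e = 0.25,
                     control = quick_control())
  y <- ds[[1]]; t <- ds[[2]]
  expect_equal(at$estimate, mean(y[t == 1]) - mean(y[t == 0]), tolerance = 1e-9)
  expect_true(at$naive)
})

test_that("with true propensities and no confounding the estimator is unbiased", {
  # randomized trial: treatment independent of confounders, tau0 = 1
  scen <- mev_scenario(n = 5000, gamma = c(0, 0, 0, 0, 0, 0))
  sim <- simulate_mev_data(scen, seed = 18)
  y <- sim$data[[1]]; t <- sim$data[[2]]
  est <- ipw_stabilized(y, t, sim$truth$propensity)
  mc_se <- sd(y) * sqrt(1 / sum(t) + 1 / sum(1 - t))
  expect_lt(abs(est - 1), 3 * mc_se)
})

test_that("stabilized IPW with true propensities concentrates as n grows", {
  scen_small <- mev_scenario(n = 500)
  scen_big <- mev_scenario(n = 5000)
  err <- function(scen, seeds) {
    vapply(seeds, function(s) {
      sim <- simulate_mev_data(scen, seed = s)
      ipw_stabilized(sim$data[[1]], sim$data[[2]], sim$truth$propensity) - 1
    }, numeric(1))
  }
  e_small <- err(scen_small, 1:40)
  e_big <- err(scen_big, 1:40)
  expect_lt(abs(mean(e_big)), abs(mean(e_small)) + 2 * sd(e_small) / sqrt(40))
  expect_lt(sd(e_big), 0.6 * sd(e_small))
})

test_that("bootstrap inference returns a variance, p-value, and flags degeneracy", {
  sim <- simulate_mev_data(mev_scenario(n = 250), seed = 19)
  bt <- bootstrap_ate(sim$data, support = c(1, 2), sigma_e = 0.25,
                      control = quick_control(k = 3, m = 4), b = 8)
  expect_gt(bt$variance, 0)
  expect_true(bt$p_value >= 0 && bt$p_value <= 1)
  expect_equal(bt$n_bootstrap, 8L)
  expect_false(bt$degenerate)
  # p-value is the declared two-sided normal tail
  expect_equal(bt$p_value,
               2 * pnorm(abs(bt$estimate) / sqrt(bt$variance), lower.tail = FALSE))

  # degenerate outcome: all bootstrap estimates identical -> flagged, not NaN
  degen <- sim$data
  degen[[1]] <- 1
  dd <- causal_data(degen, px = 2)
  expect_warning(
    bt0 <- bootstrap_ate(dd, support = integer(0), sigma_e = 0.25,
                         control = quick_control(k = 2, m = 3), b = 5),
    "degenerate|zero"
  )
  expect_true(bt0$degenerate)
  expect_true(is.na(bt0$p_value))
})

test_that("the full pipeline composes its stages and is deterministic", {
  sim <- simulate_mev_data(mev_scenario(n = 300), seed = 20)
  ctrl <- quick_control(seed = 77, k = 4, m = 4)
  fit <- ate_pipeline(sim$data, sigma_e = 0.25, control = ctrl,
                      penalty = "scad", tuning = "bic", b = 5)
  fit2 <- ate_pipeline(sim$data, sigma_e = 0.25, control = ctrl,
                       penalty = "scad", tuning = "bic", b = 5)
  expect_identical(glance(fit), glance(fit2))
  expect_identical(fit$simex$gamma, fit2$simex$gamma)

  # manual composition agrees
  sx <- simex_propensity(sim$data, sigma_e = 0.25, control = ctrl)
  expect_identical(fit$simex$gamma, sx$gamma)
  sel <- select_gamma(sx$gamma, v = information_weights(sim$data, sx),
                      penalty = "scad", tuning = "bic", n = 300)
  expect_identical(fit$selection$support, sel$support)

  # full-model mode skips selection
  full <- ate_pipeline(sim$data, sigma_e = 0.25, control = ctrl,
                       b = 0, select = FALSE)
  expect_null(full$selection)
  expect_equal(full$ate$support, 1:5)
})

test_that("px = 0 pipelines run the classic IPW-with-selection workflow", {
  scen <- mev_scenario(n = 300, px = 0, pz = 3, gamma = c(0, 0.8, 0, 0),
                       beta = c(0.5, 0, 0))
  sim <- simulate_mev_data(scen, seed = 21)
  fit <- ate_pipeline(sim$data, control = quick_control(), b = 0,
                      penalty = "lasso", tuning = "bic")
  expect_identical(fit$simex$gamma, fit$simex$naive$gamma)
  expect_true(fit$ate$naive)
  expect_true(is.finite(fit$ate$estimate))
})
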
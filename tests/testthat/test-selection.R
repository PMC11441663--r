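test_that("penalty values and derivatives match their closed forms", {
  expect_equal(penalty_value(2, 0.5, "lasso"), 1.0)
  expect_equal(penalty_value(2, 0.5, "elastic_net", alpha = 0), 2.0)
  expect_equal(penalty_value(5, 1, "mcp", a = 3), 1.5)          # saturated at a lam^2 / 2
  expect_equal(penalty_value(10, 1, "scad", a = 3.7), (3.7 + 1) / 2)  # plateau

  lam <- 0.8
  expect_equal(penalty_derivative(0.5 * lam, lam, "scad"), lam)
  expect_equal(penalty_derivative(2 * lam, lam, "scad", a = 3.7), 1.7 / 2.7 * lam)
  expect_equal(penalty_derivative(3 * lam, lam, "mcp", a = 3), 0)
  expect_equal(penalty_derivative(0.2, 0.5, "mcp", a = 3), 0.5 - 0.2 / 3)

  # value is the integral of the derivative (numeric check on a fine grid)
  for (pen in c("scad", "mcp")) {
    u <- seq(0, 5, by = 1e-4)
    num <- cumsum(penalty_derivative(u, 1, pen)) * 1e-4
    expect_lt(max(abs(num - penalty_value(u, 1, pen))), 2e-3)
  }
})

test_that("threshold maps equal the published closed forms and the grid oracle", {
  expect_equal(threshold_penalized(1.0, 0.3, "lasso"), 0.7)
  expect_equal(threshold_penalized(0.25, 0.3, "lasso"), 0)
  expect_equal(threshold_penalized(5, 1, "scad", a = 3.7), 5)   # beyond a*lam: unshrunk

  set.seed(71)
  for (i in 1:60) {
    z <- runif(1, -4, 4)
    lam <- runif(1, 0.05, 1.5)
    pen <- sample(c("lasso", "scad", "mcp"), 1)
    closed <- switch(pen,
      lasso = soft_threshold(z, lam),
      scad = scad_threshold(z, lam),
      mcp = mcp_threshold(z, lam)
    )
    ours <- threshold_penalized(z, lam, pen)
    expect_equal(ours, closed, tolerance = 1e-10, info = paste(pen, i))
    expect_lt(abs(ours - grid_threshold(z, lam, pen)), 1e-4)
  }
})

test_that("the penalized minimizer reduces to componentwise thresholds at V = I", {
  set.seed(73)
  for (i in 1:10) {
    p1 <- sample(3:7, 1)
    gt <- rnorm(p1)
    lam <- runif(1, 0.1, 1)
    pen <- sample(c("lasso", "scad", "mcp"), 1)
    sol <- minimize_penalized_loss(gt, diag(p1), lam, pen)
    expect_equal(sol[1], gt[1], tolerance = 1e-10)   # intercept untouched
    expect_equal(sol[-1], threshold_penalized(gt[-1], lam, pen),
                 tolerance = 1e-10, info = paste(pen, i))
  }
  # lambda = 0 returns gamma_tilde exactly
  gt <- c(1, -2, 0.3)
  expect_identical(minimize_penalized_loss(gt, diag(3), 0, "lasso"), gt)
})

test_that("solutions for general PSD V are global minimizers (objective oracle)", {
  set.seed(79)
  obj <- function(g, gt, v, lam, pen) {
    drop(t(g - gt) %*% v %*% (g - gt)) / 2 +
      sum(penalty_value(abs(g[-1]), lam, pen))
  }
  for (i in 1:5) {
    a <- matrix(rnorm(36), 6)
    v <- crossprod(a) / 6 + diag(6) * 0.1
    gt <- rnorm(6)
    lam <- 0.2
    sol <- minimize_penalized_loss(gt, v, lam, "lasso")
    f0 <- obj(sol, gt, v, lam, "lasso")
    for (j in 1:200) {
      pert <- sol + rnorm(6, sd = sample(c(0.001, 0.05, 0.5), 1))
      expect_gte(obj(pert, gt, v, lam, "lasso"), f0 - 1e-10)
    }
    # and against optim from multiple starts
    ref <- optim(gt, obj, gt = gt, v = v, lam = lam, pen = "lasso",
                 method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
    expect_lte(f0, ref$value + 1e-6)
  }
})

test_that("solutions are exactly sparse and the lasso zero set grows with lambda", {
  set.seed(83)
  gt <- c(0.5, rnorm(6))
  lams <- seq(0.05, 2, length.out = 20)
  prev_zero <- integer(0)
  for (lam in lams) {
    sol <- minimize_penalized_loss(gt, diag(7), lam, "lasso")
    zero <- which(sol[-1] == 0)          # hard zeros, not small numbers
    expect_true(all(prev_zero %in% zero))
    prev_zero <- zero
  }
  expect_equal(prev_zero, which(abs(gt[-1]) < 2))
})

test_that("SCAD and MCP leave large coefficients unshrunk (near-unbiasedness)", {
  gt <- c(0, 5, -4.5, 0.1)
  for (pen in c("scad", "mcp")) {
    sol <- minimize_penalized_loss(gt, diag(4), 0.5, pen)
    expect_equal(sol[2:3], gt[2:3], tolerance = 1e-10, info = pen)
    expect_equal(sol[4], 0, info = pen)
  }
})

test_that("BIC tuning picks the sparser model in the worked example", {
  # gamma_tilde = (1, 0.01): zeroing the 0.01 coefficient costs 2l = 1e-4,
  # far below the 2 log(100) df saving, so lambda = 10 must win
  sel <- select_gamma(c(1, 0.01), v = diag(2), penalty = "lasso",
                      tuning = "bic", n = 100, lambda_grid = c(0.001, 10))
  expect_equal(sel$lambda, 10)
  expect_equal(sel$support, integer(0))
  expect_equal(sel$gamma[1], 1)          # intercept never penalized

  # hand check of both BIC values
  expect_equal(sel$path$criterion[sel$path$lambda == 10],
               2 * (0.01^2 / 2) + 2 * log(100) * 1)
  expect_equal(sel$path$criterion[sel$path$lambda == 0.001],
               2 * (0.001^2 / 2) + 2 * log(100) * 2)

  one <- select_gamma(c(1, 0.5), v = diag(2), tuning = "bic", n = 50,
                      lambda_grid = 0.2)
  expect_equal(one$lambda, 0.2)
})

test_that("model size decreases weakly along the lambda path", {
  set.seed(89)
  for (i in 1:5) {
    gt <- c(rnorm(1), rnorm(8))
    sel <- select_gamma(gt, v = diag(9), penalty = "lasso", tuning = "bic", n = 500)
    expect_true(all(diff(sel$path$df) >= 0))   # path is decreasing in lambda
  }
})

test_that("CV tuning is mechanically sound", {
  # identity V: the pseudo-regression factor is the identity
  expect_equal(unname(simexipw:::sigma_sqrt(diag(3))), diag(3))

  set.seed(97)
  gt <- c(0.5, rnorm(5, sd = 0.1))
  sel <- select_gamma(gt, v = diag(6), penalty = "lasso", tuning = "cv", folds = 3)
  expect_s3_class(sel, "confounder_selection")
  expect_true(sel$lambda %in% sel$path$lambda)
  expect_true(all(sel$path$criterion >= 0))

  expect_error(select_gamma(gt, v = diag(6), tuning = "cv", folds = 7),
               "cannot exceed")
  expect_error(select_gamma(gt, v = diag(6), tuning = "cv", folds = 1), ">= 2")
  expect_error(select_gamma(gt, v = diag(6), tuning = "bic"), "sample size")
})

test_that("penalty hyperparameters are validated", {
  expect_error(penalty_value(1, 1, "scad", a = 2), "a > 2")
  expect_error(penalty_value(1, 1, "mcp", a = 1), "a > 1")
  expect_error(penalty_value(1, 1, "elastic_net", alpha = 1.2), "alpha")
  expect_error(minimize_penalized_loss(c(1, 1), matrix(c(1, 2, 2, 1), 2), 0.1, "lasso"),
               "semidefinite")
})
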
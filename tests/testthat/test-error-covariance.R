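test_that("replicate-based covariance matches the hand-computed moment formula", {
  # one subject, replicates (1, 3): mean 2, scatter (1 + 1)/(2 - 1) = 2
  em <- sigma_e_from_replicates(list(matrix(c(1, 3), 2, 1)))
  expect_equal(unname(em$sigma_e), matrix(2, 1, 1))
  expect_equal(em$provenance, "replicates")
  expect_false(em$psd_repaired)

  # identical replicates everywhere -> zero matrix
  em0 <- sigma_e_from_replicates(list(matrix(c(5, 5), 2, 1), matrix(c(2, 2), 2, 1)))
  expect_equal(unname(em0$sigma_e), matrix(0, 1, 1))

  expect_error(sigma_e_from_replicates(list(matrix(1, 1, 1))), "No replicate information")
})

test_that("replicate covariance pools per-subject scatters with (n_i - 1) weights", {
  set.seed(11)
  reps <- replicate(20, matrix(rnorm(6), 3, 2), simplify = FALSE)
  em <- sigma_e_from_replicates(reps)
  manual <- Reduce(`+`, lapply(reps, function(m) cov(m) * (nrow(m) - 1))) /
    sum(vapply(reps, nrow, integer(1)) - 1)
  expect_equal(unname(em$sigma_e), unname(manual), tolerance = 1e-12)
})

test_that("replicate covariance is unbiased in a Monte-Carlo experiment", {
  set.seed(21)
  n <- 5000
  x <- rnorm(n)
  reps <- lapply(seq_len(n), function(i) matrix(x[i] + rnorm(2, sd = 0.5), 2, 1))
  em <- sigma_e_from_replicates(reps)
  expect_lt(abs(em$sigma_e[1, 1] - 0.25) / 0.25, 0.05)
})

test_that("validation-based covariance recovers the error variance by additivity", {
  # surrogates identical to truth -> zero matrix
  x <- matrix(rnorm(40), 20, 2)
  expect_equal(unname(sigma_e_from_validation(validation_sample(x, x))$sigma_e),
               matrix(0, 2, 2))

  set.seed(31)
  m <- 10000
  x <- matrix(rnorm(2 * m), m, 2)
  e <- cbind(rnorm(m, sd = sqrt(0.2)), rnorm(m, sd = sqrt(0.4)))
  em <- sigma_e_from_validation(validation_sample(x, x + e))
  expect_lt(abs(em$sigma_e[1, 1] - 0.2) / 0.2, 0.10)
  expect_lt(abs(em$sigma_e[2, 2] - 0.4) / 0.4, 0.10)
  expect_lt(abs(em$sigma_e[1, 2]), 0.03)
})

test_that("PSD repair truncates negative eigenvalues and flags itself", {
  id <- diag(2)
  r <- repair_psd(id)
  expect_false(r$repaired)
  expect_equal(r$matrix, id)

  r2 <- repair_psd(diag(c(1, -0.1)))
  expect_true(r2$repaired)
  expect_equal(r2$matrix, diag(c(1, 0)))

  expect_error(repair_psd(matrix(c(1, 2, 3, 4), 2)), "symmetric")

  # any repaired output admits a (jittered) Cholesky factorization
  set.seed(5)
  for (i in 1:10) {
    a <- matrix(rnorm(9), 3); a <- (a + t(a)) / 2
    fixed <- repair_psd(a)$matrix
    expect_no_error(chol(fixed + 1e-10 * diag(3)))
  }
})

test_that("an indefinite validation difference is repaired loudly", {
  # construct x with larger variance than xstar so the difference is negative
  set.seed(8)
  x <- matrix(rnorm(200, sd = 2), 100, 2)
  xs <- matrix(rnorm(200, sd = 1), 100, 2)
  expect_warning(em <- sigma_e_from_validation(validation_sample(x, xs)),
                 "repaired")
  expect_true(em$psd_repaired)
  expect_true(all(eigen(em$sigma_e, symmetric = TRUE)$values >= -1e-12))
})

test_that("scalar error variances expand to diagonal matrices with provenance", {
  em <- error_model(0.25, px = 3)
  expect_equal(em$sigma_e, diag(0.25, 3))
  expect_equal(em$provenance, "known")
  expect_error(error_model(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})
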
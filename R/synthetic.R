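#' Scenario specification for the synthetic-data generator
#'
#' Describes a data-generating process with the exact structure the estimator
#' assumes: multivariate Gaussian confounders, a link-specified treatment
#' model, potential outcomes composed into the observed outcome, classical
#' additive Gaussian surrogate error on the error-prone confounders, and
#' optional replicates and validation pairs.
#'
#' The default is the benchmark scenario used throughout the test suite:
#' n = 2000 subjects, two error-prone and three error-free confounders,
#' treatment-model coefficients `(0, 0.5, 0.5, 0, 0, 0)` (the two error-prone
#' confounders informative, the three error-free ones spurious), logistic
#' link, linear outcome `Y = T + 0.5 (x1 + z1) + N(0, 1)` so the true ATE is
#' 1, and error covariance `0.25 I`. It exercises selection (true zeros),
#' correction (material attenuation), and ATE recovery at once.
#'
#' @param n Sample size.
#' @param px,pz Numbers of error-prone and error-free confounders.
#' @param gamma True treatment-model coefficients, intercept first
#'   (length `1 + px + pz`).
#' @param link Treatment-model link.
#' @param outcome `"linear"` or `"binary"` outcome model.
#' @param tau0 True ATE of the linear outcome model (`Y(t) = tau0 t +
#'   beta' W + eps`). For the binary model the true ATE is instead computed
#'   by Monte-Carlo integration and recorded in the truth record.
#' @param beta Outcome-model coefficients on `(x..., z...)`.
#' @param sd_y Outcome noise standard deviation (linear model).
#' @param sigma_w Confounder covariance (matrix or scalar common variance).
#' @param sigma_e Measurement-error covariance (matrix or scalar).
#' @param rm Replicate schedule: integer vector of length `px` (0/1 = single
#'   surrogate column, `>= 2` = that many replicate columns).
#' @return A list of class `mev_scenario`.
#' @export
mev_scenario <- function(n = 2000L, px = 2L, pz = 3L,
                         gamma = c(0, 0.5, 0.5, 0, 0, 0),
                         link = c("logistic", "probit", "cloglog"),
                         outcome = c("linear", "binary"),
                         tau0 = 1,
                         beta = c(0.5, 0, 0.5, 0, 0),
                         sd_y = 1,
                         sigma_w = 1,
                         sigma_e = 0.25,
                         rm = rep(0L, px)) {
  link <- match.arg(link)
  outcome <- match.arg(outcome)
  p <- px + pz
  if (length(gamma) != p + 1L) stop("`gamma` must have length 1 + px + pz.", call. = FALSE)
  if (length(beta) != p) stop("`beta` must have length px + pz.", call. = FALSE)
  if (length(rm) != px) stop("`rm` must have length px.", call. = FALSE)
  sw <- if (is.matrix(sigma_w)) sigma_w else diag(sigma_w, p)
  se <- if (is.matrix(sigma_e)) sigma_e else diag(sigma_e, max(px, 1L))
  if (px == 0L) se <- matrix(numeric(0), 0, 0)
  if (!is_symmetric_matrix(sw) || (px > 0 && !is_symmetric_matrix(se))) {
    stop("`sigma_w` and `sigma_e` must be symmetric.", call. = FALSE)
  }
  structure(list(n = as.integer(n), px = as.integer(px), pz = as.integer(pz),
                 gamma = gamma, link = link, outcome = outcome, tau0 = tau0,
                 beta = beta, sd_y = sd_y, sigma_w = sw, sigma_e = se,
                 rm = as.integer(rm)),
            class = "mev_scenario")
}

#' Simulate a dataset from a scenario
#'
#' Draws confounders `W ~ N(0, sigma_w)`, treatment
#' `T | W ~ Bernoulli(g^{-1}(W'gamma))`, potential outcomes from the outcome
#' model composed into the observed outcome `Y = T Y(1) + (1-T) Y(0)`, and
#' surrogates `X* = X + e`, `e ~ N(0, sigma_e)` (independent draws per
#' replicate column). Warns when the realized true propensities fall outside
#' `[0.01, 0.99]` for more than 1% of subjects.
#'
#' @param scenario An [mev_scenario()].
#' @param seed Integer seed; identical seed gives an identical dataset.
#' @return A list with `data` (a `causal_data` tibble in the positional
#'   layout) and `truth` (true ATE, coefficients, treatment-model support,
#'   propensities, true confounders, and potential outcomes).
#' @export
simulate_mev_data <- function(scenario = mev_scenario(), seed = 1L) {
  stopifnot(inherits(scenario, "mev_scenario"))
  set.seed(as.integer(seed))
  n <- scenario$n; px <- scenario$px; pz <- scenario$pz
  p <- px + pz

  w <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = scenario$sigma_w)
  w <- matrix(w, nrow = n)
  pi_true <- link_inverse(drop(cbind(1, w) %*% scenario$gamma), scenario$link)
  trt <- stats::rbinom(n, 1L, pi_true)

  lin <- drop(w %*% scenario$beta)
  if (scenario$outcome == "linear") {
    eps <- stats::rnorm(n, sd = scenario$sd_y)
    y1 <- scenario$tau0 + lin + eps
    y0 <- lin + eps
    tau0 <- scenario$tau0
  } else {
    p1 <- clamp_prob(stats::plogis(scenario$tau0 + lin))
    p0 <- clamp_prob(stats::plogis(lin))
    y1 <- stats::rbinom(n, 1L, p1)
    y0 <- stats::rbinom(n, 1L, p0)
    # true ATE by Monte-Carlo integration over the confounder law
    wmc <- matrix(MASS::mvrnorm(200000, mu = rep(0, p), Sigma = scenario$sigma_w), ncol = p)
    lmc <- drop(wmc %*% scenario$beta)
    tau0 <- mean(stats::plogis(scenario$tau0 + lmc) - stats::plogis(lmc))
  }
  y <- trt * y1 + (1 - trt) * y0

  x_true <- w[, seq_len(px), drop = FALSE]
  z <- w[, px + seq_len(pz), drop = FALSE]

  # surrogate columns: one joint N(0, Sigma_e) error draw per replicate
  # index, shared across confounders, so cross-confounder error correlation
  # is preserved within each replicate
  xcols <- list()
  if (px > 0L) {
    rt <- sigma_sqrt(scenario$sigma_e)
    width <- pmax(scenario$rm, 1L)
    err <- lapply(seq_len(max(width)), function(r) matrix(stats::rnorm(n * px), n) %*% rt)
    for (j in seq_len(px)) {
      for (r in seq_len(width[j])) {
        xcols[[paste0("x", j, if (width[j] > 1L) paste0("_r", r) else "")]] <-
          x_true[, j] + err[[r]][, j]
      }
    }
  }

  dat <- tibble::as_tibble(c(
    list(y = y, t = as.numeric(trt)),
    xcols,
    stats::setNames(lapply(seq_len(pz), function(j) z[, j]), paste0("z", seq_len(pz)))
  ))
  ds <- causal_data(dat, px = px, rm = scenario$rm)

  frac_bad <- mean(pi_true < 0.01 | pi_true > 0.99)
  if (frac_bad > 0.01) {
    warning(sprintf("Positivity: %.1f%% of true propensities outside [0.01, 0.99].",
                    100 * frac_bad), call. = FALSE)
  }

  list(data = ds,
       truth = list(tau0 = tau0, gamma = scenario$gamma,
                    support = which(scenario$gamma[-1L] != 0),
                    propensity = pi_true, x_true = x_true,
                    y1 = y1, y0 = y0, scenario = scenario))
}

#' Simulate an external validation sample for a scenario
#'
#' Independent pairs of true confounder values and surrogates under the same
#' error covariance as the main sample (transportability).
#'
#' @param scenario An [mev_scenario()] with `px >= 1`.
#' @param m Validation-sample size (`>= 2`).
#' @param seed Integer seed.
#' @return A [validation_sample()].
#' @export
make_validation <- function(scenario = mev_scenario(), m = 1000L, seed = 1L) {
  stopifnot(inherits(scenario, "mev_scenario"))
  if (scenario$px < 1L) stop("Validation needs px >= 1.", call. = FALSE)
  m <- as.integer(m)
  if (m < 2L) stop("`m` must be >= 2.", call. = FALSE)
  set.seed(as.integer(seed))
  p <- scenario$px + scenario$pz
  w <- matrix(MASS::mvrnorm(m, mu = rep(0, p), Sigma = scenario$sigma_w), ncol = p)
  x <- w[, seq_len(scenario$px), drop = FALSE]
  rt <- sigma_sqrt(scenario$sigma_e)
  e <- matrix(stats::rnorm(m * scenario$px), m) %*% rt
  validation_sample(x, x + e)
}
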
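#' Fit an extrapolation function to a SIMEX trajectory
#'
#' Fits one of the four working extrapolants to the points
#' \eqn{(\psi, \hat\theta(\psi))}: linear \eqn{\beta_0+\beta_1 u}, quadratic
#' \eqn{\beta_0+\beta_1 u+\beta_2 u^2}, cubic, or rational linear
#' \eqn{\beta_0 + \beta_1/(\beta_2+u)}. Polynomial families use exact least
#' squares; the rational family uses Levenberg–Marquardt nonlinear least
#' squares with starts profiled from a small grid of pole positions.
#'
#' A rational fit falls back to the quadratic (with `fallback_used = TRUE`
#' and a warning) when it fails to converge, when its pole lies on the
#' fitting interval (\eqn{\beta_2 \in (-\max\psi, 0]}), when
#' \eqn{|\beta_2 - 1| < 10^{-6}} (the extrapolation point \eqn{u = -1} would
#' sit at the pole), or when the trajectory is numerically constant.
#'
#' @param psi Numeric grid of non-negative values (length >= number of
#'   coefficients in the family).
#' @param values Trajectory values at `psi`.
#' @param family One of `"quadratic"` (default), `"linear"`,
#'   `"rational_linear"`, `"cubic"`.
#' @return A list of class `extrapolant_fit`: `family`, `coefficients`,
#'   `fitted`, `value_at_minus_one`, `fallback_used`.
#' @examples
#' f <- fit_extrapolant(seq(0, 1, length.out = 10), 1 + 2 * seq(0, 1, length.out = 10))
#' f$value_at_minus_one  # -1
#' @export
fit_extrapolant <- function(psi, values,
                            family = c("quadratic", "linear", "rational_linear", "cubic")) {
  family <- match.arg(family)
  psi <- as.numeric(psi); values <- as.numeric(values)
  if (length(psi) != length(values)) stop("`psi` and `values` lengths differ.", call. = FALSE)
  if (anyNA(psi) || anyNA(values)) stop("Missing values in the trajectory.", call. = FALSE)
  n_coef <- switch(family, linear = 2L, quadratic = 3L, rational_linear = 3L, cubic = 4L)
  if (length(psi) < n_coef) {
    stop(sprintf("Grid of length %d cannot identify a %s fit.", length(psi), family),
         call. = FALSE)
  }

  if (family == "rational_linear") {
    return(fit_rational_linear(psi, values))
  }

  deg <- switch(family, linear = 1L, quadratic = 2L, cubic = 3L)
  basis <- stats::poly(psi, degree = deg, raw = TRUE, simple = TRUE)
  fit <- stats::lm.fit(cbind(1, basis), values)
  beta <- unname(fit$coefficients)
  new_extrapolant_fit(family, beta, fitted = drop(cbind(1, basis) %*% beta),
                      psi = psi, fallback_used = FALSE)
}

new_extrapolant_fit <- function(family, beta, fitted, psi, fallback_used) {
  names(beta) <- paste0("b", seq_along(beta) - 1L)
  structure(list(family = family, coefficients = beta, psi = psi,
                 fitted = fitted,
                 value_at_minus_one = eval_extrapolant(family, beta, -1),
                 fallback_used = fallback_used),
            class = "extrapolant_fit")
}

eval_extrapolant <- function(family, beta, u) {
  beta <- unname(beta)
  switch(family,
    linear = beta[1] + beta[2] * u,
    quadratic = beta[1] + beta[2] * u + beta[3] * u^2,
    cubic = beta[1] + beta[2] * u + beta[3] * u^2 + beta[4] * u^3,
    rational_linear = beta[1] + beta[2] / (beta[3] + u)
  )
}

fit_rational_linear <- function(psi, values) {
  psi_max <- max(psi)
  fallback <- function(msg) {
    warning(sprintf("Rational-linear extrapolant unusable (%s); falling back to quadratic.", msg),
            call. = FALSE)
    out <- fit_extrapolant(psi, values, "quadratic")
    out$fallback_used <- TRUE
    out
  }
  if (stats::sd(values) < 1e-12 * max(1, abs(mean(values)))) {
    return(fallback("constant trajectory"))
  }

  # For a fixed pole position b2, b0 and b1 are linear; profile over a start
  # grid of b2 values and polish with Levenberg-Marquardt.
  profile_fit <- function(b2) {
    basis <- cbind(1, 1 / (b2 + psi))
    cf <- stats::lm.fit(basis, values)$coefficients
    rss <- sum((values - drop(basis %*% cf))^2)
    list(start = c(b0 = unname(cf[1]), b1 = unname(cf[2]), b2 = b2), rss = rss)
  }
  starts <- lapply(psi_max * c(0.25, 0.5, 1, 2, 4, 8), profile_fit)
  starts <- starts[order(vapply(starts, `[[`, numeric(1), "rss"))]

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ b0 + b1 / (b2 + u),
                        data = data.frame(u = psi, v = values),
                        start = as.list(s$start),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) next
    beta <- stats::coef(fit)
    b2 <- beta[["b2"]]
    if (b2 > -psi_max && b2 <= 0) next      # pole on the fitting interval
    if (abs(b2 - 1) < 1e-6) next            # pole at the extrapolation point
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(beta = beta, rss = rss)
  }
  if (is.null(best)) return(fallback("no admissible converged fit"))
  beta <- unname(best$beta)
  new_extrapolant_fit("rational_linear", beta,
                      fitted = beta[1] + beta[2] / (beta[3] + psi),
                      psi = psi, fallback_used = FALSE)
}

#' Evaluate an extrapolant fit, by default at the error-free point
#'
#' @param fit An `extrapolant_fit`.
#' @param u Evaluation point(s); default `-1`, the zero-measurement-error
#'   extrapolation point.
#' @return Numeric vector of extrapolant values.
#' @export
extrapolate_at <- function(fit, u = -1) {
  if (!inherits(fit, "extrapolant_fit")) stop("`fit` must be an extrapolant_fit.", call. = FALSE)
  eval_extrapolant(fit$family, fit$coefficients, u)
}
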
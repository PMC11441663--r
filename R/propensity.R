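#' Inverse link functions for the treatment model
#'
#' Maps the linear predictor to a propensity score under the logistic, probit,
#' or complementary log-log treatment model. Outputs are clamped to
#' `[1e-12, 1 - 1e-12]` so downstream inverse weights stay finite.
#'
#' @param eta Numeric vector of linear-predictor values.
#' @param link One of `"logistic"`, `"probit"`, `"cloglog"`.
#' @return A probability vector of the same length as `eta`.
#' @examples
#' link_inverse(0, "logistic")   # 0.5
#' link_inverse(0, "cloglog")    # 1 - exp(-1)
#' @export
link_inverse <- function(eta, link = c("logistic", "probit", "cloglog")) {
  link <- match.arg(link)
  if (any(!is.finite(eta))) stop("`eta` must be finite.", call. = FALSE)
  p <- switch(link,
    logistic = stats::plogis(eta),
    probit   = stats::pnorm(eta),
    cloglog  = -expm1(-exp(pmin(eta, 700)))
  )
  clamp_prob(p)
}

# First derivative d pi / d eta of the inverse link.
link_mu_eta <- function(eta, link) {
  switch(link,
    logistic = {
      p <- stats::plogis(eta)
      p * (1 - p)
    },
    probit = stats::dnorm(eta),
    cloglog = exp(pmin(eta - exp(pmin(eta, 700)), 700))
  )
}

#' Likelihood score of the treatment model
#'
#' The Bernoulli-likelihood score \eqn{\sum_i S_i(\gamma; W_i)} for the given
#' link: each subject contributes
#' \eqn{(T_i - \pi_i)\,h'(\eta_i) / \{\pi_i(1-\pi_i)\}\, W_i}
#' with \eqn{\pi_i = h(\eta_i)}; for the logistic link this reduces to
#' \eqn{(T_i - \pi_i) W_i}.
#'
#' @param gamma Coefficient vector, intercept first (length `ncol(w)`).
#' @param t Binary treatment vector.
#' @param w Design matrix with leading intercept column (see [build_design()]).
#' @inheritParams link_inverse
#' @return Numeric score vector of length `ncol(w)`.
#' @export
treatment_score <- function(gamma, t, w, link = c("logistic", "probit", "cloglog")) {
  link <- match.arg(link)
  w <- as.matrix(w)
  if (length(gamma) != ncol(w)) stop("length(gamma) must equal ncol(w).", call. = FALSE)
  if (length(t) != nrow(w)) stop("length(t) must equal nrow(w).", call. = FALSE)
  eta <- drop(w %*% gamma)
  p <- link_inverse(eta, link)
  r <- (t - p) * link_mu_eta(eta, link) / (p * (1 - p))
  drop(crossprod(w, r))
}

#' Fit the parametric treatment model by maximum likelihood
#'
#' Solves the score equation by Newton–Raphson with step-halving (Fisher
#' scoring weights), falling back to BFGS on a non-positive-definite
#' information matrix. Convergence is declared when the maximum absolute
#' score component falls below `tol`.
#'
#' @inheritParams treatment_score
#' @param start Optional starting coefficients (warm start).
#' @param tol Score tolerance for convergence (default `1e-8`).
#' @param max_iter Maximum Newton iterations.
#' @return A list of class `treatment_fit`: `gamma` (named coefficients),
#'   `converged`, `iterations`, `max_score`, and the `link`.
#' @export
fit_treatment_model <- function(t, w, link = c("logistic", "probit", "cloglog"),
                                start = NULL, tol = 1e-8, max_iter = 100L) {
  link <- match.arg(link)
  w <- as.matrix(w)
  assert_binary(t)
  if (sum(t) == 0L || sum(t) == length(t)) {
    stop("Both treatment groups must be non-empty.", call. = FALSE)
  }
  bern_newton(t, w, link, start = start, tol = tol, max_iter = max_iter)
}

# Numerically stable Bernoulli log-likelihood per link, as a function of the
# linear predictor only (avoids forming clamped probabilities).
bern_loglik_eta <- function(t, eta, link) {
  switch(link,
    logistic = {
      # sum t*eta - log(1 + exp(eta)), stable for large |eta|
      sum(t * eta) - sum(pmax(eta, 0) + log1p(exp(-abs(eta))))
    },
    probit = sum(stats::pnorm(ifelse(t == 1, eta, -eta), log.p = TRUE)),
    cloglog = {
      ee <- exp(pmin(eta, 700))
      lp1 <- log(pmax(-expm1(-ee), 1e-300))
      sum(t * lp1) - sum((1 - t) * ee)
    }
  )
}

# Lean Newton/Fisher-scoring core shared by the user-facing fitter and the
# SIMEX inner loops (which call it thousands of times per run).
bern_newton <- function(t, w, link, start = NULL, tol = 1e-8, max_iter = 100L) {
  p1 <- ncol(w)
  gamma <- if (is.null(start)) numeric(p1) else as.numeric(start)
  eta <- drop(w %*% gamma)
  ll <- bern_loglik_eta(t, eta, link)
  converged <- FALSE
  iter <- 0L
  max_score <- Inf
  for (iter in seq_len(max_iter)) {
    if (link == "logistic") {
      pr <- stats::plogis(eta)
      r <- t - pr
      wt <- pr * (1 - pr)
    } else {
      pr <- link_inverse(eta, link)
      dmu <- link_mu_eta(eta, link)
      v <- pr * (1 - pr)
      r <- (t - pr) * dmu / v
      wt <- dmu * dmu / v
    }
    score <- drop(crossprod(w, r))
    max_score <- max(abs(score))
    if (max_score < tol) { converged <- TRUE; break }
    info <- crossprod(w * wt, w)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) {
      # singular or non-PD information: quasi-Newton fallback
      opt <- stats::optim(gamma, fn = function(g) -bern_loglik_eta(t, drop(w %*% g), link),
                          gr = function(g) -treatment_score(g, t, w, link),
                          method = "BFGS",
                          control = list(maxit = 500L, reltol = 1e-14))
      gamma <- opt$par
      eta <- drop(w %*% gamma)
      ll <- -opt$value
      next
    }
    # step-halving on the log-likelihood
    d_eta <- drop(w %*% step)
    new_ll <- -Inf
    for (h in 0:25) {
      sc <- 1 / 2^h
      cand_eta <- eta + sc * d_eta
      new_ll <- bern_loglik_eta(t, cand_eta, link)
      if (is.finite(new_ll) && new_ll >= ll - 1e-12) break
    }
    gamma <- gamma + sc * step
    eta <- cand_eta
    ll <- new_ll
  }
  if (!converged) {
    max_score <- max(abs(treatment_score(gamma, t, w, link)))
    converged <- max_score < tol
  }
  if (converged && all(abs(link_inverse(eta, link) - t) < 1e-8)) {
    # every fitted probability is numerically at its observed outcome: the
    # score vanishes along a divergent path (complete separation), so the
    # "root" is not an interior maximum
    converged <- FALSE
  }
  if (!converged) {
    warning(sprintf(
      "Treatment-model fit did not converge (max |score| = %.3g); possible separation.",
      max_score), call. = FALSE)
  }
  names(gamma) <- colnames(w)
  structure(list(gamma = gamma, converged = converged, iterations = iter,
                 max_score = max_score, link = link),
            class = "treatment_fit")
}

#' Predict propensity scores from a fitted (or supplied) coefficient vector
#'
#' @param gamma Coefficient vector (intercept first) or a `treatment_fit`.
#' @param w Design matrix with leading intercept column.
#' @inheritParams link_inverse
#' @return Probability vector of length `nrow(w)`.
#' @export
predict_propensity <- function(gamma, w, link = c("logistic", "probit", "cloglog")) {
  if (inherits(gamma, "treatment_fit")) {
    link <- gamma$link
    gamma <- gamma$gamma
  } else {
    link <- match.arg(link)
  }
  link_inverse(drop(as.matrix(w) %*% gamma), link)
}
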
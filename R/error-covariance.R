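#' Measurement-error covariance with provenance
#'
#' Wraps a `px x px` symmetric matrix together with a record of how it was
#' obtained: user-specified (`"known"`), moment-based from replicate
#' surrogate measurements, or by covariance additivity from an external
#' validation sample. Non-positive-semidefinite inputs are repaired by
#' eigenvalue truncation and flagged.
#'
#' @param sigma_e Symmetric numeric matrix (a scalar is interpreted as that
#'   common variance times the identity of dimension `px`).
#' @param provenance One of `"known"`, `"replicates"`, `"validation"`.
#' @param px Dimension, required only when `sigma_e` is a scalar.
#' @return A list of class `error_model`: `sigma_e`, `provenance`,
#'   `psd_repaired`.
#' @export
error_model <- function(sigma_e, provenance = c("known", "replicates", "validation"),
                        px = NULL) {
  provenance <- match.arg(provenance)
  if (is.numeric(sigma_e) && length(sigma_e) == 1L && !is.matrix(sigma_e)) {
    if (is.null(px)) stop("Scalar `sigma_e` needs `px` to set the dimension.", call. = FALSE)
    sigma_e <- diag(sigma_e, px)
  }
  sigma_e <- as.matrix(sigma_e)
  if (!is_symmetric_matrix(sigma_e)) {
    stop("`sigma_e` must be symmetric (tolerance 1e-10).", call. = FALSE)
  }
  rep <- repair_psd(sigma_e)
  structure(list(sigma_e = rep$matrix, provenance = provenance,
                 psd_repaired = rep$repaired),
            class = "error_model")
}

#' Project a symmetric matrix onto the positive-semidefinite cone
#'
#' Eigen-decomposes the input and truncates negative eigenvalues at zero.
#' Already-PSD inputs are returned unchanged.
#'
#' @param sigma Symmetric numeric matrix.
#' @return A list with `matrix` (the PSD result) and `repaired` (logical).
#' @export
repair_psd <- function(sigma) {
  sigma <- as.matrix(sigma)
  if (!is_symmetric_matrix(sigma)) {
    stop("`sigma` must be symmetric.", call. = FALSE)
  }
  eg <- eigen(sigma, symmetric = TRUE)
  if (all(eg$values >= -1e-12)) {
    return(list(matrix = sigma, repaired = FALSE))
  }
  vals <- pmax(eg$values, 0)
  fixed <- eg$vectors %*% (vals * t(eg$vectors))
  fixed <- (fixed + t(fixed)) / 2
  dimnames(fixed) <- dimnames(sigma)
  list(matrix = fixed, repaired = TRUE)
}

#' Estimate the error covariance from replicate surrogate measurements
#'
#' Method-of-moments estimator: pooled within-subject scatter of the
#' replicates about their subject means, divided by \eqn{\sum_i (n_i - 1)}.
#' Positive semidefinite by construction (a sum of outer products).
#'
#' @param replicates Either a list of per-subject numeric matrices
#'   (`n_i x px`, `n_i >= 1`, at least one subject with `n_i >= 2`) or a
#'   `causal_data` object whose `rm` declares replicate columns.
#' @return An `error_model` with provenance `"replicates"`.
#' @export
sigma_e_from_replicates <- function(replicates) {
  if (inherits(replicates, "causal_data")) {
    replicates <- cd_replicates(replicates)
  }
  if (!is.list(replicates) || length(replicates) == 0L) {
    stop("`replicates` must be a non-empty list of per-subject matrices.", call. = FALSE)
  }
  replicates <- lapply(replicates, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  })
  px <- ncol(replicates[[1L]])
  ni <- vapply(replicates, nrow, integer(1))
  denom <- sum(ni - 1L)
  if (denom < 1L) {
    stop("No replicate information: every subject has a single measurement.", call. = FALSE)
  }
  acc <- matrix(0, px, px)
  for (m in replicates) {
    if (nrow(m) < 2L) next
    dev <- sweep(m, 2L, colMeans(m))
    acc <- acc + crossprod(dev)
  }
  em <- error_model(acc / denom, provenance = "replicates")
  em
}

#' Estimate the error covariance from an external validation sample
#'
#' By additivity of covariances under the classical additive error model,
#' \eqn{\hat\Sigma_e = \hat\Sigma_{X^*} - \hat\Sigma_X}, with both empirical
#' covariances over the validation sample (divisor \eqn{m}). The difference
#' can be indefinite in finite samples; any repair is flagged, never silent.
#'
#' @param val A [validation_sample()].
#' @return An `error_model` with provenance `"validation"`; check
#'   `psd_repaired`.
#' @export
sigma_e_from_validation <- function(val) {
  if (!inherits(val, "validation_sample")) {
    stop("`val` must be a validation_sample.", call. = FALSE)
  }
  m <- val$m
  cov_m <- function(a) {
    dev <- sweep(a, 2L, colMeans(a))
    crossprod(dev) / m
  }
  diff <- cov_m(val$xstar) - cov_m(val$x)
  out <- error_model(diff, provenance = "validation")
  if (out$psd_repaired) {
    warning("Validation-based error covariance was indefinite; repaired by eigenvalue truncation.",
            call. = FALSE)
  }
  out
}
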
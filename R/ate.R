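# Step-5 machinery: IPW estimators on the selected treatment model, the
# SIMEX-extrapolated ATE, bootstrap variance, and the end-to-end pipeline.

#' Inverse-probability-weighted estimators of the average treatment effect
#'
#' `ipw_naive()` is the Horvitz–Thompson form
#' \eqn{n^{-1}\sum T_iY_i/\pi_i - n^{-1}\sum (1-T_i)Y_i/(1-\pi_i)};
#' `ipw_stabilized()` is the Hájek form with weights normalized to sum to one
#' within each treatment arm, which is invariant to rescaling the weights of
#' an arm and robust to extreme propensities.
#'
#' @param y Observed outcome vector.
#' @param t Binary treatment vector.
#' @param pi Fitted propensity scores, strictly inside (0, 1).
#' @return The scalar ATE estimate.
#' @examples
#' ipw_stabilized(c(2, 4, 1, 3), c(1, 1, 0, 0), c(0.25, 0.75, 0.25, 0.75))  # 0
#' @export
ipw_naive <- function(y, t, pi) {
  check_ipw_inputs(y, t, pi)
  n <- length(y)
  sum(t * y / pi) / n - sum((1 - t) * y / (1 - pi)) / n
}

#' @rdname ipw_naive
#' @export
ipw_stabilized <- function(y, t, pi) {
  check_ipw_inputs(y, t, pi)
  if (sum(t) == 0 || sum(t) == length(t)) {
    stop("Both treatment arms must be non-empty.", call. = FALSE)
  }
  w1 <- t / pi
  w0 <- (1 - t) / (1 - pi)
  sum(w1 * y) / sum(w1) - sum(w0 * y) / sum(w0)
}

check_ipw_inputs <- function(y, t, pi) {
  if (length(y) != length(t) || length(y) != length(pi)) {
    stop("`y`, `t`, `pi` must have equal length.", call. = FALSE)
  }
  assert_binary(t)
  if (any(pi <= 0 | pi >= 1)) {
    stop("All propensity scores must lie strictly inside (0, 1).", call. = FALSE)
  }
  invisible(NULL)
}

# Propensity clamp used before weighting; far inside the link_inverse clamp
# so the count is meaningful.
ATE_PI_EPS <- 1e-6

#' SIMEX-extrapolated ATE on the selected treatment model
#'
#' For every (k, psi) the working surrogates are regenerated, the reduced
#' treatment model — intercept plus the selected confounder columns — is
#' refit, and the stabilized IPW estimate is computed; the per-psi averages
#' are extrapolated to \eqn{\psi = -1}. With `px = 0`, or when no selected
#' confounder is error-prone, the estimate is the plain stabilized IPW on the
#' naive reduced fit.
#'
#' @inheritParams simex_propensity
#' @param support Indices (in `1..p`, confounder order of [build_design()]
#'   without the intercept) of the retained confounders, or a
#'   `confounder_selection`. Empty support gives an intercept-only model and
#'   the difference of arm means.
#' @return A list of class `ate_fit`: `estimate`, `psi_trajectory` (tibble of
#'   `psi`, `ate`), `extrapolant_fit`, `n_dropped`, `n_clamped`, `naive`
#'   (logical short-circuit flag).
#' @export
estimate_ate <- function(data, support, px = NULL, rm = NULL, sigma_e = NULL,
                         control = simex_control(), replicate = FALSE,
                         collapse = c("first", "mean")) {
  collapse <- match.arg(collapse)
  ds <- if (inherits(data, "causal_data")) data else causal_data(data, px = px %||% 0L, rm = rm)
  if (inherits(support, "confounder_selection")) support <- support$support
  support <- sort(unique(as.integer(support)))
  pxd <- cd_px(ds)
  p <- pxd + cd_pz(ds)
  if (length(support) > 0L && (min(support) < 1L || max(support) > p)) {
    stop(sprintf("`support` indices must lie in 1..%d.", p), call. = FALSE)
  }

  y <- cd_outcome(ds)
  trt <- cd_treatment(ds)
  w0 <- build_design(ds, collapse = collapse)
  keep <- c(1L, 1L + support)                # intercept + selected columns
  x_sel <- support[support <= pxd]           # selected error-prone confounders

  reduced_ipw <- function(w_red, start = NULL) {
    fit <- fit_treatment_model(trt, w_red, link = control$link, start = start)
    pi_hat <- clamp_prob(predict_propensity(fit$gamma, w_red, control$link), ATE_PI_EPS)
    list(ate = ipw_stabilized(y, trt, pi_hat), fit = fit,
         clamped = sum(pi_hat <= ATE_PI_EPS | pi_hat >= 1 - ATE_PI_EPS))
  }

  naive_red <- reduced_ipw(w0[, keep, drop = FALSE])

  if (pxd == 0L || length(x_sel) == 0L) {
    # nothing error-prone in the final model: plain stabilized IPW
    traj <- tibble::tibble(psi = control$psi, ate = naive_red$ate)
    return(structure(list(estimate = naive_red$ate,
                          naive_estimate = naive_red$ate,
                          psi_trajectory = traj,
                          extrapolant_fit = NULL, n_dropped = 0L,
                          n_clamped = naive_red$clamped, naive = TRUE,
                          support = support, control = control,
                          reduced_fit = naive_red$fit),
                     class = "ate_fit"))
  }

  if (replicate) {
    reps <- cd_replicates(ds)
    em <- NULL
  } else {
    if (is.null(sigma_e)) stop("`sigma_e` is required unless replicate = TRUE.", call. = FALSE)
    em <- if (inherits(sigma_e, "error_model")) sigma_e else error_model(sigma_e, px = pxd)
    xs <- cd_xstar(ds, collapse = collapse)
  }

  psi <- control$psi
  m_grid <- length(psi)
  x_idx <- 1L + seq_len(pxd)
  sums <- numeric(m_grid)
  n_ok <- integer(m_grid)
  n_dropped <- 0L
  n_clamped <- 0L
  for (kk in seq_len(control$k)) {
    for (mm in seq_len(m_grid)) {
      set.seed(substream_seed(control$seed, kk, mm, offset = 1L))
      w <- w0
      w[, x_idx] <- if (replicate) {
        replicate_surrogate(reps, psi[mm])
      } else {
        add_pseudo_error(xs, psi[mm], em)
      }
      res <- tryCatch(
        suppressWarnings(reduced_ipw(w[, keep, drop = FALSE],
                                     start = naive_red$fit$gamma)),
        error = function(e) NULL
      )
      if (is.null(res) || !res$fit$converged) {
        n_dropped <- n_dropped + 1L
      } else {
        sums[mm] <- sums[mm] + res$ate
        n_ok[mm] <- n_ok[mm] + 1L
        n_clamped <- n_clamped + res$clamped
      }
    }
  }
  if (n_dropped > control$drop_max * control$k * m_grid || any(n_ok == 0L)) {
    stop(sprintf("Too many failed reduced-model fits: %d of %d.",
                 n_dropped, control$k * m_grid), call. = FALSE)
  }
  traj <- sums / n_ok
  efit <- fit_extrapolant(psi, traj, control$extrapolant)

  structure(list(estimate = efit$value_at_minus_one,
                 naive_estimate = naive_red$ate,
                 psi_trajectory = tibble::tibble(psi = psi, ate = traj),
                 extrapolant_fit = efit, n_dropped = n_dropped,
                 n_clamped = n_clamped, naive = FALSE, support = support,
                 control = control, reduced_fit = naive_red$fit),
            class = "ate_fit")
}

#' Bootstrap variance and p-value for the SIMEX-corrected ATE
#'
#' Draws `b` row-resampled datasets (with replacement, size n; a subject's
#' replicate columns travel with its row), re-runs [estimate_ate()] on each
#' with the selected support held fixed, and reports the sample variance of
#' the bootstrap estimates together with a two-sided p-value from the normal
#' reference \eqn{2\{1-\Phi(|\hat\tau|/\sqrt{\widehat{var}})\}}. Keeping the
#' support fixed matches a workflow where selection is done once on the
#' original sample; it understates model-selection variability.
#'
#' @inheritParams estimate_ate
#' @param b Number of bootstrap resamples (`>= 2`).
#' @return A list of class `ate_boot`: `estimate`, `variance`, `p_value`,
#'   `n_bootstrap`, `degenerate` (TRUE when the bootstrap variance is zero,
#'   in which case `p_value` is `NA`), `reference` (`"normal"`), and the
#'   original `ate_fit`.
#' @export
bootstrap_ate <- function(data, support, px = NULL, rm = NULL, sigma_e = NULL,
                          control = simex_control(), replicate = FALSE,
                          collapse = c("first", "mean"), b = 100L) {
  collapse <- match.arg(collapse)
  b <- as.integer(b)
  if (b < 2L) stop("`b` must be >= 2.", call. = FALSE)
  ds <- if (inherits(data, "causal_data")) data else causal_data(data, px = px %||% 0L, rm = rm)
  point <- estimate_ate(ds, support, sigma_e = sigma_e, control = control,
                        replicate = replicate, collapse = collapse)

  n <- nrow(ds)
  trt <- cd_treatment(ds)
  est <- numeric(b)
  for (bb in seq_len(b)) {
    idx <- NULL
    for (try in seq_len(10L)) {
      set.seed(substream_seed(control$seed, 0L, try, offset = 7919L + bb))
      cand <- sample.int(n, n, replace = TRUE)
      if (length(unique(trt[cand])) == 2L) { idx <- cand; break }
    }
    if (is.null(idx)) {
      stop("Could not draw a bootstrap resample with both treatment arms after 10 tries.",
           call. = FALSE)
    }
    ds_b <- causal_data(tibble::as_tibble(ds)[idx, , drop = FALSE],
                        px = cd_px(ds), rm = cd_rm(ds))
    ctrl_b <- control
    ctrl_b$seed <- substream_seed(control$seed, 0L, 0L, offset = 104729L + bb)
    est[bb] <- estimate_ate(ds_b, support, sigma_e = sigma_e, control = ctrl_b,
                            replicate = replicate, collapse = collapse)$estimate
  }
  variance <- stats::var(est)
  degenerate <- !is.finite(variance) || variance <= 0
  p_value <- if (degenerate) NA_real_ else {
    2 * stats::pnorm(abs(point$estimate) / sqrt(variance), lower.tail = FALSE)
  }
  if (degenerate) {
    warning("Bootstrap variance is zero or undefined; p-value not available.", call. = FALSE)
  }
  structure(list(estimate = point$estimate, variance = variance,
                 p_value = p_value, n_bootstrap = b, degenerate = degenerate,
                 reference = "normal", boot_estimates = est, ate_fit = point),
            class = "ate_boot")
}

#' Full estimation pipeline: correction, selection, weighting, bootstrap
#'
#' Runs the five-step procedure end to end: SIMEX correction of the
#' treatment-model coefficients ([simex_propensity()]), penalized confounder
#' selection on the corrected coefficients ([select_gamma()]), and the
#' SIMEX-extrapolated stabilized-IPW estimate of the ATE with bootstrap
#' variance ([bootstrap_ate()]). `select = FALSE` skips the selection step
#' and keeps the full model (all confounders).
#'
#' By default the selection loss is weighted by the observed information of
#' the naive treatment-model fit, which makes the quadratic loss a bona fide
#' likelihood approximation and the BIC comparison meaningful; pass
#' `v = "identity"` for an unweighted loss.
#'
#' @inheritParams simex_propensity
#' @inheritParams select_gamma
#' @param v Selection weight matrix: `"information"` (default),
#'   `"identity"`, or an explicit matrix.
#' @param b Number of bootstrap resamples; `0` skips the bootstrap.
#' @param select Run the selection step? `FALSE` keeps all confounders.
#' @return A list of class `simexipw_fit` with elements `simex`
#'   (`simex_fit`), `selection` (`confounder_selection` or `NULL`), `ate`
#'   (`ate_fit`), `boot` (`ate_boot` or `NULL`), plus the call parameters.
#' @export
ate_pipeline <- function(data, px = NULL, rm = NULL, sigma_e = NULL,
                         control = simex_control(), replicate = FALSE,
                         collapse = c("first", "mean"),
                         penalty = "scad", tuning = "bic",
                         v = c("information", "identity"),
                         folds = 5L, a = NULL, alpha = 1,
                         b = 100L, select = TRUE) {
  collapse <- match.arg(collapse)
  ds <- if (inherits(data, "causal_data")) data else causal_data(data, px = px %||% 0L, rm = rm)

  sx <- simex_propensity(ds, sigma_e = sigma_e, control = control,
                         replicate = replicate, collapse = collapse)

  p <- cd_px(ds) + cd_pz(ds)
  if (select) {
    v_mat <- if (is.character(v)) {
      v <- match.arg(v)
      if (v == "identity") diag(p + 1L) else naive_information(ds, sx, collapse)
    } else as.matrix(v)
    sel <- select_gamma(sx$gamma, v = v_mat, penalty = penalty, tuning = tuning,
                        n = nrow(ds), folds = folds, a = a, alpha = alpha)
    support <- sel$support
  } else {
    sel <- NULL
    support <- seq_len(p)
  }

  if (b > 0L) {
    boot <- bootstrap_ate(ds, support, sigma_e = sigma_e, control = control,
                          replicate = replicate, collapse = collapse, b = b)
    ate <- boot$ate_fit
  } else {
    boot <- NULL
    ate <- estimate_ate(ds, support, sigma_e = sigma_e, control = control,
                        replicate = replicate, collapse = collapse)
  }

  structure(list(simex = sx, selection = sel, ate = ate, boot = boot,
                 control = control, penalty = penalty, tuning = tuning,
                 select = select),
            class = "simexipw_fit")
}

#' Information-based selection weight matrix
#'
#' Observed (Fisher) information of the naive treatment-model fit on the
#' working design. Used as the default weight `V_n` of the penalized
#' selection loss in [ate_pipeline()]: it turns the quadratic loss into the
#' second-order approximation of the treatment-model log-likelihood around
#' the fit, which puts the loss and the `log(n)` model-size term of the BIC
#' on the same scale.
#'
#' @param data A `causal_data` object (or data frame plus `px`/`rm`).
#' @param fit A `simex_fit` (for its naive fit and link), or a
#'   `treatment_fit`.
#' @inheritParams simex_propensity
#' @return A `(p+1) x (p+1)` positive-semidefinite matrix.
#' @export
information_weights <- function(data, fit, px = NULL, rm = NULL,
                                collapse = c("first", "mean")) {
  collapse <- match.arg(collapse)
  ds <- if (inherits(data, "causal_data")) data else causal_data(data, px = px %||% 0L, rm = rm)
  tf <- if (inherits(fit, "simex_fit")) fit$naive else fit
  stopifnot(inherits(tf, "treatment_fit"))
  w <- build_design(ds, collapse = collapse)
  eta <- drop(w %*% tf$gamma)
  pr <- link_inverse(eta, tf$link)
  dmu <- link_mu_eta(eta, tf$link)
  crossprod(w * (dmu^2 / (pr * (1 - pr))), w)
}

naive_information <- function(ds, sx, collapse) {
  information_weights(ds, sx, collapse = collapse)
}

#' @export
print.ate_boot <- function(x, ...) {
  cat("SIMEX-corrected stabilized-IPW ATE\n")
  cat(sprintf("  estimate = %.6g\n  variance = %.6g (bootstrap, B = %d)\n",
              x$estimate, x$variance, x$n_bootstrap))
  cat(sprintf("  p-value  = %s (two-sided %s reference)\n",
              ifelse(is.na(x$p_value), "NA (degenerate)", format.pval(x$p_value)),
              x$reference))
  invisible(x)
}

#' @export
print.ate_fit <- function(x, ...) {
  cat("SIMEX-corrected stabilized-IPW ATE\n")
  cat(sprintf("  estimate = %.6g\n", x$estimate))
  if (x$naive) cat("  (no error-prone confounder in the final model; plain stabilized IPW)\n")
  invisible(x)
}

#' @export
print.simexipw_fit <- function(x, ...) {
  cat("Five-step SIMEX-corrected IPW pipeline\n")
  cat("  corrected coefficients:\n")
  print(round(x$simex$gamma, 4))
  if (!is.null(x$selection)) {
    cat("  selected confounders:",
        if (length(x$selection$support)) paste(x$selection$support, collapse = ", ")
        else "(none)", "\n")
  } else cat("  selection skipped (full model)\n")
  if (!is.null(x$boot)) print(x$boot) else print(x$ate)
  invisible(x)
}
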
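#' SIMEX configuration
#'
#' Collects the tuning constants of the simulation-extrapolation procedure.
#' Defaults follow common practice for this estimator: `k = 200` simulated
#' surrogate sets per grid point and a grid of 10 equally spaced values on
#' `[0, 1]` whose first element is 0.
#'
#' @param psi Increasing grid of non-negative noise-inflation factors; the
#'   first element must be 0.
#' @param k Number of simulated surrogate sets per grid point.
#' @param extrapolant Extrapolation family (see [fit_extrapolant()]).
#' @param link Treatment-model link (see [link_inverse()]).
#' @param seed Master seed for the simulation; per-(k, psi) substreams are
#'   derived deterministically in k-major order, so changing `k` or the grid
#'   does not reshuffle unrelated draws.
#' @param drop_max Maximum tolerated fraction of failed per-(k, psi) fits;
#'   failures beyond this are an error, below it they are dropped from the
#'   average with a recorded count.
#' @return A list of class `simex_control`.
#' @export
simex_control <- function(psi = seq(0, 1, length.out = 10), k = 200L,
                          extrapolant = c("quadratic", "linear", "rational_linear", "cubic"),
                          link = c("logistic", "probit", "cloglog"),
                          seed = 1L, drop_max = 0.1) {
  extrapolant <- match.arg(extrapolant)
  link <- match.arg(link)
  psi <- as.numeric(psi)
  if (length(psi) < 2L) stop("`psi` needs at least two grid points.", call. = FALSE)
  if (psi[1L] != 0) stop("The first psi grid value must be 0.", call. = FALSE)
  if (any(psi < 0)) stop("All psi values must be non-negative.", call. = FALSE)
  if (is.unsorted(psi, strictly = TRUE)) stop("`psi` must be strictly increasing.", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be a positive integer.", call. = FALSE)
  if (drop_max < 0 || drop_max >= 1) stop("`drop_max` must be in [0, 1).", call. = FALSE)
  structure(list(psi = psi, k = k, extrapolant = extrapolant, link = link,
                 seed = as.integer(seed), drop_max = drop_max),
            class = "simex_control")
}

#' Add calibrated pseudo-error to observed surrogates
#'
#' Returns \eqn{X^* + \sqrt{\psi}\, e} with rows of \eqn{e} i.i.d.
#' \eqn{N(0, \Sigma_e)}, so the added noise has covariance \eqn{\psi\Sigma_e}
#' and the total surrogate error is \eqn{(1+\psi)\Sigma_e} — vanishing at the
#' extrapolation point \eqn{\psi = -1}.
#'
#' @param xstar `n x px` matrix of observed surrogates.
#' @param psi Non-negative noise-inflation factor.
#' @param error_model An [error_model()] (or PSD matrix) for \eqn{\Sigma_e}.
#' @return An `n x px` matrix of pseudo-surrogates.
#' @export
add_pseudo_error <- function(xstar, psi, error_model) {
  assert_scalar_number(psi, "psi")
  if (psi < 0) {
    stop("`psi` must be >= 0; psi = -1 exists only through extrapolation.", call. = FALSE)
  }
  xstar <- as.matrix(xstar)
  sig <- if (inherits(error_model, "error_model")) error_model$sigma_e else as.matrix(error_model)
  if (psi == 0 || all(sig == 0)) return(xstar)
  rt <- sigma_sqrt(sig)
  n <- nrow(xstar)
  noise <- matrix(stats::rnorm(n * ncol(xstar)), n) %*% rt
  xstar + sqrt(psi) * noise
}

# Upper-triangular-ish square root of a PSD matrix; Cholesky with an
# eigen fallback for semidefinite input.
sigma_sqrt <- function(sig) {
  ch <- tryCatch(chol(sig), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  eg <- eigen(sig, symmetric = TRUE)
  if (any(eg$values < -1e-10)) stop("Error covariance is not PSD.", call. = FALSE)
  t(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors)))
}

#' Normalized replicate contrasts
#'
#' Draws `n_i` standard-normal variates, centers them, and scales them to
#' unit sum of squares, giving contrast coefficients with
#' \eqn{\sum_j c_j = 0} and \eqn{\sum_j c_j^2 = 1} exactly.
#'
#' @param n_i Number of replicates for the subject (`>= 2`).
#' @return Numeric vector of length `n_i`.
#' @export
replicate_contrasts <- function(n_i) {
  n_i <- as.integer(n_i)
  if (n_i < 2L) stop("`n_i` must be >= 2.", call. = FALSE)
  for (attempt in 1:2) {
    d <- stats::rnorm(n_i)
    dev <- d - mean(d)
    ss <- sum(dev^2)
    if (ss > 0) return(dev / sqrt(ss))
  }
  stop("Degenerate contrast draw (all variates equal).", call. = FALSE)
}

#' Generate pseudo-surrogates from replicate measurements
#'
#' The replicate-contrast construction for data where every subject has
#' `n_i >= 2` surrogate replicates and \eqn{\Sigma_e} is never estimated
#' explicitly:
#' \eqn{X^{**}_i(\psi) = \bar X^*_i + \sqrt{\psi/n_i}\sum_j c_{ij} X^*_{ij}},
#' whose increment around the replicate mean has covariance
#' \eqn{(\psi/n_i)\Sigma_e}.
#'
#' @param replicates List of per-subject `n_i x px` replicate matrices.
#' @param psi Non-negative noise-inflation factor.
#' @return An `n x px` matrix of working surrogates (`psi = 0` returns the
#'   per-subject replicate means).
#' @export
replicate_surrogate <- function(replicates, psi) {
  assert_scalar_number(psi, "psi")
  if (psi < 0) stop("`psi` must be >= 0.", call. = FALSE)
  ni <- vapply(replicates, nrow, integer(1))
  if (any(ni < 2L)) {
    stop("Every subject needs n_i >= 2 replicates for the replicate-contrast path; use the known-covariance or validation route otherwise.",
         call. = FALSE)
  }
  out <- t(vapply(replicates, function(m) {
    xbar <- colMeans(m)
    if (psi == 0) return(xbar)
    cc <- replicate_contrasts(nrow(m))
    xbar + sqrt(psi / nrow(m)) * drop(crossprod(m, cc))
  }, numeric(ncol(replicates[[1L]]))))
  if (ncol(replicates[[1L]]) == 1L) out <- matrix(out, ncol = 1L)
  out
}

#' SIMEX-corrected treatment-model coefficients
#'
#' Implements the simulation and extrapolation stages for the treatment
#' model: for every psi on the grid and every k, working surrogates are
#' generated (by [add_pseudo_error()] with \eqn{\Sigma_e}, or by
#' [replicate_surrogate()] when `replicate = TRUE`), the treatment model is
#' refit, the per-k estimates are averaged, and each coefficient's trajectory
#' is extrapolated to \eqn{\psi = -1}.
#'
#' With `px = 0` there is nothing to correct and the naive maximum-likelihood
#' fit on the observed confounders is returned unchanged.
#'
#' @param data A `causal_data` object, or a data frame in the positional
#'   layout together with `px`/`rm`.
#' @param sigma_e \eqn{\Sigma_e} as an [error_model()], matrix, or scalar
#'   common variance. Ignored when `replicate = TRUE`.
#' @param control A [simex_control()].
#' @param replicate Use the replicate-contrast path (every error-prone
#'   confounder must have `rm >= 2` replicate columns)?
#' @param collapse Replicate-collapse rule for the non-replicate path when
#'   replicate columns are present (see [build_design()]).
#' @inheritParams causal_data
#' @return A list of class `simex_fit`: `psi`, `estimates` (grid x
#'   coefficients matrix of per-psi averages), `gamma` (the extrapolated
#'   coefficients), `extrapolant_fits` (per coefficient), `naive` (the naive
#'   fit on observed data), `n_dropped`, and the `control`.
#' @export
simex_propensity <- function(data, px = NULL, rm = NULL, sigma_e = NULL,
                             control = simex_control(), replicate = FALSE,
                             collapse = c("first", "mean")) {
  collapse <- match.arg(collapse)
  ds <- if (inherits(data, "causal_data")) data else causal_data(data, px = px %||% 0L, rm = rm)
  stopifnot(inherits(control, "simex_control"))
  trt <- cd_treatment(ds)
  z <- cd_z(ds)
  pxd <- cd_px(ds)

  w0 <- build_design(ds, collapse = collapse)
  naive <- fit_treatment_model(trt, w0, link = control$link)

  if (pxd == 0L) {
    # nothing error-prone: the naive estimate is the answer
    mest <- matrix(rep(naive$gamma, each = length(control$psi)),
                   nrow = length(control$psi),
                   dimnames = list(NULL, names(naive$gamma)))
    return(structure(list(psi = control$psi, estimates = mest,
                          gamma = naive$gamma, extrapolant_fits = NULL,
                          naive = naive, n_dropped = 0L, control = control,
                          replicate = FALSE, collapse = collapse),
                     class = "simex_fit"))
  }

  if (replicate) {
    reps <- cd_replicates(ds)
    em <- NULL
  } else {
    if (is.null(sigma_e)) stop("`sigma_e` is required unless replicate = TRUE.", call. = FALSE)
    em <- if (inherits(sigma_e, "error_model")) sigma_e else error_model(sigma_e, px = pxd)
    xs <- cd_xstar(ds, collapse = collapse)
    reps <- NULL
  }

  psi <- control$psi
  m_grid <- length(psi)
  p1 <- ncol(w0)
  x_idx <- 1L + seq_len(pxd)

  sums <- matrix(0, m_grid, p1)
  n_ok <- integer(m_grid)
  n_dropped <- 0L
  for (kk in seq_len(control$k)) {
    for (mm in seq_len(m_grid)) {
      set.seed(substream_seed(control$seed, kk, mm))
      w <- w0
      w[, x_idx] <- if (replicate) {
        replicate_surrogate(reps, psi[mm])
      } else {
        add_pseudo_error(xs, psi[mm], em)
      }
      fit <- tryCatch(
        suppressWarnings(fit_treatment_model(trt, w, link = control$link,
                                             start = naive$gamma)),
        error = function(e) NULL
      )
      if (is.null(fit) || !fit$converged) {
        n_dropped <- n_dropped + 1L
      } else {
        sums[mm, ] <- sums[mm, ] + fit$gamma
        n_ok[mm] <- n_ok[mm] + 1L
      }
    }
  }
  if (n_dropped > control$drop_max * control$k * m_grid || any(n_ok == 0L)) {
    stop(sprintf("Too many failed treatment-model fits: %d of %d.",
                 n_dropped, control$k * m_grid), call. = FALSE)
  }
  est <- sums / n_ok
  colnames(est) <- colnames(w0)

  fits <- lapply(seq_len(p1), function(j) {
    fit_extrapolant(psi, est[, j], control$extrapolant)
  })
  gamma <- vapply(fits, `[[`, numeric(1), "value_at_minus_one")
  names(gamma) <- colnames(w0)
  names(fits) <- colnames(w0)

  structure(list(psi = psi, estimates = est, gamma = gamma,
                 extrapolant_fits = fits, naive = naive,
                 n_dropped = n_dropped, control = control,
                 replicate = replicate, collapse = collapse),
            class = "simex_fit")
}

#' @export
print.simex_fit <- function(x, ...) {
  cat("SIMEX-corrected treatment model (", x$control$link, " link, ",
      x$control$extrapolant, " extrapolant)\n", sep = "")
  cat("  psi grid: ", length(x$psi), " points on [0, ", max(x$psi), "], k = ",
      x$control$k, "\n", sep = "")
  cat("  corrected coefficients:\n")
  print(round(x$gamma, 6))
  if (x$n_dropped > 0L) cat("  dropped fits:", x$n_dropped, "\n")
  invisible(x)
}
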
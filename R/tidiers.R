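#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the SIMEX coefficient trajectory
#'
#' One row per (psi, coefficient) with the per-psi averaged estimate; the
#' extrapolated coefficients are available via `glance()` or `x$gamma`.
#'
#' @param x A `simex_fit`.
#' @param ... Unused.
#' @return A tibble with columns `psi`, `term`, `estimate`.
#' @export
tidy.simex_fit <- function(x, ...) {
  est <- tibble::as_tibble(x$estimates)
  est$psi <- x$psi
  tidyr::pivot_longer(est, -"psi", names_to = "term", values_to = "estimate")
}

#' @rdname tidy.simex_fit
#' @export
glance.simex_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$gamma),
    estimate = unname(x$gamma),
    naive = unname(x$naive$gamma),
    extrapolant = x$control$extrapolant,
    fallback = if (is.null(x$extrapolant_fits)) FALSE
               else vapply(x$extrapolant_fits, `[[`, logical(1), "fallback_used")
  )
}

#' Tidy a confounder-selection result
#'
#' @param x A `confounder_selection`.
#' @param ... Unused.
#' @return A tibble with `term` (0 = intercept, then confounder index),
#'   `estimate`, and `selected`.
#' @export
tidy.confounder_selection <- function(x, ...) {
  p1 <- length(x$gamma)
  tibble::tibble(
    term = if (!is.null(names(x$gamma)) && all(nzchar(names(x$gamma))))
             names(x$gamma) else as.character(seq_len(p1) - 1L),
    estimate = unname(x$gamma),
    selected = c(TRUE, seq_len(p1 - 1L) %in% x$support)
  )
}

#' @rdname tidy.confounder_selection
#' @export
glance.confounder_selection <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, df = sum(x$gamma != 0),
                 n_selected = length(x$support),
                 penalty = x$penalty, tuning = x$tuning)
}

#' Tidy the per-psi ATE trajectory
#'
#' @param x An `ate_fit`.
#' @param ... Unused.
#' @return The `psi`/`ate` trajectory tibble.
#' @export
tidy.ate_fit <- function(x, ...) x$psi_trajectory

#' @rdname tidy.ate_fit
#' @export
glance.ate_fit <- function(x, ...) {
  tibble::tibble(estimate = x$estimate,
                 extrapolant = if (is.null(x$extrapolant_fit)) NA_character_
                               else x$extrapolant_fit$family,
                 n_dropped = x$n_dropped, n_clamped = x$n_clamped,
                 plain_ipw = x$naive)
}

#' One-row summary of a bootstrap ATE result
#'
#' @param x An `ate_boot`.
#' @param ... Unused.
#' @return A tibble with `estimate`, `variance`, `std_error`, `p_value`,
#'   `n_bootstrap`, `degenerate`.
#' @export
glance.ate_boot <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, variance = x$variance,
                 std_error = sqrt(x$variance), p_value = x$p_value,
                 n_bootstrap = x$n_bootstrap, degenerate = x$degenerate)
}

#' @rdname glance.ate_boot
#' @export
tidy.ate_boot <- function(x, ...) glance.ate_boot(x, ...)

#' One-row summary of the full pipeline
#'
#' @param x A `simexipw_fit`.
#' @param ... Unused.
#' @return A tibble with the ATE estimate, bootstrap variance and p-value
#'   (when computed), and the selected support size.
#' @export
glance.simexipw_fit <- function(x, ...) {
  base <- if (!is.null(x$boot)) glance.ate_boot(x$boot)
          else tibble::tibble(estimate = x$ate$estimate,
                              variance = NA_real_, std_error = NA_real_,
                              p_value = NA_real_, n_bootstrap = 0L,
                              degenerate = FALSE)
  base$n_selected <- if (!is.null(x$selection)) length(x$selection$support)
                     else length(x$ate$support)
  base$penalty <- if (x$select) x$penalty else NA_character_
  base
}

#' @rdname glance.simexipw_fit
#' @export
tidy.simexipw_fit <- function(x, ...) {
  out <- glance.simex_fit(x$simex)
  out$selected <- c(TRUE, seq_len(length(x$simex$gamma) - 1L) %in% x$ate$support)
  out
}
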
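#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# evaluation grid from the extrapolation point to the end of the psi grid
extrapolant_curve <- function(fit, psi_max) {
  u <- seq(-1, psi_max, length.out = 200)
  tibble::tibble(psi = u, value = eval_extrapolant(fit$family, fit$coefficients, u))
}

#' Plot the SIMEX coefficient trajectories with their extrapolants
#'
#' Per-psi averaged coefficient estimates (points), the fitted extrapolation
#' curves, and the extrapolated values at `psi = -1` (open circles).
#'
#' @param object A `simex_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.simex_fit <- function(object, ...) {
  pts <- tidy(object)
  if (is.null(object$extrapolant_fits)) {
    return(ggplot2::ggplot(pts, ggplot2::aes(x = .data$psi, y = .data$estimate)) +
             ggplot2::geom_point() +
             ggplot2::facet_wrap(~term, scales = "free_y") +
             ggplot2::labs(x = expression(psi), y = "coefficient"))
  }
  curves <- purrr::imap_dfr(object$extrapolant_fits, function(f, nm) {
    dplyr::mutate(extrapolant_curve(f, max(object$psi)), term = nm)
  })
  ext <- tibble::tibble(term = names(object$gamma), psi = -1,
                        estimate = unname(object$gamma))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$psi, y = .data$estimate)) +
    ggplot2::geom_line(data = curves, ggplot2::aes(y = .data$value),
                       linetype = 2, colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(data = ext, shape = 1, size = 2, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = expression(psi), y = "coefficient",
                  title = "SIMEX trajectories and extrapolation to psi = -1")
}

#' Plot the per-psi ATE trajectory with its extrapolant
#'
#' @param object An `ate_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ate_fit <- function(object, ...) {
  pts <- object$psi_trajectory
  g <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$psi, y = .data$ate)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(psi), y = "stabilized-IPW ATE",
                  title = "ATE trajectory and extrapolation to psi = -1")
  if (!is.null(object$extrapolant_fit)) {
    g <- g +
      ggplot2::geom_line(data = extrapolant_curve(object$extrapolant_fit, max(pts$psi)),
                         ggplot2::aes(y = .data$value), linetype = 2, colour = "grey40") +
      ggplot2::annotate("point", x = -1, y = object$estimate, shape = 1,
                        size = 2, colour = "firebrick")
  }
  g
}

#' Plot the tuning-criterion path of a confounder selection
#'
#' @param object A `confounder_selection`.
#' @param ... Unused.
#' @return A ggplot object (criterion vs log lambda, selected lambda marked).
#' @export
autoplot.confounder_selection <- function(object, ...) {
  ggplot2::ggplot(object$path, ggplot2::aes(x = log(.data$lambda), y = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = log(object$lambda), linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = expression(log(lambda)),
                  y = toupper(object$tuning),
                  title = sprintf("%s path (%s penalty)", toupper(object$tuning),
                                  object$penalty))
}
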
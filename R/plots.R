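#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an adsorption curve
#'
#' Adsorption probability against the sweep variable (log x-axis for
#' positive grids spanning decades), with the half-peak level drawn to make
#' the binding window visible.
#'
#' @param object An [adsorption_curve()].
#' @param normalized Plot `theta_normalized` instead of `theta`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot adsorption_curve
#' @export
autoplot.adsorption_curve <- function(object, normalized = FALSE, ...) {
  y <- if (normalized) "theta_normalized" else "theta"
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x,
                                            y = .data[[y]])) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5 * max(object[[y]]),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = attr(object, "sweep") %||% "sweep variable",
      y = if (normalized) "theta / max(theta)" else "adsorption probability theta"
    )
  if (all(object$x > 0) && max(object$x) / min(object$x) > 100) {
    p <- p + ggplot2::scale_x_log10()
  }
  p
}

#' Plot an annealing fit against its dataset
#'
#' Normalised adsorption data (with msrd error bars) and the fitted
#' forward-model prediction per loading.
#'
#' @param object An [anneal_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot anneal_fit
#' @export
autoplot.anneal_fit <- function(object, ...) {
  pred <- predict_adsorption(object$dataset, object$ligand_density_ref,
                             object$receptor_density, object$model)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$loading)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$theta_norm - .data$msrd, 0),
                   ymax = pmin(.data$theta_norm + .data$msrd, 1)),
      width = 0.05, colour = "grey40"
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$theta_norm), size = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$theta_norm_model),
                       colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$theta_norm_model),
                        colour = "firebrick", shape = 1, size = 3) +
    ggplot2::labs(x = "ligand loading (sigma_L / sigma_ref)",
                  y = "normalised adsorption theta'")
}

#' Plot the annealing convergence trace
#'
#' Best-ever objective against cooling step, on a log-log scale.
#'
#' @param fit An [anneal_fit()].
#' @return A ggplot.
#' @export
plot_anneal_trace <- function(fit) {
  stopifnot(inherits(fit, "anneal_fit"))
  ggplot2::ggplot(fit$trace,
                  ggplot2::aes(x = .data$step, y = .data$best_objective)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cooling step", y = "best objective E")
}
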
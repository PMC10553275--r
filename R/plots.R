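#' Plot a simulation's density time series
#'
#' Cooperator and defector densities per step, with the total density as a
#' thin grey line; a useful first look at whether a run has equilibrated,
#' oscillates, or lost one type.
#'
#' @param object An `"ecoflow_sim"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecoflow_sim
#' @export
autoplot.ecoflow_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$steps[, c("t", "rho_C", "rho_D")],
    cols = c("rho_C", "rho_D"),
    names_to = "type", values_to = "density"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$density,
                                     colour = .data$type)) +
    ggplot2::geom_line(data = object$steps,
                       ggplot2::aes(x = .data$t, y = .data$rho),
                       inherit.aes = FALSE, colour = "grey60",
                       linewidth = 0.3) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(rho_C = "#2166ac", rho_D = "#b2182b"),
      labels = c(rho_C = "cooperators", rho_D = "defectors"),
      name = NULL
    ) +
    ggplot2::labs(x = "time step", y = "density (per site)") +
    ggplot2::theme_minimal()
}

#' Plot a lifespan distribution
#'
#' Log-count histogram of lifespans with the fitted exponential tail (when
#' available) overlaid.
#'
#' @param object An `"ecoflow_lifespan"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecoflow_lifespan
#' @export
autoplot.ecoflow_lifespan <- function(object, ...) {
  h <- object$hist[object$hist$count > 0, ]
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$age, y = .data$count)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lifespan (steps)", y = "deaths",
                  title = sprintf("strategy %s", object$strategy)) +
    ggplot2::theme_minimal()
  if (object$tail_fitted) {
    p <- p + ggplot2::geom_smooth(
      data = h[h$age >= stats::median(h$age), ],
      method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.4,
      colour = "#e08214"
    )
  }
  p
}

#' Plot a mean-field phase diagram
#'
#' Tile plot of the phase classification over the `(lambda/eta, r)` grid
#' produced by [mf_phase_diagram()], with the analytic cooperation onset
#' [r_star()] overlaid.
#'
#' @param phases Tibble from [mf_phase_diagram()].
#' @return A ggplot object.
#' @export
plot_phase_diagram <- function(phases) {
  curve <- tibble::tibble(
    ratio = seq(min(phases$ratio), max(phases$ratio), length.out = 200)
  )
  curve$r <- r_star(curve$ratio, 1)
  ggplot2::ggplot(phases, ggplot2::aes(x = .data$ratio, y = .data$r)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$phase)) +
    ggplot2::geom_line(data = curve, colour = "#e08214", linewidth = 0.8) +
    ggplot2::scale_fill_brewer(palette = "RdBu", name = NULL) +
    ggplot2::labs(x = expression(lambda / eta), y = "enhancement factor r") +
    ggplot2::theme_minimal()
}
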
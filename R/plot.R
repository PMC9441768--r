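# ggplot2 figure analogues

.phase_palette <- c(
  all_A_shell = "#1b9e77", mixed = "#7570b3",
  all_A_core = "#d95f02", unstable = "grey70"
)

#' Plot a swept equilibrium curve
#'
#' Shell fraction `alpha*` (and optionally `n*` or radii) against the
#' swept variable, coloured by phase.
#'
#' @param object A `micelle_sweep` from [sweep_micelle()].
#' @param y Column to plot (default `"alpha_star"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.micelle_sweep <- function(object, y = "alpha_star", ...) {
  xv <- attr(object, "variable")
  ggplot2::ggplot(object, ggplot2::aes(.data[[xv]], .data[[y]])) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phase), size = 1.4) +
    ggplot2::scale_colour_manual(values = .phase_palette, drop = FALSE) +
    ggplot2::labs(x = xv, y = y, colour = "phase") +
    ggplot2::theme_minimal()
}

#' Plot a phase map
#'
#' Tile plot of phase labels over the two-parameter grid.
#'
#' @param object A `phase_map` from [phase_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_map <- function(object, ...) {
  xv <- attr(object, "x_variable")
  ggplot2::ggplot(object,
                  ggplot2::aes(.data[[xv]], .data$N_A, fill = .data$phase)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = .phase_palette, drop = FALSE,
                               na.value = "white") +
    ggplot2::labs(x = xv, y = "N_A", fill = "phase") +
    ggplot2::theme_minimal()
}

#' Plot a steady-state size distribution
#'
#' @param object A `size_distribution` from [size_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.size_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$n, .data$prob)) +
    ggplot2::geom_col(width = 1, fill = "#1b9e77", colour = NA) +
    ggplot2::labs(x = "aggregation number n", y = "probability") +
    ggplot2::theme_minimal()
}

#' Free-energy landscape in the shell fraction
#'
#' `F_n(alpha)` against `alpha` for one or more aggregation numbers;
#' useful to see the double well behind the first-order transition.
#'
#' @param params A [micelle_params()] object.
#' @param n Aggregation numbers (vector).
#' @param grid_n Number of `alpha` grid points.
#' @return A ggplot object.
#' @export
plot_alpha_landscape <- function(params, n, grid_n = 201) {
  states <- tidyr::expand_grid(n = n, alpha = seq(0, 1, length.out = grid_n))
  fe <- free_energy(states, params)
  ggplot2::ggplot(fe, ggplot2::aes(.data$alpha, .data$total,
                                   colour = factor(.data$n))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "shell fraction alpha", y = "F_n(alpha) [kBT]",
                  colour = "n") +
    ggplot2::theme_minimal()
}
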
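#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_errorbar geom_tile coord_equal labs facet_wrap
#'   scale_colour_manual scale_fill_manual theme_minimal
#' @export
ggplot2::autoplot

granusim_palette <- c(acidogen = "#2ca02c", methanogen = "#d62728",
                      dead = "#222222")

#' Plot the agents of a world state
#'
#' Draws each cell at its position, sized by radius and coloured by
#' type (green acidogens, red methanogens, black dead biomass, the
#' conventional fluorescence colouring).
#'
#' @param object a `world_state` (or `granulation_run`: final state).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.world_state <- function(object, ...) {
  state <- if (inherits(object, "granulation_run")) object$state else object
  a <- state$agents
  a$radius <- agent_radii(a, state$species, state$config)
  ggplot(a, aes(x = .data$x, y = .data$y, colour = .data$species,
                size = .data$radius)) +
    geom_point() +
    scale_colour_manual(values = granusim_palette) +
    ggplot2::scale_size_identity() +
    coord_equal(xlim = c(0, state$config$domain_width),
                ylim = c(0, state$config$domain_height)) +
    labs(x = "x (µm)", y = "y (µm)",
         title = sprintf("t = %.0f h", state$time)) +
    theme_minimal()
}

#' Plot the summary series of a run
#'
#' Cell counts, biomass and solute totals against time.
#'
#' @param object a `granulation_run`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.granulation_run <- function(object, ...) {
  s <- object$summary
  counts <- tidyr::pivot_longer(
    s[, c("time", "acidogens", "methanogens", "dead")],
    -"time", names_to = "series", values_to = "value")
  counts$panel <- "cell count"
  sol <- tidyr::pivot_longer(
    s[, c("time", "glucose_g", "acetate_g", "methane_g",
          "ch4_cumulative_g")],
    -"time", names_to = "series", values_to = "value")
  sol$panel <- "solute mass (g)"
  d <- dplyr::bind_rows(counts, sol)
  ggplot(d, aes(x = .data$time, y = .data$value, colour = .data$series)) +
    geom_line() +
    facet_wrap(~panel, scales = "free_y") +
    labs(x = "time (h)", y = NULL) +
    theme_minimal()
}

#' Plot a radial stratification profile
#'
#' Mean per-type counts per radial bin with across-quarter standard
#' deviations.
#'
#' @param object a `radial_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.radial_profile <- function(object, ...) {
  s <- object$summary
  s$mid <- (s$bin_lo + s$bin_hi) / 2
  ggplot(s, aes(x = .data$mid, y = .data$mean, fill = .data$species)) +
    geom_col(position = "dodge") +
    geom_errorbar(aes(ymin = pmax(.data$mean - .data$sd, 0),
                      ymax = .data$mean + .data$sd),
                  position = "dodge", width = 0) +
    scale_fill_manual(values = granusim_palette) +
    labs(x = "distance from centroid (µm)",
         y = "cells per quarter (mean ± sd)") +
    theme_minimal()
}

#' Heatmap of a methane-yield scan
#'
#' Mean specific methane yield per (glucose, initial count) cell.
#'
#' @param object a `scan_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.scan_result <- function(object, ...) {
  g <- object$grid
  ggplot(g, aes(x = factor(.data$count), y = factor(.data$glucose),
                fill = .data$mean_yield)) +
    geom_tile() +
    ggplot2::scale_fill_gradient(low = "#2166ac", high = "#b2182b") +
    labs(x = sprintf("initial %s count", object$spec$varied_species),
         y = "bulk glucose (g/L)", fill = "ml CH4 / g") +
    theme_minimal()
}
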
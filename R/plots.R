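#' Plot posterior species richness against a vegetation metric
#'
#' Points are posterior medians with 95% credible-interval error bars; the
#' line is the ordinary least-squares fit of median richness on the metric.
#'
#' @param object A `richness_posterior`.
#' @param covariates Tibble with `site` and the metric column.
#' @param metric Metric column to plot against.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.richness_posterior <- function(object, covariates,
                                        metric = "dens_canopy", ...) {
  df <- dplyr::inner_join(object, covariates, by = "site")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[metric]], y = .data$median)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      linewidth = 0.3, colour = "grey60", width = 0
    ) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = metric, y = "Posterior median species richness")
}

#' Plot species responses to midstory and canopy density
#'
#' Each species is placed at its posterior-mean effects of midstory and
#' canopy density on occupancy; species in the lower-left quadrant favour
#' the open structure of ghost forest, upper-right species favour
#' unaffected closed-canopy forest.
#'
#' @param object A `support_classification`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.support_classification <- function(object, ...) {
  wide <- tidyr::pivot_wider(
    object[, c("species", "covariate", "mean")],
    names_from = "covariate", values_from = "mean"
  )
  strong <- object |>
    dplyr::group_by(species = .data$species) |>
    dplyr::summarise(any_strong = any(.data$strength == "strong"),
                     .groups = "drop")
  wide <- dplyr::left_join(wide, strong, by = "species")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$b_mid, y = .data$b_canopy)) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$any_strong)) +
    ggplot2::labs(x = "Midstory density effect",
                  y = "Canopy density effect",
                  colour = "Any strong effect")
}

#' Plot net habitat change by species and stratum
#'
#' @param object A `habitat_change_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.habitat_change_table <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = factor(.data$species), y = .data$net_ha)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~stratum, scales = "free_y") +
    ggplot2::labs(x = "Species", y = "Net habitat change (ha)")
}

#' Map the classified occupancy change of one species
#'
#' @param change Tibble from [classify_change()].
#' @return A ggplot raster map with loss/none/gain fills.
#' @export
plot_change_map <- function(change) {
  ggplot2::ggplot(change, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$change)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(loss = "#2166ac", none = "grey90", gain = "#1b7837"),
      drop = FALSE
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "Habitat change")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
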
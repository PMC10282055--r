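#' Plot a distance-regression fit
#'
#' Log-log scatter of mask activity against residence distance with the
#' fitted power law; a slope of -2 is the inverse-square dilution
#' expectation.
#'
#' @param object A `distance_fit` from [distance_regression()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.distance_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$distance_km, y = .data$a137_bq)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_function(
      fun = function(d) 10^(object$intercept + object$slope * log10(d)),
      colour = "firebrick"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Distance from source [km]",
      y = expression({}^137 * Cs ~ "activity [Bq]"),
      title = sprintf("slope %.2f, R² = %.3f (n = %d)",
                      object$slope, object$r_squared, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an imaging-plate image
#'
#' PSL count map as a raster; hotspots from [detect_hotspots()] can be
#' overlaid.
#'
#' @param object An [ip_image()].
#' @param spots Optional hotspot tibble to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ip_image <- function(object, spots = NULL, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$counts <- as.numeric(object[cbind(df$row, df$col)])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$counts)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "PSL counts") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column [px]", y = "row [px]") +
    ggplot2::theme_minimal()
  if (!is.null(spots) && nrow(spots) > 0) {
    p <- p + ggplot2::geom_point(
      data = spots,
      ggplot2::aes(x = .data$centroid_col, y = .data$centroid_row),
      inherit.aes = FALSE, shape = 1, colour = "red", size = 4
    )
  }
  p
}

#' Plot isotope ratios in decreasing order
#'
#' Cs-134/Cs-137 activity ratios at a common reference date with 1-sigma
#' error bars, arranged in decreasing order, against the cumulative-burnup
#' reference ratios of the three reactor units (0.941, 1.08, 1.05).  With
#' nine years of Cs-134 decay the per-particle errors are large, so unit
#' attribution from single particles is generally not possible — the plot
#' makes that visible.
#'
#' @param data Tibble with `ratio` and `ratio_sigma` columns, e.g. from
#'   [isotope_ratio_table()].
#' @param unit_ratios Reference ratios to draw as horizontal lines.
#' @return A ggplot.
#' @export
plot_isotope_ratios <- function(data,
                                unit_ratios = c(`Unit 1` = 0.941,
                                                `Unit 2` = 1.08,
                                                `Unit 3` = 1.05)) {
  df <- data[!is.na(data$ratio), ]
  df <- df[order(-df$ratio), ]
  df$rank <- seq_len(nrow(df))
  ref <- tibble(unit = names(unit_ratios), ratio = unname(unit_ratios))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$ratio)) +
    ggplot2::geom_hline(data = ref,
                        ggplot2::aes(yintercept = .data$ratio,
                                     linetype = .data$unit),
                        colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$ratio - .data$ratio_sigma,
      ymax = .data$ratio + .data$ratio_sigma
    ), size = 0.3) +
    ggplot2::labs(
      x = "Particle (decreasing ratio)",
      y = expression({}^134 * Cs / {}^137 * Cs ~ "activity ratio"),
      linetype = NULL
    ) +
    ggplot2::theme_minimal()
}
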
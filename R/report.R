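#' Plate heatmap data
#'
#' Expands per-well values onto the full 16 x 24 grid, clipping to the
#' display scale (the screen's defaults: 0--6000 for cell numbers, 0--3.75
#' for ALP intensity per cell). Wells without a value stay blank (`NA`).
#' The returned table is the machine-readable twin of the rendered heatmap.
#'
#' @param wells Tibble with columns `well` and the value column.
#' @param value Column to display (tidy-eval).
#' @param scale Display scale `c(min, max)`; values are clipped to it.
#' @return Tibble with one row per grid well: `well`, `row`, `col`,
#'   `value` (raw) and `display` (clipped).
#' @export
plate_heatmap_data <- function(wells, value, scale = c(0, 6000)) {
  stopifnot(length(scale) == 2, scale[1] < scale[2])
  vals <- wells |>
    dplyr::transmute(well = parse_well(.data$well)$well,
                     value = {{ value }})
  grid <- parse_well(all_wells_384())
  grid |>
    dplyr::left_join(vals, by = "well") |>
    dplyr::mutate(display = pmin(pmax(.data$value, scale[1]), scale[2]))
}

#' Render a plate heatmap
#'
#' @param data Output of [plate_heatmap_data()].
#' @param title Plot title.
#' @return A ggplot object (16 x 24 tile grid, plate orientation: row A on
#'   top).
#' @export
plot_plate_heatmap <- function(data, title = NULL) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$display)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_y_reverse(breaks = 1:16, labels = LETTERS[1:16],
                             expand = c(0, 0)) +
    ggplot2::scale_x_continuous(breaks = c(1, seq(4, 24, 4)),
                                position = "top", expand = c(0, 0)) +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' Rank-plot data with hit-category color classes
#'
#' Orders genes by the plotted statistic and tags each with the display
#' class used in the screen's rank plots: `viability` for genes below the
#' cell-number cut (<60%), `up` for ALP >= 160% (inclusive), `down` for
#' ALP <= 40%, `other` otherwise. Ties in the statistic are broken by gene
#' symbol so the ordering is deterministic.
#'
#' @param results Per-gene tibble (needs `gene_symbol`,
#'   `mean_pct_cell_number`, `mean_pct_alp`, and the ranking statistic).
#' @param statistic Column to rank by (tidy-eval), e.g. `mean_pct_alp`.
#' @param thresholds A [hit_thresholds()].
#' @return `results` ordered by the statistic with columns `rank`,
#'   `statistic` and `color_class`.
#' @export
rank_plot_data <- function(results, statistic = mean_pct_alp,
                           thresholds = hit_thresholds()) {
  th <- thresholds
  out <- results |>
    dplyr::mutate(statistic = {{ statistic }},
                  color_class = dplyr::case_when(
                    .data$mean_pct_cell_number < th$viability_pct_min ~ "viability",
                    .data$mean_pct_alp >= th$alp_pct_up ~ "up",
                    .data$mean_pct_alp <= th$alp_pct_down ~ "down",
                    TRUE ~ "other"
                  )) |>
    dplyr::arrange(.data$statistic, .data$gene_symbol) |>
    dplyr::mutate(rank = dplyr::row_number())
  out
}

#' Render a rank plot
#'
#' @param data Output of [rank_plot_data()].
#' @param ylab Axis label for the ranked statistic.
#' @return A ggplot object; classes use the screen's colors (red = up,
#'   green = down, light blue = viability casualties).
#' @export
plot_rank <- function(data, ylab = "statistic") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$rank, y = .data$statistic,
                                     color = .data$color_class)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_color_manual(values = c(up = "red3", down = "green4",
                                           viability = "skyblue2",
                                           other = "grey40")) +
    ggplot2::labs(x = "rank", y = ylab, color = NULL) +
    ggplot2::theme_classic()
}

#' Plot method for screen analyses
#'
#' @param object An `osteo_screen` object.
#' @param type `"rank_alp"` (percent ALP rank plot), `"rank_cells"`
#'   (percent cell-number rank plot) or `"rank_z"` (z-score rank plot).
#' @param ... Unused.
#' @method autoplot osteo_screen
#' @return A ggplot object.
#' @export
autoplot.osteo_screen <- function(object,
                                  type = c("rank_alp", "rank_cells", "rank_z"),
                                  ...) {
  type <- match.arg(type)
  res <- object$results |>
    dplyr::left_join(object$hits[c("gene_symbol", "category")],
                     by = "gene_symbol")
  switch(type,
    rank_alp = plot_rank(rank_plot_data(res, .data$mean_pct_alp,
                                        object$thresholds),
                         ylab = "ALP activity (% of Non-Targeting)"),
    rank_cells = plot_rank(rank_plot_data(res, .data$mean_pct_cell_number,
                                          object$thresholds),
                           ylab = "cell number (% of Non-Targeting)"),
    rank_z = plot_rank(rank_plot_data(res, .data$mean_z_alp,
                                      object$thresholds),
                       ylab = "z-score of log2 ALP activity")
  )
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
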
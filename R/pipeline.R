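#' Run a screen end-to-end on field images
#'
#' Segments and quantifies every field, aggregates to wells, annotates with
#' the layout, and runs the full screen statistics. This is the programmatic
#' equivalent of the command-line `run-all`.
#'
#' @param fields List of `field_image` objects (e.g. from
#'   [simulate_screen()] or read from TIFF with [read_field_channel()]).
#' @param layout Plate layout covering every imaged well.
#' @param params A [detection_params()].
#' @param thresholds A [hit_thresholds()].
#' @param ... Passed to [screen_analysis()].
#' @return An `osteo_screen` object whose `field_measurements` element keeps
#'   the per-field table.
#' @export
run_screen <- function(fields, layout, params = detection_params(),
                       thresholds = hit_thresholds(), ...) {
  fm <- quantify_fields(fields, params)
  wells <- aggregate_well(fm) |> annotate_wells(layout)
  scr <- screen_analysis(wells, thresholds = thresholds, ...)
  scr$field_measurements <- fm
  scr
}

#' Simulate, analyse and summarise a synthetic screen in one call
#'
#' Convenience wrapper used by power/recovery studies: simulates
#' measurement-level data for a replicated layout, aggregates and analyses
#' it. No images are rendered.
#'
#' @param layout Single-plate layout (replicated internally).
#' @param effects [gene_effects()] tibble.
#' @param config A [simulation_config()]; `n_replicates` controls the
#'   number of plates.
#' @param thresholds A [hit_thresholds()].
#' @return An `osteo_screen` object.
#' @export
simulate_and_analyze <- function(layout, effects,
                                 config = simulation_config(),
                                 thresholds = hit_thresholds()) {
  lay <- replicate_layout(layout, config$n_replicates)
  fm <- simulate_measurements(lay, effects, config)
  wells <- aggregate_well(fm)
  screen_analysis(wells, thresholds = thresholds)
}
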
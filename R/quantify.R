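#' Measure one field
#'
#' The field-level readouts of the screen: the nuclei count, the summed
#' background-corrected ELF intensity over the detected spot area, the spot
#' area in pixels, and (when available) the Ki67-positive nucleus count.
#'
#' @param nuclei Label map of segmented nuclei.
#' @param spots Label map of detected ALP spots.
#' @param elf_corrected Background-corrected ELF raster (same shape as
#'   `spots`).
#' @param ki67 Optional classification tibble from [classify_ki67()].
#' @return One-row tibble: `nuclei_count`, `alp_intensity_in_spots`,
#'   `spot_area_px`, `ki67_positive_count`.
#' @export
measure_field <- function(nuclei, spots, elf_corrected, ki67 = NULL) {
  stopifnot(all(dim(spots) == dim(elf_corrected)))
  in_spots <- as.integer(spots) > 0L
  tibble::tibble(
    nuclei_count = label_count(nuclei),
    alp_intensity_in_spots = sum(as.numeric(elf_corrected)[in_spots]),
    spot_area_px = sum(in_spots),
    ki67_positive_count = if (is.null(ki67)) NA_integer_ else
      as.integer(attr(ki67, "positive_count"))
  )
}

#' Quantify a field image end-to-end
#'
#' Runs [segment_field()] with the chosen operator set and then
#' [measure_field()], carrying the field's identifiers along.
#'
#' @param field A `field_image`.
#' @param params A [detection_params()].
#' @return One-row tibble with `plate_id`, `well`, `field` and the
#'   [measure_field()] columns.
#' @export
quantify_field <- function(field, params = detection_params()) {
  seg <- segment_field(field, params)
  m <- measure_field(seg$nuclei, seg$spots, seg$elf_corrected, seg$ki67)
  dplyr::bind_cols(
    tibble::tibble(plate_id = field$plate_id, well = field$well,
                   field = field$field),
    m
  )
}

#' Quantify a list of field images
#'
#' @param fields List of `field_image` objects (e.g. from
#'   [simulate_screen()]).
#' @param params A [detection_params()].
#' @return Field-measurement tibble, one row per field.
#' @export
quantify_fields <- function(fields, params = detection_params()) {
  purrr::map_dfr(fields, quantify_field, params = params)
}

#' Aggregate field measurements into well measurements
#'
#' Per well: the cell number is the sum of detected nuclei over all measured
#' fields; the per-cell ALP activity is the ELF intensity within spot area
#' per field divided by that field's nuclei count, averaged (unweighted)
#' over the well's fields. Fields without nuclei are excluded from that mean
#' (they carry no per-cell information and would divide by zero); if no
#' field has nuclei the per-cell activity is missing, not zero. The Ki67
#' fraction is computed from pooled counts, `sum(positive) / sum(nuclei)`,
#' which is unbiased when fields differ in density.
#'
#' @param fields Field-measurement tibble with columns `plate_id`, `well`,
#'   `nuclei_count`, `alp_intensity_in_spots` and optionally
#'   `ki67_positive_count`; any grouping columns (`gene_symbol`, `role`) are
#'   carried through.
#' @return Well-measurement tibble: one row per (plate, well) with
#'   `cell_number`, `alp_per_cell`, `ki67_fraction`, `n_fields_used`.
#' @export
aggregate_well <- function(fields) {
  stopifnot(nrow(fields) >= 1)
  if (!"plate_id" %in% names(fields)) fields$plate_id <- NA_character_
  if (!"well" %in% names(fields)) fields$well <- NA_character_
  if (!"ki67_positive_count" %in% names(fields)) {
    fields$ki67_positive_count <- NA_integer_
  }
  carry <- intersect(c("gene_symbol", "role"), names(fields))
  fields |>
    dplyr::group_by(.data$plate_id, .data$well) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(carry), dplyr::first),
      cell_number = sum(.data$nuclei_count),
      alp_per_cell = {
        ok <- .data$nuclei_count > 0
        if (any(ok)) {
          mean(.data$alp_intensity_in_spots[ok] / .data$nuclei_count[ok])
        } else NA_real_
      },
      ki67_fraction = if (all(is.na(.data$ki67_positive_count)) ||
                          sum(.data$nuclei_count) == 0) NA_real_ else {
        sum(.data$ki67_positive_count) / sum(.data$nuclei_count)
      },
      n_fields_used = dplyr::n(),
      .groups = "drop"
    )
}

#' Attach layout annotation to well measurements
#'
#' @param wells Well-measurement tibble.
#' @param layout Plate layout.
#' @return Wells with `gene_symbol` and `role` columns from the layout.
#' @export
annotate_wells <- function(wells, layout) {
  layout <- validate_plate_layout(layout)
  wells |>
    dplyr::select(-dplyr::any_of(c("gene_symbol", "role"))) |>
    dplyr::left_join(layout[c("plate_id", "well", "gene_symbol", "role")],
                     by = c("plate_id", "well")) |>
    dplyr::relocate("gene_symbol", "role", .after = "well")
}

#' Time-course summary of cell number, ALP activity and Ki67 positivity
#'
#' Summarises replicate wells per condition (osteogenic induction status)
#' and day: mean and SEM (`sd/sqrt(n)`) of the cell number and per-cell ALP
#' activity, fold change of ALP relative to the uninduced condition at the
#' same day, and the pooled Ki67-positive percentage.
#'
#' @param wells Well-measurement tibble with additional columns `condition`
#'   (e.g. `"+OI"`, `"-OI"`) and `day`.
#' @param reference Condition used as the fold-change baseline
#'   (default `"-OI"`).
#' @return Tibble with one row per (condition, day): means, SEMs,
#'   `alp_fold_change` and `pct_ki67`. SEM columns are `NA` for single
#'   replicates.
#' @export
timecourse_table <- function(wells, reference = "-OI") {
  stopifnot(all(c("condition", "day") %in% names(wells)))
  sem <- function(x) if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_
  res <- wells |>
    dplyr::group_by(.data$condition, .data$day) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_cell_number = mean(.data$cell_number),
      sem_cell_number = sem(.data$cell_number),
      mean_alp_per_cell = mean(.data$alp_per_cell, na.rm = TRUE),
      sem_alp_per_cell = sem(.data$alp_per_cell[!is.na(.data$alp_per_cell)]),
      pct_ki67 = if (all(is.na(.data$ki67_fraction))) NA_real_ else {
        100 * sum(.data$ki67_fraction * .data$cell_number, na.rm = TRUE) /
          sum(.data$cell_number[!is.na(.data$ki67_fraction)])
      },
      .groups = "drop"
    )
  ref <- res |>
    dplyr::filter(.data$condition == reference) |>
    dplyr::select("day", ref_alp = "mean_alp_per_cell")
  res |>
    dplyr::left_join(ref, by = "day") |>
    dplyr::mutate(alp_fold_change = .data$mean_alp_per_cell / .data$ref_alp) |>
    dplyr::select(-"ref_alp")
}
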
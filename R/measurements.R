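measurement_cols <- c("plate_id", "well", "gene_symbol", "role",
                      "cell_number", "alp_per_cell", "ki67_fraction",
                      "n_fields_used")

#' Write / read well-level measurement tables
#'
#' Measurement tables are comma-separated with the fixed column order
#' `plate_id, well, gene_symbol, role, cell_number, alp_per_cell,
#' ki67_fraction, n_fields_used`. Missing values (e.g. `alp_per_cell` for a
#' well in which no field contained nuclei, or `ki67_fraction` when the Ki67
#' channel was not imaged) are written as empty cells, never as sentinel
#' numbers, so they cannot leak into normalization as fake zeros.
#'
#' @param wells Tibble of well measurements (one row per well).
#' @param path Output (or input) CSV path.
#' @return `write_measurements()` returns `path` invisibly;
#'   `read_measurements()` returns the measurement tibble.
#' @export
write_measurements <- function(wells, path) {
  missing_cols <- setdiff(measurement_cols, names(wells))
  if (length(missing_cols)) {
    stop("measurement table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(wells[measurement_cols], path, na = "")
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement table not found: ", path, call. = FALSE)
  readr::read_csv(path, col_types = readr::cols(
    plate_id = readr::col_character(),
    well = readr::col_character(),
    gene_symbol = readr::col_character(),
    role = readr::col_character(),
    cell_number = readr::col_double(),
    alp_per_cell = readr::col_double(),
    ki67_fraction = readr::col_double(),
    n_fields_used = readr::col_integer()
  )) |>
    dplyr::mutate(gene_symbol = dplyr::coalesce(.data$gene_symbol, ""))
}
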
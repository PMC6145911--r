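# Shared fixtures, built in code at test time.

# minimal two-role layout on one plate
tiny_layout <- function(plate_id = "p1") {
  tibble::tibble(
    plate_id = plate_id,
    well = c("A1", "A2", "A3", "B1", "B2", "B3"),
    role = c("non_targeting", "non_targeting", "library",
             "library", "mock", "untreated"),
    gene_symbol = c("", "", "Hgf", "Sp7", "", ""),
    n_fields_expected = 3L,
    replicate_group = "rg"
  )
}

# transfection-QC layout: kif11 wells vs mock wells, no library genes
qc_layout <- function(n_each = 6, n_fields = 2L) {
  tibble::tibble(
    plate_id = "qc",
    well = c(sprintf("A%d", seq_len(n_each)), sprintf("B%d", seq_len(n_each))),
    role = rep(c("kif11_control", "mock"), each = n_each),
    gene_symbol = rep(c("Kif11", ""), each = n_each),
    n_fields_expected = n_fields,
    replicate_group = "qc"
  )
}

# simulator settings for small rendered fixtures with well-separated,
# in-range, high-SNR objects (counts must match ground truth exactly)
fixture_config <- function(seed, n_wells_cells = 60, n_fields = 2L,
                           image_size = c(200L, 260L), ...) {
  simulation_config(
    baseline_cells_per_well = n_fields * n_wells_cells / 0.8,
    n_fields = n_fields,
    image_size_px = image_size,
    spot_intensity_mean = 20000,
    spots_per_cell_mean = 2,
    spot_diameter_um = c(1.5, 4),
    spots_nonoverlapping = TRUE,
    read_noise_sd = 4,
    background_level = 100,
    seed = seed,
    ...
  )
}

# detection parameters matched to the fixture intensity scale: the spot peak
# threshold of the round-object route is an instrument-scale quantity
fixture_params <- function(mode) {
  detection_params(mode = mode, spot_intensity_threshold_au = 100)
}

# paint a raised-cosine disk directly (independent of the package renderer)
paint_disk <- function(img, x, y, r, peak) {
  d <- sqrt(outer((seq_len(nrow(img)) - 1 - y)^2,
                  (seq_len(ncol(img)) - 1 - x)^2, `+`))
  v <- ifelse(d <= r - 1, 1, ifelse(d < r, 0.5 * (1 + cos(pi * (d - (r - 1)))), 0))
  img + v * peak
}

# well-measurement row builder
well_row <- function(plate_id, well, role, gene_symbol, cell_number,
                     alp_per_cell, ki67_fraction = NA_real_,
                     n_fields_used = 15L) {
  tibble::tibble(plate_id = plate_id, well = well, gene_symbol = gene_symbol,
                 role = role, cell_number = cell_number,
                 alp_per_cell = alp_per_cell, ki67_fraction = ki67_fraction,
                 n_fields_used = n_fields_used)
}
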
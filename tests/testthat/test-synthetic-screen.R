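test_that("the generator is deterministic given the seed", {
  lay <- qc_layout(n_each = 2)
  cfg <- fixture_config(seed = 3, n_wells_cells = 20)
  a <- simulate_screen(lay, gene_effects(character(0)), cfg) |> suppressWarnings()
  b <- simulate_screen(lay, gene_effects(character(0)), cfg) |> suppressWarnings()
  expect_identical(a$truth$nuclei, b$truth$nuclei)
  expect_identical(a$truth$spots, b$truth$spots)
  expect_identical(a$fields[[1]]$channels$nuclear, b$fields[[1]]$channels$nuclear)
  expect_identical(a$fields[[3]]$channels$elf, b$fields[[3]]$channels$elf)
})

test_that("a null screen without noise reproduces the baseline cell count", {
  lay <- tiny_layout()
  cfg <- simulation_config(baseline_cells_per_well = 300, well_coverage = 1,
                           n_fields = 3, noise_cv = 0, seed = 1)
  fm <- simulate_measurements(lay, gene_effects(c("Hgf", "Sp7")), cfg)
  wells <- aggregate_well(fm)
  expect_true(all(wells$cell_number == 300))
})

test_that("ground truth conserves planted counts and nuclei never overlap", {
  lay <- qc_layout(n_each = 2)
  cfg <- fixture_config(seed = 5, n_wells_cells = 40)
  sim <- simulate_screen(lay, gene_effects(character(0)), cfg,
                         render = FALSE) |> suppressWarnings()
  counts <- dplyr::count(sim$truth$nuclei, plate_id, well, name = "planted")
  joined <- dplyr::left_join(sim$truth$wells, counts,
                             by = c("plate_id", "well"))
  expect_equal(joined$true_cell_count, joined$planted)
  # pairwise non-overlap within every field
  overlaps <- sim$truth$nuclei |>
    dplyr::group_by(well, field) |>
    dplyr::group_map(function(df, key) {
      if (nrow(df) < 2) return(0L)
      d <- as.matrix(stats::dist(cbind(df$x, df$y)))
      rs <- outer(df$radius_px, df$radius_px, `+`)
      sum(d[upper.tri(d)] <= rs[upper.tri(rs)])
    })
  expect_equal(sum(unlist(overlaps)), 0L)
})

test_that("raising alp_fold never lowers a gene's true summed spot intensity", {
  lay <- tibble::tibble(plate_id = "p", well = c("A1", "A2"),
                        role = c("non_targeting", "library"),
                        gene_symbol = c("", "Hgf"),
                        n_fields_expected = 2L, replicate_group = "p")
  prev <- -Inf
  for (fold in c(0.25, 0.5, 1, 2, 4)) {
    cfg <- fixture_config(seed = 11, n_wells_cells = 30)
    sim <- simulate_screen(lay, gene_effects("Hgf", alp_fold = fold), cfg,
                           render = FALSE)
    tot <- sim$truth$wells$true_spot_intensity[sim$truth$wells$well == "A2"]
    expect_gte(tot, prev)
    prev <- tot
  }
})

test_that("rendered fields honour the planted geometry and intensities", {
  cfg <- simulation_config(image_size_px = c(80L, 100L), background_level = 50,
                           read_noise_sd = 0, seed = 1)
  empty <- tibble::tibble(plate_id = "p", well = "A1", field = 0L,
                          nucleus = integer(0), x = numeric(0), y = numeric(0),
                          radius_px = numeric(0), peak_au = numeric(0),
                          ki67_au = numeric(0), ki67_positive = logical(0))
  no_spots <- tibble::tibble(plate_id = character(0), well = character(0),
                             field = integer(0), nucleus = integer(0),
                             x = numeric(0), y = numeric(0),
                             radius_px = numeric(0), intensity = numeric(0))
  fi <- render_field(empty, no_spots, cfg)
  expect_true(all(fi$channels$nuclear == 50))
  expect_true(all(fi$channels$elf == 50))

  # one 10 um nucleus: nuclear channel peaks at its centre
  nuc <- empty
  nuc[1, ] <- list("p", "A1", 0L, 1L, 40, 30, 10 / 2 / cfg$pixel_size_um,
                   2000, NA_real_, NA)
  fi <- render_field(nuc, no_spots, cfg)
  peak_at <- which(fi$channels$nuclear == max(fi$channels$nuclear),
                   arr.ind = TRUE)
  expect_true(any(peak_at[, "row"] == 31 & peak_at[, "col"] == 41))

  # planted summed spot intensity is conserved by the renderer
  cfg0 <- simulation_config(image_size_px = c(80L, 100L), background_level = 0,
                            read_noise_sd = 0, seed = 1)
  spots <- tibble::tibble(plate_id = "p", well = "A1", field = 0L,
                          nucleus = 1L, x = c(20, 60, 45), y = c(20, 50, 65),
                          radius_px = c(2, 1.2, 0.6),
                          intensity = c(1000, 2500, 700))
  fi <- render_field(empty, spots, cfg0)
  expect_equal(sum(fi$channels$elf), sum(spots$intensity), tolerance = 1e-6)
})

test_that("a planted twofold ALP effect is recovered near 200% of control", {
  lay <- tibble::tibble(plate_id = "p",
                        well = c(sprintf("A%d", 1:8), "B1"),
                        role = c(rep("non_targeting", 8), "library"),
                        gene_symbol = c(rep("", 8), "Hgf"),
                        n_fields_expected = 5L, replicate_group = "p")
  cfg <- simulation_config(n_fields = 5, noise_cv = 0.1, n_replicates = 3,
                           seed = 20)
  scr <- simulate_and_analyze(lay, gene_effects("Hgf", alp_fold = 2), cfg)
  # well-level lognormal noise at cv 0.1 over 3 replicates: 3 sd of the
  # mean percent is ~35 percentage points around 200
  expect_lt(abs(scr$results$mean_pct_alp - 200), 35)
})

test_that("field images round-trip through 16-bit TIFF", {
  lay <- qc_layout(n_each = 1, n_fields = 1L)
  cfg <- fixture_config(seed = 9, n_wells_cells = 10, n_fields = 1L,
                        image_size = c(60L, 80L))
  sim <- suppressWarnings(simulate_screen(lay, gene_effects(character(0)), cfg))
  dir <- withr::local_tempdir()
  manifest <- write_field_images(sim$fields, dir)
  expect_equal(nrow(manifest), 2 * 2)  # 2 wells x 2 channels
  f1 <- sim$fields[[1]]
  back <- read_field_channel(file.path(
    dir, sprintf("qc_%s_f0_nuclear.tif", f1$well)))
  expect_equal(dim(back), dim(f1$channels$nuclear))
  # 16-bit quantisation: absolute error bounded by one grey level
  expect_lt(max(abs(back - pmin(f1$channels$nuclear, 65535))), 1.01)
})
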
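#' Simulation configuration for synthetic screens
#'
#' Bundles every parameter of the synthetic-screen generator. The defaults
#' emulate the screening conditions of the assay: 1800 cells seeded per
#' 384-well grown to a differentiation-endpoint population around 3000 cells,
#' 15 fields covering ~80% of the well at a binning-2 pixel size of
#' 1.29 um/px, round nuclei with diameters inside the detectable 4--21.22 um
#' band, punctate ALP spots inside 1.3--8 um, triplicate plates, and a
#' transfection efficiency of 0.75 (the fraction of cells killed in Kif11
#' control wells by day 8).
#'
#' Noise model: per-well multiplicative lognormal noise (mean 1, coefficient
#' of variation `noise_cv`) applied independently to the expected cell number
#' and to the per-spot ALP intensity scale; Poisson cell and spot counts;
#' additive Gaussian read noise on rendered images, clipped at zero. The
#' assay itself reports no quantitative noise model, so `noise_cv` and
#' `read_noise_sd` are stated assumptions, not measured facts. Setting
#' `noise_cv = 0` switches cell counts from Poisson draws to their
#' deterministic expected values, so a null screen reproduces the baseline
#' cell number exactly.
#'
#' @param baseline_cells_per_well Expected endpoint cell population of an
#'   unperturbed well (all fields extrapolated to the full well).
#' @param well_coverage Fraction of the well area covered by the imaged
#'   fields (0.8 for 15 fields).
#' @param n_fields Fields imaged per well.
#' @param n_replicates Replicate plates.
#' @param image_size_px Field raster size as `c(rows, cols)`.
#' @param pixel_size_um Pixel size in micrometres.
#' @param nuclei_diameter_um Range (min, max) of nucleus diameters, um.
#' @param spot_diameter_um Range (min, max) of ALP spot diameters, um.
#' @param spots_per_cell_mean Mean ALP spots per cell (Poisson rate).
#' @param spot_intensity_mean Mean total intensity of one spot, a.u.
#' @param spot_intensity_cv Coefficient of variation of the lognormal
#'   per-spot total intensity.
#' @param spots_nonoverlapping If `TRUE`, spot placement rejection-samples
#'   against previously placed spots so rendered spots never overlap
#'   (useful for fixtures whose detected counts must equal ground truth).
#' @param nucleus_peak_au Mean peak intensity of a nucleus in the nuclear
#'   channel, a.u.
#' @param background_level Constant background level added to every rendered
#'   channel, a.u.
#' @param read_noise_sd SD of additive Gaussian read noise, a.u.
#' @param noise_cv Coefficient of variation of the per-well multiplicative
#'   lognormal noise.
#' @param transfection_efficiency Fraction of cells that take up siRNA; in
#'   `kif11_control` wells the planted viability effect acts only on this
#'   transfected fraction.
#' @param ki67_positive_fraction Fraction of nuclei simulated as
#'   proliferating (Ki67 positive); `NA` disables the Ki67 channel.
#' @param ki67_positive_mean_au,ki67_negative_mean_au Mean nuclear Ki67
#'   intensity of positive and negative nuclei (a.u.); each nucleus's mean is
#'   drawn from a normal with SD 10% of the mean, so the populations are well
#'   separated relative to the 300 a.u. positivity threshold.
#' @param max_placement_tries Rejection-sampling attempts per nucleus before
#'   giving up with an error suggesting a lower density.
#' @param seed Integer seed; all generator output is deterministic given the
#'   seed and inputs.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(baseline_cells_per_well = 3000,
                              well_coverage = 0.8,
                              n_fields = 15L,
                              n_replicates = 3L,
                              image_size_px = c(520L, 696L),
                              pixel_size_um = 1.29,
                              nuclei_diameter_um = c(9, 15),
                              spot_diameter_um = c(2, 6),
                              spots_per_cell_mean = 4,
                              spot_intensity_mean = 800,
                              spot_intensity_cv = 0.5,
                              spots_nonoverlapping = FALSE,
                              nucleus_peak_au = 2000,
                              background_level = 100,
                              read_noise_sd = 10,
                              noise_cv = 0.10,
                              transfection_efficiency = 0.75,
                              ki67_positive_fraction = NA_real_,
                              ki67_positive_mean_au = 800,
                              ki67_negative_mean_au = 50,
                              max_placement_tries = 200L,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    baseline_cells_per_well >= 0, well_coverage >= 0, well_coverage <= 1,
    n_fields >= 1, n_replicates >= 1, length(image_size_px) == 2,
    all(image_size_px > 0), pixel_size_um > 0,
    length(nuclei_diameter_um) == 2, diff(nuclei_diameter_um) > 0,
    nuclei_diameter_um[1] >= 4, nuclei_diameter_um[2] <= 21.22,
    length(spot_diameter_um) == 2, diff(spot_diameter_um) > 0,
    spot_diameter_um[1] >= 1.3, spot_diameter_um[2] <= 8,
    spots_per_cell_mean >= 0, spot_intensity_mean >= 0,
    spot_intensity_cv >= 0,
    background_level >= 0, read_noise_sd >= 0, noise_cv >= 0,
    transfection_efficiency >= 0, transfection_efficiency <= 1,
    is.na(ki67_positive_fraction) ||
      (ki67_positive_fraction >= 0 && ki67_positive_fraction <= 1)
  )
  structure(cfg, class = "simulation_config")
}

#' Per-gene planted effects
#'
#' Ground-truth effect sizes for a synthetic screen: `viability_fraction`
#' scales a gene's expected cell number (1 = no effect) and `alp_fold`
#' scales its expected per-cell ALP activity (1 = no effect).
#'
#' @param gene_symbol Character vector of gene symbols.
#' @param viability_fraction,alp_fold Numeric vectors (recycled) of
#'   multiplicative effects, both >= 0.
#' @return Tibble with columns `gene_symbol`, `viability_fraction`,
#'   `alp_fold`.
#' @export
gene_effects <- function(gene_symbol, viability_fraction = 1, alp_fold = 1) {
  stopifnot(all(viability_fraction >= 0), all(alp_fold >= 0))
  tibble::tibble(gene_symbol = gene_symbol,
                 viability_fraction = as.numeric(viability_fraction),
                 alp_fold = as.numeric(alp_fold))
}

# lognormal multiplier with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# lognormal draws with given means (vector) and common cv
rlnorm_mean_cv <- function(means, cv) {
  if (cv == 0) return(means)
  s <- sqrt(log1p(cv^2))
  stats::rlnorm(length(means), meanlog = log(pmax(means, 1e-12)) - s^2 / 2,
                sdlog = s)
}

# expected-cell multiplier for a well given its role and planted effect;
# in kif11 wells the knockdown only kills the transfected fraction
viability_multiplier <- function(role, viability_fraction, transfection_efficiency) {
  ifelse(role == "kif11_control",
         (1 - transfection_efficiency) +
           transfection_efficiency * viability_fraction,
         viability_fraction)
}

# join layout with effects; control/mock/untreated default to no effect,
# kif11 defaults to viability 0 (complete loss of transfected cells)
resolve_effects <- function(layout, effects) {
  layout <- validate_plate_layout(layout)
  eff <- layout |>
    dplyr::left_join(effects, by = "gene_symbol")
  eff$viability_fraction[is.na(eff$viability_fraction)] <-
    ifelse(eff$role[is.na(eff$viability_fraction)] == "kif11_control", 0, 1)
  eff$alp_fold[is.na(eff$alp_fold)] <- 1
  targeted <- eff$role %in% roles_needing_gene() & eff$role != "kif11_control"
  unresolved <- targeted & !eff$gene_symbol %in% effects$gene_symbol
  if (any(unresolved)) {
    stop("no effect entry for gene(s): ",
         paste(unique(eff$gene_symbol[unresolved]), collapse = ", "),
         call. = FALSE)
  }
  eff
}

#' Simulate field-level measurements directly (no image rendering)
#'
#' Draws per-field nuclei counts and summed ALP spot intensities from the
#' generator's statistical model without placing or rendering any pixels:
#' expected cells per field = `baseline_cells_per_well * well_coverage /
#' n_fields` times the gene's viability multiplier and a per-well lognormal
#' noise factor; nuclei counts are Poisson; spot counts are Poisson with rate
#' `nuclei * spots_per_cell_mean`; the summed spot intensity is a Gamma sum
#' of exponential per-spot intensities with scale `spot_intensity_mean *
#' alp_fold` times an independent per-well lognormal factor. This is the same
#' model the image-rendering path samples from, so measurement-level and
#' image-level simulations are statistically interchangeable; this fast path
#' makes whole-screen power studies tractable.
#'
#' @param layout Plate layout (one or more plates).
#' @param effects Tibble from [gene_effects()].
#' @param config A [simulation_config()].
#' @return Tibble with one row per (plate, well, field): `plate_id`, `well`,
#'   `gene_symbol`, `role`, `field`, `nuclei_count`,
#'   `alp_intensity_in_spots`, `spot_area_px` (NA: nothing was rendered),
#'   `ki67_positive_count`.
#' @export
simulate_measurements <- function(layout, effects, config = simulation_config()) {
  eff <- resolve_effects(layout, effects)
  withr::with_seed(config$seed, {
    cells_per_field <- config$baseline_cells_per_well * config$well_coverage /
      config$n_fields
    n_wells <- nrow(eff)
    u_cells <- rlnorm_cv(n_wells, config$noise_cv)
    u_alp <- rlnorm_cv(n_wells, config$noise_cv)
    viab <- viability_multiplier(eff$role, eff$viability_fraction,
                                 config$transfection_efficiency)
    per_field <- tidyr::expand_grid(
      i = seq_len(n_wells),
      field = seq_len(config$n_fields) - 1L
    )
    lambda <- cells_per_field * viab[per_field$i] * u_cells[per_field$i]
    # noise_cv = 0 turns the generator deterministic at the count level: a
    # null screen then reproduces the baseline exactly
    nuclei <- if (config$noise_cv == 0) as.integer(round(lambda)) else
      stats::rpois(nrow(per_field), lambda)
    n_spots <- stats::rpois(nrow(per_field), nuclei * config$spots_per_cell_mean)
    scale <- config$spot_intensity_mean * eff$alp_fold[per_field$i] *
      u_alp[per_field$i]
    # summed per-spot lognormal intensities, exactly as the rendered path
    owner <- rep(seq_along(n_spots), n_spots)
    intens <- rlnorm_mean_cv(scale[owner], config$spot_intensity_cv)
    alp <- numeric(length(n_spots))
    if (length(owner)) {
      sums <- rowsum(intens, owner)
      alp[as.integer(rownames(sums))] <- sums[, 1L]
    }
    ki67 <- if (is.na(config$ki67_positive_fraction)) NA_integer_ else {
      stats::rbinom(nrow(per_field), nuclei, config$ki67_positive_fraction)
    }
    tibble::tibble(
      plate_id = eff$plate_id[per_field$i],
      well = eff$well[per_field$i],
      gene_symbol = eff$gene_symbol[per_field$i],
      role = eff$role[per_field$i],
      field = per_field$field,
      nuclei_count = nuclei,
      alp_intensity_in_spots = alp,
      spot_area_px = NA_real_,
      ki67_positive_count = ki67
    )
  })
}

# place n non-overlapping circles (radii r, px) in an nr x nc image.
# 0-based pixel-centre coordinates; bounded rejection sampling.
place_nuclei <- function(n, r, nr, nc, max_tries) {
  if (n == 0L) return(tibble::tibble(x = numeric(0), y = numeric(0)))
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- stats::runif(1, r[i], nc - 1 - r[i])
      y <- stats::runif(1, r[i], nr - 1 - r[i])
      if (i == 1L ||
          all((xs[seq_len(i - 1)] - x)^2 + (ys[seq_len(i - 1)] - y)^2 >
              (r[seq_len(i - 1)] + r[i] + 2)^2)) {
        xs[i] <- x; ys[i] <- y; placed <- TRUE; break
      }
    }
    if (!placed) {
      stop("could not place ", n, " non-overlapping nuclei in a ",
           nr, "x", nc, " field after ", max_tries,
           " tries; lower the cell density or enlarge the field",
           call. = FALSE)
    }
  }
  tibble::tibble(x = xs, y = ys)
}

# geometric ground truth for one field of one well
simulate_field_geometry <- function(plate_id, well, field, role, viab_mult,
                                    alp_scale, config) {
  nr <- config$image_size_px[1]; nc <- config$image_size_px[2]
  cells_per_field <- config$baseline_cells_per_well * config$well_coverage /
    config$n_fields
  n <- if (config$noise_cv == 0) as.integer(round(cells_per_field * viab_mult))
  else stats::rpois(1, cells_per_field * viab_mult)
  diam <- stats::runif(n, config$nuclei_diameter_um[1], config$nuclei_diameter_um[2])
  r_px <- diam / 2 / config$pixel_size_um
  pos <- place_nuclei(n, r_px, nr, nc, config$max_placement_tries)
  ki67_pos <- if (is.na(config$ki67_positive_fraction)) rep(NA, n) else {
    stats::runif(n) < config$ki67_positive_fraction
  }
  ki67_au <- ifelse(is.na(ki67_pos), NA_real_,
                    ifelse(ki67_pos,
                           stats::rnorm(n, config$ki67_positive_mean_au,
                                        0.1 * config$ki67_positive_mean_au),
                           stats::rnorm(n, config$ki67_negative_mean_au,
                                        0.1 * config$ki67_negative_mean_au)))
  nuclei <- tibble::tibble(
    plate_id = plate_id, well = well, field = field,
    nucleus = seq_len(n), x = pos$x, y = pos$y, radius_px = r_px,
    peak_au = config$nucleus_peak_au * stats::runif(n, 0.8, 1.2),
    ki67_au = pmax(ki67_au, 0), ki67_positive = ki67_pos
  )
  # perinuclear spots: Poisson count per cell, lognormal total intensity
  n_spots_per <- stats::rpois(n, config$spots_per_cell_mean)
  tot <- sum(n_spots_per)
  owner <- rep(seq_len(n), n_spots_per)
  sd_px <- config$spot_diameter_um / config$pixel_size_um
  sr <- stats::runif(tot, sd_px[1], sd_px[2]) / 2
  if (config$spots_nonoverlapping && tot > 0L) {
    sx <- numeric(tot); sy <- numeric(tot)
    for (s in seq_len(tot)) {
      ok <- FALSE
      for (try in seq_len(config$max_placement_tries)) {
        ang <- stats::runif(1, 0, 2 * pi)
        # widen the perinuclear search ring as tries accumulate so dense
        # cells can still place all their spots without overlap
        dist <- stats::runif(1, 0, max(nuclei$radius_px[owner[s]] * 1.5, 1) *
                                  (1 + try / 25))
        x <- min(max(nuclei$x[owner[s]] + dist * cos(ang), sr[s] + 0.5),
                 nc - 1.5 - sr[s])
        y <- min(max(nuclei$y[owner[s]] + dist * sin(ang), sr[s] + 0.5),
                 nr - 1.5 - sr[s])
        if (s == 1L ||
            all((sx[seq_len(s - 1)] - x)^2 + (sy[seq_len(s - 1)] - y)^2 >
                (sr[seq_len(s - 1)] + sr[s] + 2)^2)) {
          sx[s] <- x; sy[s] <- y; ok <- TRUE; break
        }
      }
      if (!ok) {
        stop("could not place non-overlapping spots; lower spots_per_cell_mean",
             call. = FALSE)
      }
    }
  } else {
    ang <- stats::runif(tot, 0, 2 * pi)
    dist <- stats::runif(tot, 0, pmax(nuclei$radius_px[owner] * 1.5, 1))
    sx <- pmin(pmax(nuclei$x[owner] + dist * cos(ang), sr + 0.5), nc - 1.5 - sr)
    sy <- pmin(pmax(nuclei$y[owner] + dist * sin(ang), sr + 0.5), nr - 1.5 - sr)
  }
  spots <- tibble::tibble(
    plate_id = plate_id, well = well, field = field,
    nucleus = owner, x = sx, y = sy, radius_px = sr,
    intensity = rlnorm_mean_cv(rep(pmax(alp_scale, 1e-12), tot),
                               config$spot_intensity_cv)
  )
  list(nuclei = nuclei, spots = spots)
}

# raised-cosine-edged disk profile (edge width 1 px), peak value `peak`
disk_profile <- function(d, r, peak) {
  v <- numeric(length(d))
  v[d <= r - 1] <- 1
  edge <- d > r - 1 & d < r
  v[edge] <- 0.5 * (1 + cos(pi * (d[edge] - (r - 1))))
  v * peak
}

# add one disk to `img` (modified copy returned); x,y 0-based
add_disk <- function(img, x, y, r, peak, normalize_sum = NA) {
  # normalized (spot) kernels must always cover at least one pixel centre:
  # sub-pixel radii (1.3 um is one pixel at binning 2) otherwise fall
  # between pixels and the planted intensity would be lost
  if (!is.na(normalize_sum)) r <- max(r, 1)
  nr <- nrow(img); nc <- ncol(img)
  x0 <- max(0L, floor(x - r - 1)); x1 <- min(nc - 1L, ceiling(x + r + 1))
  y0 <- max(0L, floor(y - r - 1)); y1 <- min(nr - 1L, ceiling(y + r + 1))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - y)^2, (xs - x)^2, `+`))
  patch <- disk_profile(d, r, 1)
  if (!is.na(normalize_sum)) {
    s <- sum(patch)
    patch <- if (s > 0) patch * (normalize_sum / s) else patch
  } else {
    patch <- patch * peak
  }
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + patch
  img
}

#' Render one field's ground truth into channel rasters
#'
#' Nuclei are drawn as raised-cosine-edged disks (edge width 1 px) at their
#' planted peak intensity; ALP spots as normalized disk kernels scaled so
#' that the pixel sum of each rendered spot equals its planted total
#' intensity; the optional Ki67 channel draws each nucleus at its planted
#' mean Ki67 intensity. A constant background and additive Gaussian read
#' noise (clipped at 0) finish each channel.
#'
#' @param nuclei,spots Ground-truth tibbles for a single field (as produced
#'   by [simulate_screen()]).
#' @param config A [simulation_config()].
#' @param channels Channels to render, subset of
#'   `c("nuclear", "elf", "ki67")`.
#' @return A `field_image`: list with `plate_id`, `well`, `field`,
#'   `channels` (named list of numeric matrices) and `pixel_size_um`.
#' @export
render_field <- function(nuclei, spots, config = simulation_config(),
                         channels = c("nuclear", "elf")) {
  nr <- config$image_size_px[1]; nc <- config$image_size_px[2]
  out <- list()
  finish <- function(img) {
    img <- img + config$background_level
    if (config$read_noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, config$read_noise_sd)
    }
    pmax(img, 0)
  }
  if ("nuclear" %in% channels) {
    img <- matrix(0, nr, nc)
    for (i in seq_len(nrow(nuclei))) {
      img <- add_disk(img, nuclei$x[i], nuclei$y[i], nuclei$radius_px[i],
                      peak = nuclei$peak_au[i])
    }
    out$nuclear <- finish(img)
  }
  if ("elf" %in% channels) {
    img <- matrix(0, nr, nc)
    for (i in seq_len(nrow(spots))) {
      img <- add_disk(img, spots$x[i], spots$y[i], spots$radius_px[i],
                      peak = NA, normalize_sum = spots$intensity[i])
    }
    out$elf <- finish(img)
  }
  if ("ki67" %in% channels && nrow(nuclei) > 0 && !all(is.na(nuclei$ki67_au))) {
    img <- matrix(0, nr, nc)
    for (i in seq_len(nrow(nuclei))) {
      img <- add_disk(img, nuclei$x[i], nuclei$y[i], nuclei$radius_px[i],
                      peak = nuclei$ki67_au[i])
    }
    out$ki67 <- finish(img)
  } else if ("ki67" %in% channels) {
    out$ki67 <- finish(matrix(0, nr, nc))
  }
  structure(list(plate_id = nuclei$plate_id[1] %||% NA_character_,
                 well = nuclei$well[1] %||% NA_character_,
                 field = nuclei$field[1] %||% NA_integer_,
                 channels = out,
                 pixel_size_um = config$pixel_size_um),
            class = "field_image")
}

#' Simulate a screen: ground truth plus (optionally) rendered field images
#'
#' For every annotated well of `layout` this draws the well's noise factors
#' and expected-cell multiplier (the planted viability effect; in
#' `kif11_control` wells only the transfected fraction is affected), places
#' non-overlapping nuclei and perinuclear ALP spots in each field, and
#' renders the requested channels. Deterministic given the seed in `config`.
#'
#' @inheritParams simulate_measurements
#' @param channels Channels to render.
#' @param render If `FALSE`, skip rasterisation and return geometry only.
#' @return List with `fields` (list of `field_image`, empty when
#'   `render = FALSE`) and `truth`, itself a list of tibbles: `nuclei`,
#'   `spots` (planted geometry) and `wells` (per-well true cell count and
#'   true summed spot intensity).
#' @export
simulate_screen <- function(layout, effects, config = simulation_config(),
                            channels = c("nuclear", "elf"), render = TRUE) {
  eff <- resolve_effects(layout, effects)
  withr::with_seed(config$seed, {
    viab <- viability_multiplier(eff$role, eff$viability_fraction,
                                 config$transfection_efficiency)
    u_cells <- rlnorm_cv(nrow(eff), config$noise_cv)
    u_alp <- rlnorm_cv(nrow(eff), config$noise_cv)
    all_nuclei <- vector("list", nrow(eff) * config$n_fields)
    all_spots <- vector("list", nrow(eff) * config$n_fields)
    fields <- list()
    k <- 0L
    for (i in seq_len(nrow(eff))) {
      for (f in seq_len(config$n_fields) - 1L) {
        k <- k + 1L
        geo <- simulate_field_geometry(
          eff$plate_id[i], eff$well[i], f, eff$role[i],
          viab[i] * u_cells[i],
          config$spot_intensity_mean * eff$alp_fold[i] * u_alp[i],
          config
        )
        all_nuclei[[k]] <- geo$nuclei
        all_spots[[k]] <- geo$spots
        if (render) {
          fields[[k]] <- render_field(geo$nuclei, geo$spots, config, channels)
          # render_field on an empty field loses identifiers; restore them
          fields[[k]]$plate_id <- eff$plate_id[i]
          fields[[k]]$well <- eff$well[i]
          fields[[k]]$field <- f
        }
      }
    }
    nuclei <- dplyr::bind_rows(all_nuclei)
    spots <- dplyr::bind_rows(all_spots)
    wells <- nuclei |>
      dplyr::group_by(.data$plate_id, .data$well) |>
      dplyr::summarise(true_cell_count = dplyr::n(), .groups = "drop") |>
      dplyr::left_join(
        spots |>
          dplyr::group_by(.data$plate_id, .data$well) |>
          dplyr::summarise(true_spot_intensity = sum(.data$intensity),
                           .groups = "drop"),
        by = c("plate_id", "well")
      ) |>
      dplyr::mutate(true_spot_intensity =
                      dplyr::coalesce(.data$true_spot_intensity, 0))
    # wells whose every field drew zero nuclei still belong in the table
    wells <- eff |>
      dplyr::select("plate_id", "well", "gene_symbol", "role") |>
      dplyr::left_join(wells, by = c("plate_id", "well")) |>
      dplyr::mutate(true_cell_count =
                      dplyr::coalesce(.data$true_cell_count, 0L),
                    true_spot_intensity =
                      dplyr::coalesce(.data$true_spot_intensity, 0))
    list(fields = fields,
         truth = list(nuclei = nuclei, spots = spots, wells = wells))
  })
}

#' Write / read field images as 16-bit TIFF
#'
#' One file per channel per field, named
#' `{plate}_{well}_f{field}_{channel}.tif`. Intensities are stored as 16-bit
#' unsigned values (clipped at 65535); ground truth should be kept alongside
#' as CSV if needed.
#'
#' @param fields List of `field_image` objects.
#' @param dir Output directory (created if missing).
#' @return Tibble manifest of written files, invisibly.
#' @export
write_field_images <- function(fields, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map_dfr(fields, function(fi) {
    purrr::map_dfr(names(fi$channels), function(ch) {
      fn <- sprintf("%s_%s_f%d_%s.tif", fi$plate_id, fi$well, fi$field, ch)
      img <- pmin(pmax(fi$channels[[ch]], 0), 65535) / 65535
      tiff::writeTIFF(img, file.path(dir, fn), bits.per.sample = 16L)
      tibble::tibble(plate_id = fi$plate_id, well = fi$well,
                     field = fi$field, channel = ch, file = fn)
    })
  })
  invisible(rows)
}

#' @param path Path to a single-channel TIFF written by
#'   [write_field_images()].
#' @rdname write_field_images
#' @return `read_field_channel()` returns a numeric matrix in a.u.
#' @export
read_field_channel <- function(path) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * 65535
}
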
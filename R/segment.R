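#' Detection parameters for segmentation and spot detection
#'
#' Two operator sets are supported, mirroring the two image-analysis routes
#' of the assay. `threshold_pipeline`: adaptive (windowed) Otsu thresholding
#' of the nuclear channel with watershed splitting of touching nuclei and a
#' nucleus size gate of 4--21.22 um; median-filter background correction of
#' the ELF channel (object size 10, smoothing size 20) followed by automated
#' background global thresholding for spot identification.
#' `round_object_pipeline`: white top-hat background correction (feature
#' size 50 for the nuclear channel, 100 for ELF and Ki67, plus a 10 px
#' top-hat at the spot stage) followed by round-object detection with size
#' limits 4--21.22 um (nuclei, intensity threshold 200 a.u.) and 1.3--8 um
#' (spots, intensity threshold 1000 a.u.). Ki67-positive nuclei are those
#' whose mean nuclear Ki67 intensity exceeds 300 a.u. (strict).
#'
#' Intensity thresholds are in the arbitrary units of the instrument that
#' produced the images; adapt them when image scaling differs.
#'
#' @param mode `"threshold_pipeline"` or `"round_object_pipeline"`.
#' @param nuclei_size_um,spot_size_um Size gates (min, max) in um of
#'   equivalent diameter (diameter of the circle of equal area).
#' @param nuclei_intensity_threshold_au,spot_intensity_threshold_au Minimum
#'   component peak intensity (a.u.) in round-object detection. Peak (not
#'   mean) semantics are an assumption; the source route does not state
#'   which is used.
#' @param median_object_size,median_smoothing_size Median-filter background
#'   correction parameters (px).
#' @param tophat_feature_size Named vector of top-hat feature sizes (px) per
#'   stage: `nuclear`, `elf`, `ki67`, `spot`.
#' @param ki67_positive_threshold_au Mean-intensity positivity cut (a.u.).
#' @param otsu_window_px Window of the adaptive Otsu (px); windows whose
#'   intensity range is below `otsu_contrast_frac` of the global range fall
#'   back to the global Otsu threshold.
#' @param otsu_contrast_frac Low-contrast fallback fraction.
#' @param split_touching Split touching nuclei by distance-transform
#'   watershed (threshold pipeline).
#' @param watershed_tolerance Minimum object-height separation for the
#'   watershed split.
#' @param background_mode_multiplier Global background threshold = this
#'   multiplier times the mode of the smoothed intensity histogram.
#' @param noise_floor_sigmas Robust noise floor: thresholds and component
#'   support never drop below this many estimated background SDs (the SD is
#'   estimated from the 0.9 quantile of the zero-clipped corrected image);
#'   keeps read noise from being labeled as objects when the histogram mode
#'   of a background-subtracted image is 0.
#' @param circularity_min Round-object circularity cut,
#'   `4*pi*area/perimeter^2` with a four-direction Crofton boundary-length
#'   estimate; 0.6 by default (the source route names the operator but not
#'   the cut; digital disks score ~0.9, elongated bars well below 0.5).
#' @return List of class `detection_params`.
#' @export
detection_params <- function(mode = c("threshold_pipeline", "round_object_pipeline"),
                             nuclei_size_um = c(4, 21.22),
                             nuclei_intensity_threshold_au = 200,
                             spot_size_um = c(1.3, 8),
                             spot_intensity_threshold_au = 1000,
                             median_object_size = 10,
                             median_smoothing_size = 20,
                             tophat_feature_size = c(nuclear = 50, elf = 100,
                                                     ki67 = 100, spot = 10),
                             ki67_positive_threshold_au = 300,
                             otsu_window_px = 50,
                             otsu_contrast_frac = 0.25,
                             split_touching = TRUE,
                             watershed_tolerance = 1,
                             background_mode_multiplier = 2,
                             noise_floor_sigmas = 6,
                             circularity_min = 0.6) {
  mode <- match.arg(mode)
  p <- as.list(environment())
  stopifnot(nuclei_size_um[1] < nuclei_size_um[2],
            spot_size_um[1] < spot_size_um[2],
            nuclei_intensity_threshold_au >= 0,
            spot_intensity_threshold_au >= 0,
            median_object_size >= 1, median_smoothing_size >= 1,
            all(tophat_feature_size >= 1))
  structure(p, class = "detection_params")
}

# ---- label-map helpers -----------------------------------------------------

new_label_map <- function(labels) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  structure(labels, object_count = max(labels, 0L), class = c("label_map", "matrix"))
}

#' Number of objects in a label map
#' @param labels A label map (integer matrix, 0 = background).
#' @return Integer object count.
#' @export
label_count <- function(labels) {
  oc <- attr(labels, "object_count")
  if (is.null(oc)) max(as.integer(labels), 0L) else oc
}

# keep a subset of labels, relabeling consecutively 1..n
filter_labels <- function(labels, keep) {
  n <- max(as.integer(labels), 0L)
  map <- integer(n + 1L)
  map[which(keep) + 1L] <- seq_len(sum(keep))
  new_label_map(matrix(map[as.integer(labels) + 1L], nrow(labels), ncol(labels)))
}

label_areas <- function(labels) {
  n <- max(as.integer(labels), 0L)
  if (n == 0L) return(integer(0))
  tabulate(as.integer(labels)[as.integer(labels) > 0L], nbins = n)
}

# boundary length per label: Crofton estimate from boundary crossings in
# four directions (axis-aligned and diagonal), accurate for digital disks
# (~4% high) and rectangles (~8% low) alike
label_perimeters <- function(labels) {
  L <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  n <- max(L, 0L)
  if (n == 0L) return(numeric(0))
  nr <- nrow(L); nc <- ncol(L)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- L
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  cross <- function(shifts) {
    tot <- integer(n)
    for (sh in shifts) {
      nb <- pad[(2:(nr + 1L)) + sh[1L], (2:(nc + 1L)) + sh[2L]]
      diffs <- core > 0L & nb != core
      tot <- tot + tabulate(core[diffs], nbins = n)
    }
    tot
  }
  axis_cross <- cross(list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L)))
  diag_cross <- cross(list(c(1L, 1L), c(-1L, -1L), c(1L, -1L), c(-1L, 1L)))
  pi / 8 * (axis_cross + diag_cross / sqrt(2))
}

label_max_intensity <- function(labels, img) {
  n <- max(as.integer(labels), 0L)
  if (n == 0L) return(numeric(0))
  idx <- as.integer(labels) > 0L
  vapply(split(as.numeric(img)[idx], as.integer(labels)[idx]), max, numeric(1))[
    as.character(seq_len(n))] |> unname()
}

equivalent_diameter_um <- function(area_px, pixel_size_um) {
  2 * sqrt(area_px / pi) * pixel_size_um
}

# robust background-noise SD of a zero-clipped, background-subtracted image:
# q90 of max(N(0, sigma), 0) is 1.2816 sigma; sparse bright objects barely
# move the 0.9 quantile
estimate_noise_sd <- function(img) {
  as.numeric(stats::quantile(img, 0.9, names = FALSE)) / 1.2816
}

# run an EBImage op that expects intensities in [0, 1]
with_unit_scale <- function(img, f) {
  m <- max(img)
  if (m <= 0) return(img)
  f(img / m) * m
}

# ---- operators -------------------------------------------------------------

#' Segment nuclei by adaptive Otsu thresholding
#'
#' Foreground is taken above a windowed Otsu threshold (window
#' `otsu_window_px`; low-contrast windows fall back to the global Otsu
#' threshold), holes are filled, touching nuclei are optionally split by a
#' distance-transform watershed, and connected components whose equivalent
#' diameter falls outside `nuclei_size_um` are discarded. A constant image
#' has no threshold and yields zero objects (not an error).
#'
#' @param img Nuclear-channel raster (numeric matrix, a.u., finite, >= 0).
#' @param params A [detection_params()].
#' @param pixel_size_um Pixel size in um.
#' @return A label map (integer matrix; attribute `object_count`).
#' @export
segment_nuclei_otsu <- function(img, params = detection_params(),
                                pixel_size_um) {
  stopifnot(all(is.finite(img)), all(img >= 0))
  rng <- range(img)
  if (diff(rng) <= 0) return(new_label_map(matrix(0L, nrow(img), ncol(img))))
  m <- max(img)
  global_thr <- EBImage::otsu(EBImage::Image(img / m), range = c(0, 1)) * m
  w <- params$otsu_window_px
  nr <- nrow(img); nc <- ncol(img)
  thr <- matrix(global_thr, nr, nc)
  row_breaks <- unique(c(seq(1L, nr, by = w), nr + 1L))
  col_breaks <- unique(c(seq(1L, nc, by = w), nc + 1L))
  for (i in seq_len(length(row_breaks) - 1L)) {
    for (j in seq_len(length(col_breaks) - 1L)) {
      rs <- row_breaks[i]:(row_breaks[i + 1L] - 1L)
      cs <- col_breaks[j]:(col_breaks[j + 1L] - 1L)
      tile <- img[rs, cs, drop = FALSE]
      if (diff(range(tile)) >= params$otsu_contrast_frac * diff(rng)) {
        thr[rs, cs] <- EBImage::otsu(EBImage::Image(tile / m),
                                     range = c(0, 1)) * m
      }
    }
  }
  mask <- img > thr
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  labels <- if (params$split_touching) {
    EBImage::watershed(EBImage::distmap(mask),
                       tolerance = params$watershed_tolerance)
  } else {
    EBImage::bwlabel(mask)
  }
  labels <- new_label_map(matrix(as.integer(labels), nr, nc))
  d_um <- equivalent_diameter_um(label_areas(labels), pixel_size_um)
  filter_labels(labels,
                d_um >= params$nuclei_size_um[1] &
                  d_um <= params$nuclei_size_um[2])
}

#' Median-filter background correction
#'
#' Estimates the background as a median-smoothed image (filter radius
#' `smoothing_size` px, larger than the typical object size so objects do
#' not survive into the estimate) and returns `img - background`, clipped at
#' zero.
#'
#' @param img ELF-channel raster (a.u.).
#' @param object_size Typical object size (px); retained for the record, the
#'   background estimate must simply be smoother than this scale.
#' @param smoothing_size Median filter radius (px).
#' @return Background-corrected raster, same shape, all values >= 0.
#' @export
correct_background_median <- function(img, object_size = 10,
                                      smoothing_size = 20) {
  stopifnot(object_size >= 1, smoothing_size >= 1)
  bg <- with_unit_scale(img, function(x)
    EBImage::medianFilter(x, size = as.integer(smoothing_size)))
  pmax(img - bg, 0)
}

#' Automated background global thresholding for spot detection
#'
#' A single global threshold is estimated from the background mode of the
#' (background-corrected) image: `background_mode_multiplier` times the mode
#' of its 256-bin intensity histogram, floored at `noise_floor_sigmas` times
#' the robust background-noise SD. Connected components strictly above the
#' threshold become spots; no size filtering is applied in this mode.
#'
#' @param img Background-corrected ELF raster.
#' @param params A [detection_params()].
#' @return A label map of detected spots.
#' @export
detect_spots_background_global <- function(img, params = detection_params()) {
  m <- max(img)
  if (m <= 0) return(new_label_map(matrix(0L, nrow(img), ncol(img))))
  h <- graphics::hist(as.numeric(img), breaks = seq(0, m, length.out = 257L),
                      plot = FALSE)
  mode_val <- h$mids[which.max(h$counts)]
  thr <- max(params$background_mode_multiplier * mode_val,
             params$noise_floor_sigmas * estimate_noise_sd(img))
  new_label_map(matrix(as.integer(EBImage::bwlabel(img > thr)),
                       nrow(img), ncol(img)))
}

#' White top-hat background correction
#'
#' White top-hat (image minus its morphological opening) with a disc
#' structuring element of diameter `feature_size` px; flat or slowly varying
#' background is removed, objects smaller than the feature size are kept.
#' Output is non-negative by construction. The image is reflected by
#' `feature_size` pixels at its borders before the morphology so border
#' pixels are treated like interior ones.
#'
#' @param img Raster (a.u.).
#' @param feature_size Structuring-element diameter (px); rounded up to odd.
#' @return Corrected raster, same shape.
#' @export
tophat_correct <- function(img, feature_size) {
  stopifnot(feature_size >= 1)
  k <- as.integer(feature_size)
  if (k %% 2L == 0L) k <- k + 1L
  brush <- EBImage::makeBrush(max(k, 3L), shape = "disc")
  pad <- k
  nr <- nrow(img); nc <- ncol(img)
  ridx <- c(pmin(pad:1, nr), 1:nr, nr + 1L - pmin(1:pad, nr))
  cidx <- c(pmin(pad:1, nc), 1:nc, nc + 1L - pmin(1:pad, nc))
  padded <- img[ridx, cidx]
  out <- with_unit_scale(padded, function(x) EBImage::whiteTopHat(x, brush))
  pmax(out[pad + (1:nr), pad + (1:nc)], 0)
}

#' Round-object detection
#'
#' Identifies connected components supported above a robust noise floor and
#' keeps those whose peak intensity reaches `intensity_threshold_au`, whose
#' equivalent diameter lies within `size_um_range`, and whose circularity
#' (`4*pi*area/perimeter^2`, boundary length from a four-direction Crofton
#' estimate) is at least `circularity_min`. Intended for
#' background-corrected images.
#'
#' @param img Background-corrected raster.
#' @param size_um_range Equivalent-diameter gate (min, max), um.
#' @param intensity_threshold_au Minimum component peak intensity, a.u.
#' @param pixel_size_um Pixel size in um.
#' @param params A [detection_params()] (supplies the circularity cut and
#'   noise floor).
#' @return A label map of accepted objects.
#' @export
detect_round_objects <- function(img, size_um_range, intensity_threshold_au,
                                 pixel_size_um, params = detection_params()) {
  if (max(img) <= 0) return(new_label_map(matrix(0L, nrow(img), ncol(img))))
  floor_thr <- params$noise_floor_sigmas * estimate_noise_sd(img)
  labels <- new_label_map(matrix(as.integer(EBImage::bwlabel(img > floor_thr)),
                                 nrow(img), ncol(img)))
  if (label_count(labels) == 0L) return(labels)
  areas <- label_areas(labels)
  d_um <- equivalent_diameter_um(areas, pixel_size_um)
  peak <- label_max_intensity(labels, img)
  per <- label_perimeters(labels)
  circ <- ifelse(per > 0, 4 * pi * areas / per^2, 0)
  filter_labels(labels,
                peak >= intensity_threshold_au &
                  d_um >= size_um_range[1] & d_um <= size_um_range[2] &
                  circ >= params$circularity_min)
}

#' Classify Ki67-positive nuclei
#'
#' A nucleus is Ki67 positive when its mean Ki67 intensity over the
#' nucleus's pixels is strictly greater than the threshold.
#'
#' @param nuclei Label map of segmented nuclei.
#' @param ki67 Ki67-channel raster (same shape; background-corrected or raw,
#'   provided the threshold matches the scale).
#' @param threshold_au Positivity threshold, a.u. (default 300).
#' @return Tibble with one row per nucleus: `nucleus`, `mean_ki67`,
#'   `positive`; attribute `positive_count`.
#' @export
classify_ki67 <- function(nuclei, ki67, threshold_au = 300) {
  stopifnot(all(dim(nuclei) == dim(ki67)))
  n <- label_count(nuclei)
  if (n == 0L) {
    out <- tibble::tibble(nucleus = integer(0), mean_ki67 = numeric(0),
                          positive = logical(0))
    attr(out, "positive_count") <- 0L
    return(out)
  }
  idx <- as.integer(nuclei) > 0L
  means <- vapply(split(as.numeric(ki67)[idx], as.integer(nuclei)[idx]),
                  mean, numeric(1))[as.character(seq_len(n))]
  out <- tibble::tibble(nucleus = seq_len(n), mean_ki67 = unname(means),
                        positive = unname(means) > threshold_au)
  attr(out, "positive_count") <- sum(out$positive)
  out
}

#' Segment one field with either operator set
#'
#' Dispatches on `params$mode`: the threshold pipeline (adaptive Otsu nuclei
#' + median background correction + background global spot threshold) or the
#' round-object pipeline (top-hat corrections + round-object detection for
#' nuclei and spots). If the field carries a Ki67 channel, nuclei are also
#' classified for Ki67 positivity.
#'
#' @param field A `field_image` (see [simulate_screen()]) or a named list of
#'   channel matrices plus `pixel_size_um`.
#' @param params A [detection_params()].
#' @return List with `nuclei` and `spots` label maps, `elf_corrected`
#'   raster, and `ki67` classification tibble (or `NULL`).
#' @export
segment_field <- function(field, params = detection_params()) {
  ch <- field$channels
  px <- field$pixel_size_um
  stopifnot(!is.null(ch$nuclear), !is.null(ch$elf), is.numeric(px), px > 0)
  fs <- params$tophat_feature_size
  if (params$mode == "threshold_pipeline") {
    nuclei <- segment_nuclei_otsu(ch$nuclear, params, px)
    elf_corr <- correct_background_median(ch$elf, params$median_object_size,
                                          params$median_smoothing_size)
    spots <- detect_spots_background_global(elf_corr, params)
    ki <- if (!is.null(ch$ki67)) {
      classify_ki67(nuclei, ch$ki67, params$ki67_positive_threshold_au)
    }
  } else {
    nuc_corr <- tophat_correct(ch$nuclear, fs[["nuclear"]])
    nuclei <- detect_round_objects(nuc_corr, params$nuclei_size_um,
                                   params$nuclei_intensity_threshold_au,
                                   px, params)
    elf_corr <- tophat_correct(ch$elf, fs[["elf"]])
    spot_stage <- tophat_correct(elf_corr, fs[["spot"]])
    spots <- detect_round_objects(spot_stage, params$spot_size_um,
                                  params$spot_intensity_threshold_au,
                                  px, params)
    ki <- if (!is.null(ch$ki67)) {
      classify_ki67(nuclei, tophat_correct(ch$ki67, fs[["ki67"]]),
                    params$ki67_positive_threshold_au)
    }
  }
  list(nuclei = nuclei, spots = spots, elf_corrected = elf_corr, ki67 = ki)
}
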
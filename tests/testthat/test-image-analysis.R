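px <- 1.29  # um per pixel used throughout these fixtures

test_that("adaptive Otsu segmentation counts planted nuclei and gates size", {
  # constant image: no threshold exists, zero objects, no error
  const <- matrix(100, 120, 150)
  expect_equal(label_count(segment_nuclei_otsu(const, pixel_size_um = px)), 0)

  # 5 well-separated 10 um disks on flat background
  img <- matrix(100, 120, 150)
  centers <- cbind(x = c(25, 70, 120, 40, 100), y = c(25, 30, 40, 85, 90))
  r <- 10 / 2 / px
  for (i in 1:5) img <- paint_disk(img, centers[i, 1], centers[i, 2], r, 2000)
  lab <- segment_nuclei_otsu(img, pixel_size_um = px)
  expect_equal(label_count(lab), 5)

  # sub-range disks (2 um < 4 um minimum) are discarded, valid ones kept
  img2 <- matrix(100, 120, 150)
  for (i in 1:3) img2 <- paint_disk(img2, centers[i, 1], centers[i, 2], r, 2000)
  img2 <- paint_disk(img2, 40, 85, 2 / 2 / px, 2000)
  img2 <- paint_disk(img2, 100, 90, 2 / 2 / px, 2000)
  expect_equal(label_count(segment_nuclei_otsu(img2, pixel_size_um = px)), 3)
})

test_that("median background correction removes background, keeps impulses", {
  const <- matrix(37.5, 60, 80)
  expect_true(all(correct_background_median(const) == 0))

  # impulse of height h on constant background survives within 5%
  h <- 5000
  img <- matrix(200, 60, 80)
  img[30, 40] <- 200 + h
  out <- correct_background_median(img)
  expect_gt(out[30, 40], 0.95 * h)
  expect_lt(out[30, 40], 1.05 * h)

  # clipping contract
  noisy <- matrix(stats::rnorm(60 * 80, 100, 30), 60, 80)
  expect_gte(min(correct_background_median(abs(noisy))), 0)
})

test_that("background global thresholding finds planted spots", {
  expect_equal(label_count(detect_spots_background_global(matrix(0, 50, 60))), 0)

  # 20 spots, zero background
  img <- matrix(0, 150, 180)
  set.seed(1)
  pos <- expand.grid(x = seq(15, 165, by = 30), y = seq(15, 135, by = 30))[1:20, ]
  for (i in 1:20) img <- paint_disk(img, pos$x[i], pos$y[i], 2, 800)
  expect_equal(label_count(detect_spots_background_global(img)), 20)

  # the threshold is a global statistic: translation leaves counts unchanged
  shifted <- img[c(11:150, 1:10), ]
  expect_equal(label_count(detect_spots_background_global(shifted)), 20)
})

test_that("white top-hat removes flat and ramp background, is near-idempotent", {
  const <- matrix(250, 70, 90)
  expect_true(all(tophat_correct(const, 15) == 0))

  # slow ramp + small bright disk: ramp suppressed below 5% of disk peak
  ramp <- outer(rep(1, 70), seq(0, 100, length.out = 90))
  img <- paint_disk(ramp, 45, 35, 3, 4000)
  out <- tophat_correct(img, 15)
  disk_peak <- max(out)
  away <- out
  away[max(1, 35 - 10):min(70, 35 + 12), max(1, 45 - 8):min(90, 45 + 12)] <- 0
  expect_lt(max(away), 0.05 * disk_peak)

  # applying the filter twice changes little
  out2 <- tophat_correct(out, 15)
  expect_lt(max(abs(out2 - out)), 0.01 * max(out))
})

test_that("round-object detection gates size, intensity and circularity", {
  params <- detection_params(mode = "round_object_pipeline")

  # 1.0 um disk below the 1.3 um spot minimum is rejected
  small <- paint_disk(matrix(0, 60, 80), 40, 30, 1.0 / 2 / px, 3000)
  expect_equal(label_count(
    detect_round_objects(small, c(1.3, 8), 1000, px, params)), 0)

  # peak 150 below a 200 a.u. threshold is rejected; raising the peak passes
  dim_disk <- paint_disk(matrix(0, 60, 80), 40, 30, 10 / 2 / px, 150)
  expect_equal(label_count(
    detect_round_objects(dim_disk, c(4, 21.22), 200, px, params)), 0)
  bright <- paint_disk(matrix(0, 60, 80), 40, 30, 10 / 2 / px, 300)
  expect_equal(label_count(
    detect_round_objects(bright, c(4, 21.22), 200, px, params)), 1)

  # elongated bar with the same area as a valid disk fails circularity
  disk <- paint_disk(matrix(0, 60, 80), 40, 30, 4, 3000)
  disk_area <- sum(disk > 0)
  bar <- matrix(0, 60, 80)
  w <- 3
  len <- ceiling(disk_area / w)
  bar[29:(29 + w - 1), 10:(10 + len - 1)] <- 3000
  d_um_range <- c(0.5, 40)  # wide gate so only circularity can reject
  expect_equal(label_count(
    detect_round_objects(bar, d_um_range, 1000, px, params)), 0)
  expect_equal(label_count(
    detect_round_objects(disk, d_um_range, 1000, px, params)), 1)
})

test_that("Ki67 classification uses strict mean-intensity thresholding", {
  nuclei <- matrix(0L, 40, 50)
  nuclei[5:10, 5:10] <- 1L
  nuclei[20:25, 20:25] <- 2L
  nuclei <- structure(nuclei, object_count = 2L)

  zero <- matrix(0, 40, 50)
  expect_equal(attr(classify_ki67(nuclei, zero), "positive_count"), 0L)

  # uniform 301 vs threshold 300 is positive (strict >); 300 itself is not
  ki <- matrix(0, 40, 50)
  ki[5:10, 5:10] <- 301
  ki[20:25, 20:25] <- 300
  res <- classify_ki67(nuclei, ki, threshold_au = 300)
  expect_identical(res$positive, c(TRUE, FALSE))

  empty <- structure(matrix(0L, 40, 50), object_count = 0L)
  expect_equal(attr(classify_ki67(empty, ki), "positive_count"), 0L)
})

test_that("a planted Ki67-positive fraction is recovered exactly", {
  lay <- tibble::tibble(plate_id = "p", well = "A1", role = "mock",
                        gene_symbol = "", n_fields_expected = 2L,
                        replicate_group = "p")
  cfg <- fixture_config(seed = 13, n_wells_cells = 40,
                        ki67_positive_fraction = 0.4)
  sim <- suppressWarnings(simulate_screen(lay, gene_effects(character(0)), cfg,
                          channels = c("nuclear", "elf", "ki67")))
  planted <- sum(sim$truth$nuclei$ki67_positive)
  detected <- 0L
  for (fi in sim$fields) {
    seg <- segment_field(fi, fixture_params("threshold_pipeline"))
    detected <- detected + attr(seg$ki67, "positive_count")
  }
  expect_equal(detected, planted)
})

test_that("label maps partition the foreground disjointly", {
  img <- matrix(100, 100, 120)
  set.seed(4)
  for (i in 1:6) {
    img <- paint_disk(img, stats::runif(1, 15, 105), stats::runif(1, 15, 85),
                      10 / 2 / px, 2000)
  }
  lab <- segment_nuclei_otsu(img, pixel_size_um = px)
  n <- label_count(lab)
  expect_identical(sort(unique(as.integer(lab))), c(0L, seq_len(n)))
})

test_that("intensity scaling is equivariant for zero-background spot images", {
  img <- matrix(0, 90, 110)
  set.seed(2)
  for (i in 1:8) {
    img <- paint_disk(img, stats::runif(1, 10, 100), stats::runif(1, 10, 80),
                      2, 1500)
  }
  lab1 <- detect_spots_background_global(img)
  lab2 <- detect_spots_background_global(img * 3)
  expect_equal(label_count(lab1), label_count(lab2))
  m1 <- measure_field(lab1, lab1, img)
  m2 <- measure_field(lab2, lab2, img * 3)
  expect_equal(m2$alp_intensity_in_spots, 3 * m1$alp_intensity_in_spots)
})
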
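test_that("fractional shortening implements both denominator conventions", {
  expect_equal(fractional_shortening(100, 100), 0)
  expect_equal(fractional_shortening(100, 100, "standard"), 0)
  expect_equal(fractional_shortening(110, 100), 10)
  expect_equal(fractional_shortening(110, 100, "standard"), 10 / 110 * 100)
  expect_equal(fractional_shortening(120, 80), 50)
  expect_error(fractional_shortening(-1, 100), "positive")
})

test_that("ellipsoid volume matches closed forms and the sphere limit", {
  expect_equal(ellipsoid_volume(2, 1), pi / 3)
  expect_equal(ellipsoid_volume(2, 1, include_pi = FALSE), 1 / 3)
  d <- 7.3
  expect_equal(ellipsoid_volume(d, d), pi / 6 * d^3)
  expect_error(ellipsoid_volume(0, 1), "positive")
})

test_that("ellipsoid volume agrees with a voxel-counting oracle to 1%", {
  expect_equal(ellipsoid_volume(300, 150),
               voxel_ellipsoid_volume(300, 150, h = 0.5),
               tolerance = 0.01)
  set.seed(8)
  for (i in 1:5) {
    dl <- runif(1, 60, 350)
    ds <- runif(1, 40, dl)
    expect_equal(ellipsoid_volume(dl, ds), voxel_ellipsoid_volume(dl, ds, 0.5),
                 tolerance = 0.01)
  }
})

test_that("ellipsoid volume is monotone in each axis and cubic under scaling", {
  expect_lt(ellipsoid_volume(100, 50), ellipsoid_volume(110, 50))
  expect_lt(ellipsoid_volume(100, 50), ellipsoid_volume(100, 55))
  expect_equal(ellipsoid_volume(2 * 123, 2 * 77), 8 * ellipsoid_volume(123, 77))
})

test_that("stroke volume, ejection fraction and cardiac output compose", {
  expect_equal(stroke_volume(100, 100), 0)
  expect_equal(stroke_volume(100, 40), 60)
  expect_warning(sv_neg <- stroke_volume(40, 100), "negative stroke volume")
  expect_equal(sv_neg, -60)

  edv <- ellipsoid_volume(300, 150)
  esv <- ellipsoid_volume(280, 120)
  expect_equal(stroke_volume(edv, esv), edv - esv)

  expect_equal(ejection_fraction(100, 100), 100)
  expect_equal(ejection_fraction(40, 100), 40)
  expect_error(ejection_fraction(10, 0), "edv")

  expect_equal(cardiac_output(0, 600), 0)
  expect_equal(cardiac_output(5e5, 600), 3e8)            # 300 nL/min
  expect_equal(cardiac_output(5e5, 300), 3e8 / 2)        # linear in rate
})

test_that("ef stays within [0, 100] whenever esv <= edv", {
  set.seed(12)
  for (i in 1:50) {
    edv <- runif(1, 1e5, 5e6)
    esv <- runif(1, 0, edv)
    ef <- ejection_fraction(suppressWarnings(stroke_volume(edv, esv)), edv)
    expect_gte(ef, 0)
    expect_lte(ef, 100)
  }
})

test_that("heart_geometry validates inputs and warns on swapped phases", {
  g <- heart_geometry(300, 150, 280, 120)
  expect_s3_class(g, "heart_geometry")
  expect_warning(heart_geometry(300, 120, 280, 150), "exceeds diastolic")
  expect_error(heart_geometry(300, -1, 280, 120), "positive")
})

test_that("cardiac_metrics composes the endpoint set consistently", {
  g <- heart_geometry(300, 150, 280, 120)
  cm <- cardiac_metrics(g, hr_bpm = 600)
  expect_equal(cm$sv_um3, cm$edv_um3 - cm$esv_um3)
  expect_equal(cm$ef_pct, cm$sv_um3 / cm$edv_um3 * 100)
  expect_equal(cm$co_um3_min, cm$sv_um3 * 600)
  expect_equal(cm$co_nl_min, cm$co_um3_min / 1e6)
  expect_equal(cm$fs_pct, (150 - 120) / 120 * 100)

  cm_lit <- cardiac_metrics(g, 600, include_pi = FALSE)
  expect_equal(cm_lit$edv_um3, ellipsoid_volume(300, 150, FALSE))
  expect_equal(cm_lit$ef_pct, cm$ef_pct)  # constant cancels in the ratio
})

test_that("diameters are recovered from a synthetic beating heart within 5%", {
  sim <- simulate_heart(duration_s = 3, seed = 5)
  b <- detect_beats(extract_trace(sim$stack))
  g <- measure_diameters(sim$stack, sim$truth$roi, b)
  expect_equal(g$dl_d, 300, tolerance = 0.05)
  expect_equal(g$ds_d, 150, tolerance = 0.05)
  expect_equal(g$dl_s, 280, tolerance = 0.05)
  expect_equal(g$ds_s, 120, tolerance = 0.05)
})

test_that("a static heart yields near-zero fractional shortening", {
  sim <- simulate_heart(duration_s = 3, dl_s = 299.5, ds_s = 149.5, seed = 9)
  # beats are barely visible; use truth beat times to pick frames
  b <- structure(list(beat_times = sim$truth$beat_times,
                      intervals = diff(sim$truth$beat_times),
                      rates_bpm = 60 / diff(sim$truth$beat_times),
                      fps = 200, duration_s = 3,
                      params = list()), class = "beat_series")
  g <- suppressWarnings(suppressMessages(
    measure_diameters(sim$stack, sim$truth$roi, b)))
  expect_equal(g$dl_d, g$dl_s, tolerance = 0.01)
  fs <- fractional_shortening(max(g$ds_d, g$ds_s), min(g$ds_d, g$ds_s))
  expect_lt(fs, 2)
})

test_that("an empty ROI is reported as not segmentable", {
  frames <- array(30000, dim = c(40, 40, 600))
  frames <- frames + array(rnorm(length(frames), 0, 2), dim = dim(frames))
  stack <- frame_stack(frames, fps = 200, pixel_size_um = 2)
  b <- structure(list(beat_times = seq(0.2, 2.8, by = 0.1),
                      intervals = rep(0.1, 26), rates_bpm = rep(600, 26),
                      fps = 200, duration_s = 3, params = list()),
                 class = "beat_series")
  expect_error(measure_diameters(stack, rect_roi(0, 0, 40, 40), b),
               "heart not segmentable")
})

test_that("manual diameter CSVs are read and averaged per phase", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(
    phase = c("diastole", "diastole", "systole", "systole"),
    dl_um = c(298, 302, 279, 281),
    ds_um = c(149, 151, 119, 121)
  ), path, row.names = FALSE)
  g <- read_diameters(path)
  expect_equal(g$dl_d, 300)
  expect_equal(g$ds_s, 120)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_diameters(bad), "columns")
})

test_that("otsu threshold and component labelling agree with EBImage", {
  skip_if_not_installed("EBImage")
  # crisply bimodal image: both thresholds must land in the gap and induce
  # the same segmentation (between-class variance is flat inside the gap, so
  # exact threshold values may differ)
  set.seed(4)
  img <- matrix(rnorm(400, 0.3, 0.01), 20, 20)
  img[6:15, 6:15] <- rnorm(100, 0.7, 0.01)
  thr <- cladocardio:::otsu_threshold(as.numeric(img))
  thr_eb <- EBImage::otsu(EBImage::Image(img), range = range(img))
  expect_identical(img > thr, img > thr_eb)

  mask <- img > thr
  comp <- cladocardio:::largest_component(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  sizes <- table(lab[lab > 0])
  expect_equal(sum(comp), as.integer(max(sizes)))
})
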
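test_that("a blank frame yields no spots", {
  expect_equal(nrow(detect_spots(matrix(1000, 60, 60))), 0)
})

test_that("a matched-scale blob is found once, within half a pixel", {
  img <- render_blobs(cbind(50, 50), width = 101, height = 101, sigma = 2)
  sp <- detect_spots(img, sigma_px = 2, polarity = "dark")
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$x - 50), 0.5)
  expect_lt(abs(sp$y - 50), 0.5)
  expect_equal(sp$radius_px, sqrt(2) * 2)

  # sub-pixel: fractional true centre recovered to < 0.5 px
  img2 <- render_blobs(cbind(40.3, 55.7), width = 101, height = 101, sigma = 2)
  sp2 <- detect_spots(img2, sigma_px = 2, polarity = "dark")
  expect_equal(nrow(sp2), 1)
  expect_lt(abs(sp2$x - 40.3), 0.5)
  expect_lt(abs(sp2$y - 55.7), 0.5)
})

test_that("nearby blobs at 10+ px separation are not merged", {
  img <- render_blobs(rbind(c(40, 50), c(60, 50)), 101, 101, sigma = 2)
  sp <- detect_spots(img, sigma_px = 2, polarity = "dark")
  expect_equal(nrow(sp), 2)
  expect_equal(sort(round(sp$x)), c(40, 60))

  img3 <- render_blobs(rbind(c(30, 30), c(40, 30), c(30, 40)), 81, 81, sigma = 2)
  expect_equal(nrow(detect_spots(img3, sigma_px = 2, polarity = "dark")), 3)
})

test_that("detection is invariant to constant background and respects polarity", {
  img <- render_blobs(cbind(50, 50), 101, 101, sigma = 2)
  sp0 <- detect_spots(img, sigma_px = 2, polarity = "dark")
  sp1 <- detect_spots(img + 5000, sigma_px = 2, polarity = "dark")
  expect_equal(nrow(sp1), nrow(sp0))
  expect_equal(sp1$x, sp0$x, tolerance = 1e-9)

  bright <- 60000 - img  # invert: blob now brighter than background
  spb <- detect_spots(bright, sigma_px = 2, polarity = "bright")
  expect_equal(nrow(spb), 1)
  expect_lt(abs(spb$x - 50), 0.5)
})

test_that("LoG response of a matched blob is maximal at its centre", {
  img <- render_blobs(cbind(50, 50), 101, 101, sigma = 3)
  resp <- cladocardio:::log_response(img, 3, "dark")
  peak <- which(resp == max(resp), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(51, 51))  # 1-based row/col of (50, 50)
})

test_that("two well-separated constant-velocity particles give two clean tracks", {
  frames <- lapply(0:9, function(k) {
    render_blobs(rbind(c(10 + 2 * k, 20), c(10 + 2 * k, 50)), 60, 70, sigma = 2)
  })
  stack <- frame_stack(frames, fps = 100, pixel_size_um = 1)
  sp <- detect_spots(stack, sigma_px = 2, polarity = "dark")
  tk <- link_tracks(sp, max_disp_px = 5, max_gap = 0, min_track_len = 3)
  expect_equal(dplyr::n_distinct(tk$track), 2)
  steps <- track_steps(tk, pixel_size_um = 1, fps = 100)
  st <- steps$step_speed_um_s[!is.na(steps$step_speed_um_s)]
  expect_equal(st, rep(200, length(st)), tolerance = 0.05)
})

test_that("a one-frame blink is bridged when max_gap allows it", {
  centres <- function(k) cbind(10 + 2 * k, 30)
  frames <- lapply(0:9, function(k) {
    if (k == 5) matrix(30000, 70, 60) else render_blobs(centres(k), 60, 70, 2)
  })
  stack <- frame_stack(frames, fps = 100, pixel_size_um = 1)
  sp <- detect_spots(stack, sigma_px = 2, polarity = "dark")
  tk1 <- link_tracks(sp, max_disp_px = 5, max_gap = 1, min_track_len = 3)
  expect_equal(dplyr::n_distinct(tk1$track), 1)
  expect_equal(nrow(tk1), 9)

  # without gap closing the track splits
  tk0 <- link_tracks(sp, max_disp_px = 5, max_gap = 0, min_track_len = 3)
  expect_equal(dplyr::n_distinct(tk0$track), 2)
})

test_that("tracks terminate rather than swap when displacement exceeds the gate", {
  # two particles approach, then jump past each other by more than the gate
  pos <- list(
    rbind(c(10, 30), c(50, 30)),
    rbind(c(14, 30), c(46, 30)),
    rbind(c(18, 30), c(42, 30)),
    rbind(c(38, 30), c(22, 30))  # +20 / -20 px: beyond gate 8
  )
  frames <- lapply(pos, function(p) render_blobs(p, 70, 60, sigma = 2))
  stack <- frame_stack(frames, fps = 100, pixel_size_um = 1)
  sp <- detect_spots(stack, sigma_px = 2, polarity = "dark")
  tk <- link_tracks(sp, max_disp_px = 8, max_gap = 0, min_track_len = 2)
  # the pre-jump tracks end at frame 3: no track contains a > gate step
  steps <- track_steps(tk, 1, 100)
  disp <- steps$step_speed_um_s / 100
  expect_true(all(disp[!is.na(disp)] <= 8))
})

test_that("velocity summaries pool step speeds with the right calibration", {
  tk <- tibble::tibble(track = 1, frame = 1:5,
                       x = seq(0, 8, by = 2), y = 0)
  vs <- summarize_velocity(tk, pixel_size_um = 1, fps = 200)
  expect_equal(vs$v_max_um_s, 400)
  expect_equal(vs$v_mean_um_s, 400)
  expect_equal(vs$v_min_um_s, 400)
  # doubling the calibration doubles every velocity
  vs2 <- summarize_velocity(tk, pixel_size_um = 2, fps = 200)
  expect_equal(vs2$v_mean_um_s, 2 * vs$v_mean_um_s)
  expect_error(summarize_velocity(tk[0, ], 1, 200), "no trackable cells")
})

test_that("velocity ordering v_min <= v_mean <= v_max holds on random tracks", {
  set.seed(31)
  for (i in 1:20) {
    tk <- tibble::tibble(
      track = rep(1:3, each = 10),
      frame = rep(1:10, 3),
      x = cumsum(runif(30, 0, 3)),
      y = cumsum(runif(30, 0, 1))
    )
    vs <- summarize_velocity(tk, pixel_size_um = 1.5, fps = 100)
    expect_lte(vs$v_min_um_s, vs$v_mean_um_s)
    expect_lte(vs$v_mean_um_s, vs$v_max_um_s)
    expect_gte(vs$v_min_um_s, 0)
  }
})
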
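test_that("poincare handles constant and alternating rhythms", {
  pc <- poincare(rep(0.1, 20))
  expect_equal(pc$sd1, 0)
  expect_equal(pc$sd2, 0)
  expect_equal(pc$n_pairs, 19)

  # alternating 0.09/0.11: successive differences are +/- 0.02 (an odd
  # interval count balances the signs exactly)
  alt <- rep(c(0.09, 0.11), length.out = 51)
  pc2 <- poincare(alt)
  expect_equal(pc2$sd1, 0.02 / sqrt(2), tolerance = 1e-12)

  expect_error(poincare(0.1), ">= 2")
})

test_that("sd1^2 + sd2^2 = 2 * sdnn^2 holds to 1e-9 relative on random sequences", {
  set.seed(123)
  for (i in 1:100) {
    iv <- runif(sample(3:200, 1), 0.05, 0.3)
    pc <- poincare(iv)
    lhs <- pc$sd1^2 + pc$sd2^2
    rhs <- 2 * pc$sdnn^2
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("poincare descriptors are shift-invariant and scale linearly", {
  set.seed(7)
  iv <- runif(60, 0.08, 0.15)
  pc <- poincare(iv)
  shifted <- poincare(iv + 0.5)
  expect_equal(shifted$sd1, pc$sd1, tolerance = 1e-12)
  expect_equal(shifted$sdnn, pc$sdnn, tolerance = 1e-12)
  scaled <- poincare(3 * iv)
  expect_equal(scaled$sd1, 3 * pc$sd1, tolerance = 1e-12)
  expect_equal(scaled$sd2, 3 * pc$sd2, tolerance = 1e-12)
  expect_equal(scaled$sdnn, 3 * pc$sdnn, tolerance = 1e-12)
})

test_that("stft finds a pure tone in the right bin and rejects bad windows", {
  fs <- 200
  t <- (0:1999) / fs
  tone <- as_intensity_trace(tibble::tibble(t = t, v = sin(2 * pi * 10 * t)),
                             fps = fs)
  spec <- beat_stft(tone, window_s = 1)
  expect_equal(spec$dominant_freq, 10, tolerance = 1)
  expect_false(spec$dc_only)

  dc <- as_intensity_trace(tibble::tibble(t = t, v = rep(4, length(t))), fps = fs)
  spec_dc <- beat_stft(dc, window_s = 1)
  expect_true(spec_dc$dc_only)
  expect_true(is.na(spec_dc$dominant_freq))

  expect_error(beat_stft(tone, window_s = 20), "longer than trace")
})

test_that("stft power obeys Parseval per window to 1e-6 relative", {
  set.seed(5)
  fs <- 200
  v <- rnorm(600)
  tr <- as_intensity_trace(tibble::tibble(t = (0:599) / fs, v = v), fps = fs)
  spec <- beat_stft(tr, window_s = 1, overlap_frac = 0.5)
  n <- spec$n_window
  hop <- round(n * 0.5)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
  vc <- v - mean(v)
  for (j in seq_along(spec$times)) {
    start <- 1 + (j - 1) * hop
    seg <- vc[start:(start + n - 1)] * w
    expect_equal(cladocardio:::stft_twosided_power(spec, j),
                 n * sum(seg^2), tolerance = 1e-6)
  }
})

test_that("stft of a synthetic heart matches the programmed beat frequency", {
  sim <- simulate_heart(duration_s = 5, rate_bpm = 600, seed = 13)
  spec <- beat_stft(extract_trace(sim$stack), window_s = 1)
  expect_equal(spec$dominant_freq, 10, tolerance = 1)
})

test_that("dominant frequency tracks timing, not amplitude modulation", {
  fs <- 200
  t <- (0:1999) / fs
  am <- (1 + 0.5 * sin(2 * pi * 0.3 * t)) * sin(2 * pi * 8 * t)
  tr <- as_intensity_trace(tibble::tibble(t = t, v = am), fps = fs)
  expect_equal(beat_stft(tr, window_s = 1)$dominant_freq, 8, tolerance = 1)
})

test_that("stft agrees with an independent spectrogram implementation", {
  skip_if_not_installed("signal")
  fs <- 200
  t <- (0:1999) / fs
  v <- sin(2 * pi * 7 * t) + 0.3 * sin(2 * pi * 23 * t)
  tr <- as_intensity_trace(tibble::tibble(t = t, v = v), fps = fs)
  spec <- beat_stft(tr, window_s = 1, overlap_frac = 0.75)
  sg <- signal::specgram(v - mean(v), n = 200, Fs = fs,
                         window = signal::hanning(200), overlap = 150)
  dom_sig <- sg$f[which.max(rowSums(Mod(sg$S)^2)[-1]) + 1]
  expect_equal(spec$dominant_freq, dom_sig, tolerance = 1)
})

test_that("regularity_report bundles order-free and order-sensitive dispersion", {
  # metronomic rhythm: everything 0
  rep0 <- regularity_report(rep(0.1, 50))
  expect_equal(rep0$cv, 0)
  expect_equal(rep0$sdnn_s, 0)

  set.seed(21)
  iv <- rnorm(80, 0.1, 0.005)
  r1 <- regularity_report(iv)
  r2 <- regularity_report(iv * 1)  # identity sanity
  expect_equal(r1, r2)

  # doubling the spread about the mean doubles sdnn
  doubled <- mean(iv) + 2 * (iv - mean(iv))
  expect_equal(regularity_report(doubled)$sdnn_s, 2 * r1$sdnn_s,
               tolerance = 1e-12)

  # sdnn is order-free; sd1 generally is not
  shuffled <- sample(iv)
  rs <- regularity_report(shuffled)
  expect_equal(rs$sdnn_s, r1$sdnn_s, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(rs$sd1_s, r1$sd1_s, tolerance = 1e-6)))
})

test_that("interval_series resamples the interval tachogram uniformly", {
  sim <- simulate_heart(duration_s = 5, rate_bpm = 480, interval_sd_s = 0.01,
                        seed = 17)
  b <- detect_beats(extract_trace(sim$stack))
  its <- interval_series(b, fs = 40)
  expect_s3_class(its, "intensity_trace")
  expect_equal(diff(its$t), rep(1 / 40, nrow(its) - 1), tolerance = 1e-12)
  expect_true(all(its$v > 0.05 & its$v < 0.3))
})
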
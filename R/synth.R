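# Ground-truthed synthetic video generators. They emulate the acquisition
# conditions of high-speed daphnid videography — 200 fps for 10 s, a heart
# about 300 um long, blood-flow speeds up to ~2800 um/s — so every analysis
# module can be validated against programmed truth without animals.

# Beat schedule: truncated-Gaussian intervals with floor `eps`.
beat_schedule <- function(rate_bpm, interval_sd_s, duration_s, eps = 0.02) {
  mean_int <- 60 / rate_bpm
  t <- mean_int / 2
  times <- numeric(0)
  while (t < duration_s + mean_int) {
    times <- c(times, t)
    t <- t + max(eps, stats::rnorm(1, mean_int, interval_sd_s))
  }
  times
}

# Sum-of-Gaussians contraction envelope: 1 at a beat peak (systole), near 0
# between beats (diastole). tau sets the systolic pulse width.
contraction_envelope <- function(t, beat_times, tau) {
  c_t <- numeric(length(t))
  for (bt in beat_times) c_t <- c_t + exp(-((t - bt)^2) / (2 * tau^2))
  pmin(c_t, 1)
}

#' Simulate a beating-heart recording with known ground truth
#'
#' Renders a dark ellipse (the heart chamber in transmitted light) on a
#' bright background, with axes oscillating between diastolic and systolic
#' values. Beats occur at times `t[k+1] = t[k] + max(eps, N(60/rate_bpm,
#' interval_sd_s))` with floor `eps = 0.02 s`; around each beat the axes
#' contract following a Gaussian pulse of width `systole_frac` of the mean
#' cycle (systole occupies roughly a fifth of the cycle, as in the animal).
#' Edges are rendered with a Gaussian profile (band-limited) so sub-pixel
#' analysis is meaningful, then the frame is quantised to 16-bit counts with
#' optional Gaussian noise, like a CCD.
#'
#' Defaults mirror the acquisition conditions the package targets: 200 fps
#' for 10 s, a ~300 x 150 um diastolic heart contracting to 280 x 120 um,
#' 600 beats/min.
#'
#' @param fps Frame rate (frames/s).
#' @param duration_s Recording length (s).
#' @param rate_bpm Programmed mean heart rate (beats/min).
#' @param interval_sd_s Beat-to-beat interval SD (s); 0 gives a metronomic
#'   rhythm.
#' @param dl_d,ds_d,dl_s,ds_s Long/short axis diameters (um) at diastole and
#'   systole.
#' @param pixel_size_um Spatial calibration (um/pixel).
#' @param contrast Depth of the ellipse below background, in 16-bit counts.
#' @param noise_sd Per-pixel Gaussian noise SD, in counts.
#' @param systole_frac Gaussian pulse SD as a fraction of the mean beat
#'   interval.
#' @param margin_px Background margin around the diastolic ellipse.
#' @param seed RNG seed; identical parameters and seed give bit-identical
#'   output.
#' @return A list with `stack` (a [frame_stack()], 16-bit quantised
#'   intensities) and `truth`: programmed `beat_times`, `intervals`,
#'   `rate_bpm`, per-frame `dl_um`/`ds_um`, `edv_um3`, `esv_um3`, `sv_um3`
#'   (prolate-spheroid volumes), and the heart ROI as [rect_roi()].
#' @export
simulate_heart <- function(fps = 200, duration_s = 10, rate_bpm = 600,
                           interval_sd_s = 0, dl_d = 300, ds_d = 150,
                           dl_s = 280, ds_s = 120, pixel_size_um = 2,
                           contrast = 12000, noise_sd = 0,
                           systole_frac = 0.12, margin_px = 12, seed = 1) {
  stopifnot(rate_bpm > 0, interval_sd_s >= 0,
            dl_d > 0, ds_d > 0, dl_s > 0, ds_s > 0)
  with_seed(seed, {
    nf <- round(fps * duration_s)
    t_frames <- (seq_len(nf) - 1) / fps
    beat_times <- beat_schedule(rate_bpm, interval_sd_s, duration_s)
    tau <- systole_frac * 60 / rate_bpm
    c_t <- contraction_envelope(t_frames, beat_times, tau)
    dl_t <- dl_d - (dl_d - dl_s) * c_t
    ds_t <- ds_d - (ds_d - ds_s) * c_t

    w <- ceiling(dl_d / pixel_size_um) + 2 * margin_px
    h <- ceiling(ds_d / pixel_size_um) + 2 * margin_px
    cx <- (w - 1) / 2
    cy <- (h - 1) / 2
    X <- matrix((0:(w - 1) - cx) * pixel_size_um, h, w, byrow = TRUE)
    Y <- matrix((0:(h - 1) - cy) * pixel_size_um, h, w)
    edge_um <- 1.5 * pixel_size_um
    bg <- 30000

    frames <- array(0, dim = c(h, w, nf))
    for (k in seq_len(nf)) {
      a <- dl_t[k] / 2
      b <- ds_t[k] / 2
      r <- sqrt((X / a)^2 + (Y / b)^2)
      inside <- stats::pnorm((1 - r) * b / edge_um)
      img <- bg - contrast * inside
      if (noise_sd > 0) img <- img + stats::rnorm(h * w, 0, noise_sd)
      frames[, , k] <- pmin(pmax(round(img), 0), 65535)
    }
    truth_beats <- beat_times[beat_times >= 0 & beat_times < duration_s]
    list(
      stack = frame_stack(frames, fps = fps, pixel_size_um = pixel_size_um),
      truth = list(
        beat_times = truth_beats,
        intervals = diff(truth_beats),
        rate_bpm = rate_bpm,
        interval_sd_s = interval_sd_s,
        dl_um = dl_t, ds_um = ds_t,
        geometry = heart_geometry(dl_d, ds_d, dl_s, ds_s),
        edv_um3 = ellipsoid_volume(dl_d, ds_d),
        esv_um3 = ellipsoid_volume(dl_s, ds_s),
        sv_um3 = ellipsoid_volume(dl_d, ds_d) - ellipsoid_volume(dl_s, ds_s),
        roi = rect_roi(0, 0, w, h),
        seed = seed
      )
    )
  })
}

#' Simulate hemocytes advecting through a corridor, with known tracks
#'
#' Point-like cells (Gaussian blobs, dark on a bright background) move in the
#' +x direction with a shared, optionally pulsatile speed
#' `s(t) = mean_speed * (1 + pulsatility_frac * sin(2 * pi * beat_hz * t))`,
#' mimicking hemolymph driven by the heart. Cells are laid out on a jittered
#' staggered grid so that no two come closer than the tracking gate demands.
#' Positions are integrated analytically, so the programmed truth tracks are
#' exact.
#'
#' @param n_cells Number of cells (>= 1).
#' @param mean_speed_um_s Mean advection speed (um/s).
#' @param pulsatility_frac Pulsatility in `[0, 1]`; 1 makes the instantaneous
#'   speed swing between 0 and twice the mean.
#' @param beat_hz Pulsation frequency (Hz); the default 10 Hz matches a
#'   600 bpm heart.
#' @param cell_sigma_px Gaussian SD of the rendered blob (px); matched by
#'   `detect_spots(sigma_px = cell_sigma_px)`.
#' @param corridor_px `c(width, height)` of the field of view in pixels.
#' @param fps Frame rate (frames/s).
#' @param duration_s Recording length (s).
#' @param pixel_size_um Spatial calibration (um/pixel).
#' @param contrast Blob depth below background, counts.
#' @param noise_sd Per-pixel Gaussian noise SD, counts.
#' @param seed RNG seed.
#' @return A list with `stack` (a [frame_stack()]) and `truth`: a tibble of
#'   exact per-frame positions (`track`, `frame`, `x`, `y`, 0-based px) and
#'   instantaneous `speed_um_s`, plus the programmed parameters.
#' @export
simulate_flow <- function(n_cells = 20, mean_speed_um_s = 1000,
                          pulsatility_frac = 0, beat_hz = 10,
                          cell_sigma_px = 2.5, corridor_px = c(320, 120),
                          fps = 200, duration_s = 0.5, pixel_size_um = 2,
                          contrast = 12000, noise_sd = 0, seed = 1) {
  stopifnot(n_cells >= 1, mean_speed_um_s >= 0,
            pulsatility_frac >= 0, pulsatility_frac <= 1)
  with_seed(seed, {
    w <- corridor_px[1]
    h <- corridor_px[2]
    nf <- round(fps * duration_s)
    t_frames <- (seq_len(nf) - 1) / fps

    # displacement integral of s(t), in pixels
    disp_px <- function(t) {
      (mean_speed_um_s / pixel_size_um) *
        (t + pulsatility_frac / (2 * pi * beat_hz) * (1 - cos(2 * pi * beat_hz * t)))
    }
    travel <- disp_px(t_frames[nf])
    x_max0 <- w - 1 - ceiling(4 * cell_sigma_px) - travel
    x_min0 <- ceiling(4 * cell_sigma_px)
    if (x_max0 <= x_min0) {
      stop("corridor too short for the requested speed/duration; enlarge ",
           "`corridor_px[1]` or shorten `duration_s`", call. = FALSE)
    }
    # staggered grid with small jitter; spacing set by the grid, not the RNG
    n_rows <- max(1L, floor(sqrt(n_cells * (h / max(1, x_max0 - x_min0 + 20)))))
    n_rows <- min(max(n_rows, 1L), n_cells)
    n_cols <- ceiling(n_cells / n_rows)
    ys <- seq(4 * cell_sigma_px, h - 1 - 4 * cell_sigma_px, length.out = n_rows)
    xs <- seq(x_min0, x_max0, length.out = max(n_cols, 2L))[seq_len(n_cols)]
    grid <- expand.grid(y = ys, x = xs)[seq_len(n_cells), ]
    x0 <- grid$x + stats::runif(n_cells, -1, 1)
    y0 <- grid$y + stats::runif(n_cells, -1, 1)

    speed_t <- mean_speed_um_s *
      (1 + pulsatility_frac * sin(2 * pi * beat_hz * t_frames))
    dx <- disp_px(t_frames)

    truth <- tidyr::expand_grid(track = seq_len(n_cells),
                                frame = seq_len(nf)) |>
      dplyr::mutate(x = x0[.data$track] + dx[.data$frame],
                    y = y0[.data$track],
                    speed_um_s = speed_t[.data$frame])

    bg <- 30000
    frames <- array(0, dim = c(h, w, nf))
    xg <- 0:(w - 1)
    yg <- 0:(h - 1)
    for (k in seq_len(nf)) {
      img <- matrix(bg, h, w)
      xk <- x0 + dx[k]
      for (i in seq_len(n_cells)) {
        gx <- exp(-((xg - xk[i])^2) / (2 * cell_sigma_px^2))
        gy <- exp(-((yg - y0[i])^2) / (2 * cell_sigma_px^2))
        img <- img - contrast * (gy %o% gx)
      }
      if (noise_sd > 0) img <- img + stats::rnorm(h * w, 0, noise_sd)
      frames[, , k] <- pmin(pmax(round(img), 0), 65535)
    }
    list(
      stack = frame_stack(frames, fps = fps, pixel_size_um = pixel_size_um),
      truth = truth,
      params = list(n_cells = n_cells, mean_speed_um_s = mean_speed_um_s,
                    pulsatility_frac = pulsatility_frac, beat_hz = beat_hz,
                    cell_sigma_px = cell_sigma_px, fps = fps,
                    duration_s = duration_s, pixel_size_um = pixel_size_um,
                    seed = seed)
    )
  })
}

#' Pixel-noise level for a target trace signal-to-noise ratio
#'
#' Per-pixel Gaussian noise averages down by the square root of the ROI area
#' when the trace is formed, so a given trace-level SNR corresponds to a much
#' larger per-pixel noise. This helper renders the requested heart scene once
#' without noise, measures the RMS of the AC component of its intensity
#' trace, and returns the per-pixel `noise_sd` that makes
#' `RMS(signal) / RMS(trace noise) = snr`.
#'
#' @param snr Target trace-level signal-to-noise ratio (> 0).
#' @param ... Parameters passed to [simulate_heart()] (`noise_sd` is forced
#'   to 0 for the reference render).
#' @return A per-pixel noise SD in counts, suitable for
#'   `simulate_heart(noise_sd = ...)`.
#' @export
heart_noise_for_snr <- function(snr, ...) {
  stopifnot(snr > 0)
  args <- list(...)
  args$noise_sd <- 0
  sim <- do.call(simulate_heart, args)
  tr <- extract_trace(sim$stack)
  rms <- sqrt(mean((tr$v - mean(tr$v))^2))
  npix <- prod(dim(sim$stack$frames)[1:2])
  sqrt(npix) * rms / snr
}
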
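#' Poincare descriptors of heart-rate variability
#'
#' The Poincare plot scatters each inter-beat interval against the next,
#' `(I_n, I_(n+1))`. Its dispersion along the line of identity (`sd2`) and
#' across it (`sd1`) quantifies heart-rate variability: a regular rhythm
#' collapses onto a point, an irregular one spreads out. With population
#' (1/N) variance estimators,
#' `sd1 = SD((I_(n+1) - I_n) / sqrt(2))`,
#' `sd2 = SD((I_(n+1) + I_n) / sqrt(2))`, and
#' `sdnn = sqrt((Var(I_head) + Var(I_tail)) / 2)` over the two pair
#' coordinates, so the identity `sd1^2 + sd2^2 = 2 * sdnn^2` holds exactly.
#'
#' @param intervals A numeric vector of >= 2 inter-beat intervals in seconds,
#'   or a `beat_series` from [detect_beats()].
#' @return A `poincare_summary`: list with `sd1`, `sd2`, `sdnn` (seconds),
#'   `n_pairs`, and the interval pairs used (for plotting). [glance()] gives
#'   a one-row tibble.
#' @examples
#' poincare(rep(0.1, 10))                 # sd1 = sd2 = 0
#' poincare(rep(c(0.09, 0.11), 20))$sd1   # 0.02/sqrt(2)
#' @export
poincare <- function(intervals) {
  if (inherits(intervals, "beat_series")) intervals <- intervals$intervals
  if (!is.numeric(intervals) || length(intervals) < 2L) {
    stop("need >= 2 intervals", call. = FALSE)
  }
  n <- length(intervals)
  x <- intervals[-n]          # I_n
  y <- intervals[-1]          # I_(n+1)
  sd1 <- sd_pop((y - x) / sqrt(2))
  sd2 <- sd_pop((y + x) / sqrt(2))
  sdnn <- sqrt((var_pop(x) + var_pop(y)) / 2)
  structure(list(sd1 = sd1, sd2 = sd2, sdnn = sdnn, n_pairs = n - 1L,
                 pairs = tibble::tibble(i_n = x, i_n1 = y)),
            class = "poincare_summary")
}

#' @rdname poincare
#' @param x A `poincare_summary`.
#' @param ... Ignored.
#' @export
print.poincare_summary <- function(x, ...) {
  cat(sprintf("<poincare_summary> sd1 = %.4g s, sd2 = %.4g s, sdnn = %.4g s (%d pairs)\n",
              x$sd1, x$sd2, x$sdnn, x$n_pairs))
  invisible(x)
}

#' Short-time Fourier transform of a heartbeat trace
#'
#' Computes a Hann-windowed magnitude-squared spectrogram of the
#' mean-subtracted trace. The dominant frequency is the bin with the largest
#' total power summed over time windows (DC excluded); for a beating heart it
#' equals the beat frequency (bpm / 60). The defaults (1 s window, 75%
#' overlap) give 1 Hz frequency resolution at any sampling rate, enough to
#' resolve the 4–10 Hz cladoceran beat band at 200 fps.
#'
#' Power bookkeeping: `power[f, w]` is the two-sided `|FFT|^2` of window `w`
#' folded to one side without doubling; the helper used in validation
#' reconstructs the two-sided sum, which equals `n * sum(windowed signal^2)`
#' (Parseval).
#'
#' @param trace An `intensity_trace`, or anything [as_intensity_trace()]
#'   accepts.
#' @param window_s Window length in seconds.
#' @param overlap_frac Fractional overlap between successive windows in
#'   `[0, 1)`.
#' @return A `spectrogram_result`: list with `freqs` (Hz), `times` (window
#'   centres, s), `power` (matrix, frequency x time), `dominant_freq` (Hz, or
#'   `NA` with `dc_only = TRUE` when the trace carries no AC power).
#' @export
beat_stft <- function(trace, window_s = 1, overlap_frac = 0.75) {
  trace <- as_intensity_trace(trace)
  fps <- trace_fps(trace)
  if (!(overlap_frac >= 0 && overlap_frac < 1)) {
    stop("`overlap_frac` must be in [0, 1)", call. = FALSE)
  }
  n <- round(window_s * fps)
  if (n < 4) stop("window too short", call. = FALSE)
  if (n > nrow(trace)) {
    stop("window (", n, " samples) longer than trace (", nrow(trace), ")",
         call. = FALSE)
  }
  v <- trace$v - mean(trace$v)
  hop <- max(1L, round(n * (1 - overlap_frac)))
  starts <- seq(1L, nrow(trace) - n + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))  # periodic Hann
  nf <- floor(n / 2) + 1L
  power <- matrix(0, nrow = nf, ncol = length(starts))
  for (j in seq_along(starts)) {
    seg <- v[starts[j]:(starts[j] + n - 1L)] * w
    X <- stats::fft(seg)
    power[, j] <- Mod(X[1:nf])^2
  }
  freqs <- (0:(nf - 1L)) * fps / n
  times <- (starts - 1 + (n - 1) / 2) / fps

  total <- rowSums(power)
  ac <- total[-1]
  dc_only <- sum(ac) <= 1e-12 * max(total[1], .Machine$double.eps)
  dominant <- if (dc_only) NA_real_ else freqs[-1][which.max(ac)]

  structure(list(freqs = freqs, times = times, power = power,
                 dominant_freq = dominant, dc_only = dc_only,
                 window_s = window_s, overlap_frac = overlap_frac,
                 fps = fps, n_window = n),
            class = "spectrogram_result")
}

#' @rdname beat_stft
#' @param x A `spectrogram_result`.
#' @param ... Ignored.
#' @export
print.spectrogram_result <- function(x, ...) {
  cat(sprintf("<spectrogram_result> %d freq bins x %d windows (%.3g s Hann, %.0f%% overlap)\n",
              length(x$freqs), length(x$times), x$window_s, 100 * x$overlap_frac))
  if (x$dc_only) cat("  no AC power: dominant frequency undefined\n")
  else cat(sprintf("  dominant frequency %.4g Hz\n", x$dominant_freq))
  invisible(x)
}

# Two-sided spectral power of window j, reconstructed from the one-sided
# storage; equals n * sum(windowed-signal^2) by Parseval.
stft_twosided_power <- function(spec, j) {
  p <- spec$power[, j]
  n <- spec$n_window
  nf <- length(p)
  if (n %% 2 == 0) p[1] + p[nf] + 2 * sum(p[2:(nf - 1L)])
  else p[1] + 2 * sum(p[2:nf])
}

#' Resample an interval series onto a uniform time grid
#'
#' The sequence of inter-beat intervals is an irregularly sampled signal
#' (one value per beat). For frequency-domain analysis of interval dynamics,
#' this helper linearly interpolates interval duration against beat time onto
#' a uniform grid, returning an `intensity_trace` that [beat_stft()] accepts.
#' This interval-series mode is deliberately separate from the default
#' trace-based spectrogram: the two answer different questions (beat
#' frequency vs. frequency content of rate fluctuations).
#'
#' @param beats A `beat_series`.
#' @param fs Resampling rate in Hz.
#' @return An `intensity_trace` of interval duration (s) versus time.
#' @export
interval_series <- function(beats, fs = 50) {
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats$intervals) < 2L) stop("need >= 2 intervals", call. = FALSE)
  tt <- beats$beat_times[-1]  # interval ends
  grid <- seq(tt[1], tt[length(tt)], by = 1 / fs)
  v <- stats::approx(tt, beats$intervals, xout = grid, rule = 2)$y
  new_intensity_trace(grid, v, fps = fs)
}

#' Rhythm-regularity summary
#'
#' Bundles the standard deviation of all inter-beat intervals (`sdnn`,
#' order-free), the Poincare short- and long-axis dispersions (`sd1`, `sd2`,
#' order-sensitive), and the coefficient of variation of intervals. Larger
#' values mean a less regular rhythm. `sdnn` here is the population SD of the
#' full interval sequence, so it is invariant under reordering; the
#' `poincare()` summary's `sdnn` is the pair-coordinate version tied to the
#' `sd1`/`sd2` identity — the two differ only by edge terms of order 1/n.
#'
#' @param beats A `beat_series`, or a numeric vector of intervals (s).
#' @return A one-row tibble: `sdnn_s`, `sd1_s`, `sd2_s`, `cv`, `n_intervals`.
#' @export
regularity_report <- function(beats) {
  intervals <- if (inherits(beats, "beat_series")) beats$intervals else beats
  if (!is.numeric(intervals) || length(intervals) < 2L) {
    stop("need >= 2 intervals", call. = FALSE)
  }
  pc <- poincare(intervals)
  tibble::tibble(
    sdnn_s = sd_pop(intervals),
    sd1_s = pc$sd1,
    sd2_s = pc$sd2,
    cv = sd_pop(intervals) / mean(intervals),
    n_intervals = length(intervals)
  )
}
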
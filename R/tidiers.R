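# broom-style tidiers and ggplot2 autoplot methods for the package's result
# objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a beat series
#'
#' @param x A `beat_series` from [detect_beats()].
#' @param ... Ignored.
#' @return One row per beat: `beat_time_s`, and for every beat but the last
#'   the `interval_s` to the next beat and the instantaneous `rate_bpm`.
#' @method tidy beat_series
#' @export
tidy.beat_series <- function(x, ...) {
  n <- length(x$beat_times)
  tibble::tibble(
    beat_time_s = x$beat_times,
    interval_s = c(x$intervals, NA_real_),
    rate_bpm = c(x$rates_bpm, NA_real_)
  )
}

#' @rdname tidy.beat_series
#' @return `glance()`: a one-row summary with beat count, both heart-rate
#'   estimators, and interval mean/SD.
#' @method glance beat_series
#' @export
glance.beat_series <- function(x, ...) {
  tibble::tibble(
    n_beats = length(x$beat_times),
    bpm_per_beat_mean = heart_rate(x, "per-beat-mean"),
    bpm_reciprocal_mean = heart_rate(x, "reciprocal-of-mean-interval"),
    interval_mean_s = mean(x$intervals),
    interval_sd_s = stats::sd(x$intervals),
    duration_s = x$duration_s
  )
}

#' @rdname poincare
#' @method glance poincare_summary
#' @export
glance.poincare_summary <- function(x, ...) {
  tibble::tibble(sd1_s = x$sd1, sd2_s = x$sd2, sdnn_s = x$sdnn,
                 n_pairs = x$n_pairs)
}

#' Tidy a spectrogram
#'
#' @param x A `spectrogram_result` from [beat_stft()].
#' @param ... Ignored.
#' @return A long tibble: `freq_hz`, `time_s`, `power`.
#' @method tidy spectrogram_result
#' @export
tidy.spectrogram_result <- function(x, ...) {
  tidyr::expand_grid(time_s = x$times, freq_hz = x$freqs) |>
    dplyr::mutate(power = as.vector(x$power)) |>
    dplyr::select("freq_hz", "time_s", "power")
}

#' @rdname tidy.spectrogram_result
#' @method glance spectrogram_result
#' @export
glance.spectrogram_result <- function(x, ...) {
  tibble::tibble(dominant_freq_hz = x$dominant_freq, dc_only = x$dc_only,
                 n_windows = length(x$times), window_s = x$window_s,
                 overlap_frac = x$overlap_frac)
}

#' Plot methods for analysis results
#'
#' `autoplot()` methods give quick diagnostic figures: the intensity trace
#' with time on the x axis; the Poincare interval scatter with the identity
#' line; the spectrogram as a power raster; and particle tracks as paths
#' over the field of view (y axis reversed to match image row coordinates).
#'
#' @param object A result object.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot intensity_trace
#' @export
autoplot.intensity_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$v)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "mean ROI intensity")
}

#' @rdname autoplot.intensity_trace
#' @method autoplot poincare_summary
#' @export
autoplot.poincare_summary <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$i_n, y = .data$i_n1)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(I[n] ~ "(s)"), y = expression(I[n + 1] ~ "(s)"),
                  subtitle = sprintf("SD1 = %.4g s, SD2 = %.4g s",
                                     object$sd1, object$sd2))
}

#' @rdname autoplot.intensity_trace
#' @method autoplot spectrogram_result
#' @export
autoplot.spectrogram_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                 fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "power")
}

#' @rdname autoplot.intensity_trace
#' @method autoplot track_set
#' @export
autoplot.track_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       group = .data$track,
                                       colour = factor(.data$track))) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}
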
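# Cardiac geometry endpoints from diastolic/systolic heart diameters:
# fractional shortening, ellipsoid chamber volumes, stroke volume, ejection
# fraction and cardiac output.

#' Fractional shortening
#'
#' Percent reduction of the heart's short-axis diameter from diastole to
#' systole. Two denominator conventions exist in the water-flea literature:
#' the `"paper"` convention divides by the systolic diameter,
#' `(ds_d - ds_s) / ds_s * 100`; the `"standard"` echocardiographic
#' convention divides by the diastolic diameter, `(ds_d - ds_s) / ds_d * 100`.
#' The default follows the systolic-denominator form used in the cladoceran
#' videography protocol this package implements.
#'
#' @param ds_d Short-axis diameter at diastole (um), > 0.
#' @param ds_s Short-axis diameter at systole (um), > 0.
#' @param convention `"paper"` (systolic denominator, default) or
#'   `"standard"` (diastolic denominator).
#' @return Fractional shortening in percent.
#' @examples
#' fractional_shortening(110, 100)               # 10
#' fractional_shortening(110, 100, "standard")   # 9.09...
#' @export
fractional_shortening <- function(ds_d, ds_s,
                                  convention = c("paper", "standard")) {
  convention <- match.arg(convention)
  if (any(ds_d <= 0) || any(ds_s <= 0)) {
    stop("diameters must be positive", call. = FALSE)
  }
  den <- if (convention == "paper") ds_s else ds_d
  (ds_d - ds_s) / den * 100
}

#' Ellipsoid heart-chamber volume
#'
#' The single-chambered daphnid heart is modelled as a prolate spheroid with
#' long axis `dl` and two equal short axes `ds`; its volume is
#' `(pi/6) * dl * ds^2`. The protocol's printed formula uses the constant
#' `1/6` without pi; `include_pi = FALSE` reproduces that literal form for
#' exact comparison with values computed under it. Volumes scale the same way
#' under either constant, so ratios (ejection fraction) are unaffected.
#'
#' @param dl Long-axis diameter (um), > 0.
#' @param ds Short-axis diameter (um), > 0.
#' @param include_pi Use the true spheroid constant `pi/6` (default); `FALSE`
#'   uses `1/6`.
#' @return Volume in cubic micrometres. 1 nL = 1e6 um^3.
#' @examples
#' ellipsoid_volume(2, 1)              # pi/3
#' ellipsoid_volume(2, 1, FALSE)       # 1/3
#' @export
ellipsoid_volume <- function(dl, ds, include_pi = TRUE) {
  if (any(dl <= 0) || any(ds <= 0)) stop("diameters must be positive", call. = FALSE)
  cst <- if (include_pi) pi / 6 else 1 / 6
  cst * dl * ds^2
}

#' Stroke volume, ejection fraction and cardiac output
#'
#' `stroke_volume()` is the volume ejected per beat, `EDV - ESV`; a negative
#' result (systolic volume larger than diastolic) indicates a measurement
#' inconsistency and is flagged with a warning but returned.
#' `ejection_fraction()` is `SV / EDV * 100` percent.
#' `cardiac_output()` is `SV * heart rate`, volume pumped per minute,
#' reported in um^3/min (divide by 1e6 for nL/min).
#'
#' @param edv End-diastolic volume (um^3), >= 0.
#' @param esv End-systolic volume (um^3), >= 0.
#' @return `stroke_volume()`: um^3 per beat.
#' @examples
#' sv <- stroke_volume(ellipsoid_volume(300, 150), ellipsoid_volume(280, 120))
#' ejection_fraction(sv, ellipsoid_volume(300, 150))
#' cardiac_output(sv, hr_bpm = 600) / 1e6   # nL/min
#' @export
stroke_volume <- function(edv, esv) {
  if (any(edv < 0) || any(esv < 0)) stop("volumes must be non-negative", call. = FALSE)
  sv <- edv - esv
  if (any(sv < 0)) {
    warning("negative stroke volume: end-systolic volume exceeds end-diastolic ",
            "volume (check diastole/systole assignment)", call. = FALSE)
  }
  sv
}

#' @rdname stroke_volume
#' @param sv Stroke volume (um^3).
#' @export
ejection_fraction <- function(sv, edv) {
  if (any(edv <= 0)) stop("`edv` must be > 0", call. = FALSE)
  sv / edv * 100
}

#' @rdname stroke_volume
#' @param hr_bpm Heart rate in beats per minute (>= 0).
#' @export
cardiac_output <- function(sv, hr_bpm) {
  if (any(hr_bpm < 0)) stop("`hr_bpm` must be >= 0", call. = FALSE)
  sv * hr_bpm
}

#' Heart diameters at diastole and systole
#'
#' Container for the four manual or automated diameter measurements: long
#' (`dl`) and short (`ds`) axis at diastole (`_d`) and systole (`_s`), all in
#' micrometres. A systolic short diameter exceeding the diastolic one is
#' physiologically backwards and triggers a warning (not an error: the
#' numbers are kept so the inconsistency can be inspected).
#'
#' @param dl_d,ds_d Long/short-axis diameter at diastole (um).
#' @param dl_s,ds_s Long/short-axis diameter at systole (um).
#' @return An object of class `heart_geometry`.
#' @export
heart_geometry <- function(dl_d, ds_d, dl_s, ds_s) {
  vals <- c(dl_d = dl_d, ds_d = ds_d, dl_s = dl_s, ds_s = ds_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all diameters must be positive and finite", call. = FALSE)
  }
  if (ds_s > ds_d) {
    warning("systolic short diameter (", signif(ds_s, 4),
            " um) exceeds diastolic (", signif(ds_d, 4),
            " um); diastole/systole may be swapped", call. = FALSE)
  }
  structure(list(dl_d = dl_d, ds_d = ds_d, dl_s = dl_s, ds_s = ds_s),
            class = "heart_geometry")
}

#' @rdname heart_geometry
#' @param x A `heart_geometry`.
#' @param ... Ignored.
#' @export
print.heart_geometry <- function(x, ...) {
  cat(sprintf(
    "<heart_geometry> diastole %.4g x %.4g um, systole %.4g x %.4g um\n",
    x$dl_d, x$ds_d, x$dl_s, x$ds_s))
  invisible(x)
}

#' Full set of cardiac metrics from geometry and heart rate
#'
#' Composes [fractional_shortening()], [ellipsoid_volume()],
#' [stroke_volume()], [ejection_fraction()] and [cardiac_output()] into one
#' tidy row.
#'
#' @param geometry A [heart_geometry()].
#' @param hr_bpm Heart rate, beats per minute.
#' @param include_pi Passed to [ellipsoid_volume()].
#' @param fs_convention Passed to [fractional_shortening()].
#' @return A one-row tibble: `fs_pct`, `edv_um3`, `esv_um3`, `sv_um3`,
#'   `ef_pct`, `co_um3_min`, plus nanolitre versions `edv_nl`, `esv_nl`,
#'   `sv_nl`, `co_nl_min` (1 nL = 1e6 um^3).
#' @export
cardiac_metrics <- function(geometry, hr_bpm, include_pi = TRUE,
                            fs_convention = c("paper", "standard")) {
  stopifnot(inherits(geometry, "heart_geometry"))
  fs_convention <- match.arg(fs_convention)
  edv <- ellipsoid_volume(geometry$dl_d, geometry$ds_d, include_pi)
  esv <- ellipsoid_volume(geometry$dl_s, geometry$ds_s, include_pi)
  sv <- stroke_volume(edv, esv)
  tibble::tibble(
    fs_pct = fractional_shortening(geometry$ds_d, geometry$ds_s, fs_convention),
    edv_um3 = edv, esv_um3 = esv, sv_um3 = sv,
    ef_pct = ejection_fraction(sv, edv),
    co_um3_min = cardiac_output(sv, hr_bpm),
    edv_nl = edv / 1e6, esv_nl = esv / 1e6, sv_nl = sv / 1e6,
    co_nl_min = cardiac_output(sv, hr_bpm) / 1e6,
    hr_bpm = hr_bpm
  )
}

# ---- automated diameter measurement -----------------------------------------

# Otsu threshold on a 256-bin histogram: maximises between-class variance.
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = 256)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  breaks[which.max(sb) + 1L]
}

# Largest 4-connected component of a logical mask, by iterative label
# propagation (vectorised; converges in O(component diameter) sweeps).
largest_component <- function(mask) {
  if (!any(mask)) return(mask & FALSE)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  repeat {
    up    <- rbind(lab[-1, , drop = FALSE], 0L)
    down  <- rbind(0L, lab[-nrow(lab), , drop = FALSE])
    left  <- cbind(lab[, -1, drop = FALSE], 0L)
    right <- cbind(0L, lab[, -ncol(lab), drop = FALSE])
    new_lab <- pmax(lab, up, down, left, right)
    new_lab[!mask] <- 0L
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  counts <- table(lab[lab > 0L])
  best <- as.integer(names(counts)[which.max(counts)])
  lab == best
}

# Full ellipse axes (px) from the second moments of a solid binary region.
# For a uniform ellipse with semi-axes a >= b the coordinate covariance
# eigenvalues are a^2/4 and b^2/4, so full axes are 4 * sqrt(eigenvalues).
moment_axes <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  cc <- sweep(pts, 2, colMeans(pts))
  cv <- crossprod(cc) / nrow(pts)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  c(major = 4 * sqrt(max(ev[1], 0)), minor = 4 * sqrt(max(ev[2], 0)))
}

#' Measure heart diameters from video, beat-synchronised
#'
#' An automated stand-in for manual calliper measurements: frames nearest
#' each detected beat peak form the systolic set, frames at the midpoints
#' between consecutive peaks (the maximally relaxed phase) form the
#' diastolic set. Each selected ROI frame is thresholded (Otsu), the largest
#' connected component is taken as the heart, and full major/minor axes come
#' from a second-moment ellipse fit. The reported diameters are means over
#' each frame set, converted to micrometres. The intensity trace only fixes
#' the two phase sets up to a half-cycle shift, so if the "systolic" set
#' turns out larger than the "diastolic" one the two are swapped (with a
#' message); the phase labels follow the chamber area, not the trace
#' polarity.
#'
#' @param stack A [frame_stack()].
#' @param heart_roi A [rect_roi()] over the heart chamber.
#' @param beats A `beat_series` from [detect_beats()] on the same recording.
#' @param min_area_px Smallest connected component accepted as a heart
#'   (default 25 px); below this the ROI is declared unsegmentable.
#' @param max_frames_per_phase Cap on the number of frames segmented per
#'   phase set (default 12, evenly subsampled); averaging a dozen frames per
#'   phase is ample and keeps long recordings fast.
#' @return A [heart_geometry()] with an attribute `frames` listing the
#'   diastolic and systolic frame indices used.
#' @export
measure_diameters <- function(stack, heart_roi, beats, min_area_px = 25,
                              max_frames_per_phase = 12) {
  stopifnot(inherits(stack, "frame_stack"), inherits(beats, "beat_series"))
  d <- dim(stack$frames)
  idx <- roi_indices(heart_roi, d[1], d[2])
  fps <- stack$fps
  nf <- d[3]

  sys_frames <- pmin(pmax(round(beats$beat_times * fps) + 1, 1), nf)
  mid_times <- (beats$beat_times[-1] + beats$beat_times[-length(beats$beat_times)]) / 2
  dia_frames <- pmin(pmax(round(mid_times * fps) + 1, 1), nf)
  subsample <- function(v) {
    if (length(v) <= max_frames_per_phase) return(v)
    v[round(seq(1, length(v), length.out = max_frames_per_phase))]
  }
  sys_frames <- subsample(sys_frames)
  dia_frames <- subsample(dia_frames)

  axes_of <- function(frames) {
    out <- matrix(NA_real_, length(frames), 2)
    for (i in seq_along(frames)) {
      roi_px <- stack$frames[idx$rows, idx$cols, frames[i]]
      thr <- otsu_threshold(as.numeric(roi_px))
      below <- roi_px < thr
      if (!any(below) || all(below)) next
      # bimodality gate: a segmentable heart separates the two intensity
      # classes by well over their internal spread; a noise-only ROI does not
      # (splitting a Gaussian at its mean gives a separation of ~2.7 SD)
      m0 <- mean(roi_px[below]); m1 <- mean(roi_px[!below])
      s_within <- sqrt(stats::weighted.mean(
        c(var_pop(as.numeric(roi_px[below])), var_pop(as.numeric(roi_px[!below]))),
        c(sum(below), sum(!below))))
      if (!is.finite(s_within) || m1 - m0 < 3 * s_within) next
      # The heart lies inside the ROI while the background reaches its
      # border: of the two threshold classes, take the largest connected
      # component with the least border contact; break ties by how well the
      # component fills its own moment ellipse (a solid ellipse fills ~100%).
      best <- NULL
      best_score <- NULL
      for (mask in list(below, !below)) {
        comp <- largest_component(mask)
        area <- sum(comp)
        if (area < min_area_px) next
        border <- sum(comp[1, ]) + sum(comp[nrow(comp), ]) +
          sum(comp[, 1]) + sum(comp[, ncol(comp)])
        ax <- moment_axes(comp)
        fill <- area / (pi * ax[["major"]] * ax[["minor"]] / 4)
        score <- c(border, -fill)
        if (is.null(best) || border < best_score[1] ||
            (border == best_score[1] && fill > -best_score[2])) {
          best <- ax
          best_score <- score
        }
        if (border == 0 && fill > 0.9) break  # clean interior ellipse
      }
      if (is.null(best)) next
      out[i, ] <- best
    }
    out
  }
  sys_axes <- axes_of(sys_frames)
  dia_axes <- axes_of(dia_frames)
  if (all(is.na(sys_axes[, 1])) || all(is.na(dia_axes[, 1]))) {
    stop("heart not segmentable (no component >= ", min_area_px,
         " px); supply manual diameters instead", call. = FALSE)
  }
  px <- stack$pixel_size_um
  dia <- stats::setNames(colMeans(dia_axes, na.rm = TRUE) * px, c("major", "minor"))
  sys <- stats::setNames(colMeans(sys_axes, na.rm = TRUE) * px, c("major", "minor"))

  # the beat-peak phase is only known up to polarity; label by chamber size
  if (sys[["major"]] * sys[["minor"]]^2 > dia[["major"]] * dia[["minor"]]^2) {
    tmp <- dia; dia <- sys; sys <- tmp
    tmp_f <- dia_frames; dia_frames <- sys_frames; sys_frames <- tmp_f
    message("systolic frame set had the larger chamber; swapped phase labels")
  }
  geom <- heart_geometry(dl_d = dia[["major"]], ds_d = dia[["minor"]],
                         dl_s = sys[["major"]], ds_s = sys[["minor"]])
  attr(geom, "frames") <- list(diastole = dia_frames, systole = sys_frames)
  geom
}

#' Read manually measured diameters from CSV
#'
#' Fallback for recordings where intensity-based segmentation fails: a CSV
#' with columns `phase` (`"diastole"` or `"systole"`), `dl_um`, `ds_um`, one
#' row per measured frame; rows are averaged within phase.
#'
#' @param path CSV file path.
#' @return A [heart_geometry()].
#' @export
read_diameters <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("phase", "dl_um", "ds_um")
  if (!all(need %in% names(df))) {
    stop("diameters CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$phase <- tolower(df$phase)
  if (!all(df$phase %in% c("diastole", "systole"))) {
    stop("`phase` must be \"diastole\" or \"systole\"", call. = FALSE)
  }
  agg <- stats::aggregate(df[c("dl_um", "ds_um")], by = list(phase = df$phase), mean)
  dia <- agg[agg$phase == "diastole", ]
  sys <- agg[agg$phase == "systole", ]
  if (!nrow(dia) || !nrow(sys)) stop("need both diastole and systole rows", call. = FALSE)
  heart_geometry(dl_d = dia$dl_um, ds_d = dia$ds_um,
                 dl_s = sys$dl_um, ds_s = sys$ds_um)
}
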
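#' Frame stacks: the raw video substrate
#'
#' A `frame_stack` holds an ordered sequence of grayscale frames together with
#' the acquisition frame rate and the spatial calibration. It is the input to
#' every analysis entry point in the package.
#'
#' Coordinate convention (used unchanged by every module): `x` is the column
#' index increasing rightward, `y` is the row index increasing downward, both
#' 0-based. Rectangular regions are half-open:
#' `[x0, x0 + width) x [y0, y0 + height)`. Frame indices are 1-based, as is
#' idiomatic in R; the time of frame `k` is `(k - 1) / fps` seconds.
#'
#' Camera metadata (frame rate, pixel size) is never guessed from file
#' headers: both must be supplied by the user, because high-speed CCD
#' recordings typically do not embed them reliably.
#'
#' @param frames A numeric 3-D array `(height, width, n_frames)` or a list of
#'   equally sized numeric matrices. Intensities may be integer or real and
#'   are kept in their native units.
#' @param fps Acquisition rate in frames per second (> 0).
#' @param pixel_size_um Spatial calibration in micrometres per pixel (> 0).
#' @return An object of class `frame_stack` with elements `frames` (3-D
#'   array), `fps` and `pixel_size_um`.
#' @examples
#' frames <- array(rep(1:5, each = 4), dim = c(2, 2, 5))
#' fs <- frame_stack(frames, fps = 200, pixel_size_um = 1.5)
#' n_frames(fs)
#' duration(fs)
#' @export
frame_stack <- function(frames, fps, pixel_size_um) {
  stopifnot_scalar_pos(fps, "fps")
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  if (is.list(frames)) {
    if (length(frames) < 2L) stop("need ≥ 2 frames", call. = FALSE)
    d1 <- dim(frames[[1]])
    for (k in seq_along(frames)) {
      dk <- dim(frames[[k]])
      if (is.null(dk) || length(dk) != 2L) {
        stop("frame ", k, " is not a 2-D matrix", call. = FALSE)
      }
      if (!identical(dk, d1)) {
        stop("frame ", k, " has shape ", dk[1], "x", dk[2],
             ", expected ", d1[1], "x", d1[2], call. = FALSE)
      }
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(d1[1], d1[2], length(frames)))
  }
  d <- dim(frames)
  if (is.null(d) || length(d) != 3L) {
    stop("`frames` must be a (height, width, n_frames) array or list of matrices",
         call. = FALSE)
  }
  if (d[3] < 2L) stop("need ≥ 2 frames", call. = FALSE)
  structure(
    list(frames = frames, fps = as.numeric(fps),
         pixel_size_um = as.numeric(pixel_size_um)),
    class = "frame_stack"
  )
}

#' @rdname frame_stack
#' @param x,stack A `frame_stack`.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' @rdname frame_stack
#' @export
duration <- function(stack) n_frames(stack) / stack$fps

#' @rdname frame_stack
#' @param ... Ignored.
#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_stack> %d frames of %d x %d px, %.6g fps (%.4g s), %.4g um/px\n",
    d[3], d[1], d[2], x$fps, d[3] / x$fps, x$pixel_size_um))
  invisible(x)
}

#' @rdname frame_stack
#' @export
dim.frame_stack <- function(x) dim(x$frames)

#' Rectangular region of interest
#'
#' 0-based, half-open rectangle `[x0, x0 + width) x [y0, y0 + height)` in the
#' package-wide coordinate convention (`x` = column rightward, `y` = row
#' downward). Used to delimit the heart chamber and the thorax blood-flow
#' corridor.
#'
#' @param x0,y0 Top-left corner, 0-based pixels.
#' @param width,height Extent in pixels (>= 1).
#' @return An object of class `rect_roi`.
#' @examples
#' rect_roi(10, 5, 64, 48)
#' roi_from_string("10,5,64,48")
#' @export
rect_roi <- function(x0, y0, width, height) {
  vals <- c(x0 = x0, y0 = y0, width = width, height = height)
  if (any(!is.finite(vals)) || any(vals != round(vals))) {
    stop("ROI coordinates must be finite integers", call. = FALSE)
  }
  if (x0 < 0 || y0 < 0) stop("ROI origin must be non-negative", call. = FALSE)
  if (width < 1 || height < 1) stop("ROI width/height must be >= 1", call. = FALSE)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "rect_roi")
}

#' @rdname rect_roi
#' @param spec A string `"x0,y0,width,height"`, as accepted on the command
#'   line.
#' @export
roi_from_string <- function(spec) {
  parts <- suppressWarnings(as.numeric(strsplit(spec, ",", fixed = TRUE)[[1]]))
  if (length(parts) != 4L || anyNA(parts)) {
    stop("ROI string must be \"x0,y0,width,height\"", call. = FALSE)
  }
  rect_roi(parts[1], parts[2], parts[3], parts[4])
}

#' @rdname rect_roi
#' @export
print.rect_roi <- function(x, ...) {
  cat(sprintf("<rect_roi> x0=%d y0=%d width=%d height=%d (0-based, half-open)\n",
              x$x0, x$y0, x$width, x$height))
  invisible(x)
}

# Row/column index ranges (1-based) for an ROI; errors name the offending
# coordinate so a user can fix their crop string.
roi_indices <- function(roi, frame_height, frame_width) {
  if (roi$x0 + roi$width > frame_width) {
    stop("ROI right edge x = ", roi$x0 + roi$width,
         " exceeds frame width ", frame_width, call. = FALSE)
  }
  if (roi$y0 + roi$height > frame_height) {
    stop("ROI bottom edge y = ", roi$y0 + roi$height,
         " exceeds frame height ", frame_height, call. = FALSE)
  }
  list(rows = (roi$y0 + 1L):(roi$y0 + roi$height),
       cols = (roi$x0 + 1L):(roi$x0 + roi$width))
}

#' Crop a frame stack to a region of interest
#'
#' @param stack A [frame_stack()].
#' @param roi A [rect_roi()] fully inside the frame bounds.
#' @return A `frame_stack` of shape `(height, width)` with `fps` and
#'   `pixel_size_um` unchanged.
#' @examples
#' fs <- frame_stack(array(0, dim = c(20, 30, 3)), fps = 200, pixel_size_um = 1)
#' dim(crop(fs, rect_roi(5, 5, 10, 10)))
#' @export
crop <- function(stack, roi) {
  stopifnot(inherits(stack, "frame_stack"), inherits(roi, "rect_roi"))
  d <- dim(stack$frames)
  idx <- roi_indices(roi, d[1], d[2])
  frame_stack(stack$frames[idx$rows, idx$cols, , drop = FALSE],
              fps = stack$fps, pixel_size_um = stack$pixel_size_um)
}

#' Read and write multi-page TIFF frame stacks
#'
#' `read_stack()` reads a grayscale multi-page TIFF (8/16-bit integer or
#' 32-bit float) in acquisition order. Integer intensities are read as-is
#' (losslessly); colour pages are converted to luminance by the mean across
#' channels, deterministically. `write_stack()` writes a stack back to a
#' multi-page TIFF; `read_stack(write_stack(x))` round-trips integer stacks
#' bit-identically.
#'
#' @param path Path to a multi-page TIFF file.
#' @param fps Acquisition rate (frames per second); must be supplied, it is
#'   not read from the file.
#' @param pixel_size_um Spatial calibration (micrometres per pixel); must be
#'   supplied.
#' @return `read_stack()` returns a [frame_stack()]; `write_stack()` returns
#'   `path` invisibly.
#' @export
read_stack <- function(path, fps, pixel_size_um) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("unreadable TIFF: ", path, " (",
                                             conditionMessage(e), ")", call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop("need ≥ 2 frames, got ", length(pages), call. = FALSE)
  mats <- vector("list", length(pages))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    dk <- dim(p)
    if (length(dk) == 3L) p <- apply(p, c(1, 2), mean)  # colour -> luminance
    else if (length(dk) != 2L) stop("frame ", k, " has unsupported shape", call. = FALSE)
    mats[[k]] <- p
  }
  d1 <- dim(mats[[1]])
  for (k in seq_along(mats)) {
    if (!identical(dim(mats[[k]]), d1)) {
      stop("frame ", k, " has shape ", dim(mats[[k]])[1], "x", dim(mats[[k]])[2],
           ", inconsistent with frame 1 (", d1[1], "x", d1[2], ")", call. = FALSE)
    }
  }
  frame_stack(mats, fps = fps, pixel_size_um = pixel_size_um)
}

#' @rdname read_stack
#' @param stack A [frame_stack()].
#' @param bits Bits per sample: 8 or 16 write integer TIFF (intensities must
#'   already lie in `[0, 2^bits - 1]`); 32 writes IEEE float.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "frame_stack"))
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L, 32L)) stop("`bits` must be 8, 16 or 32", call. = FALSE)
  nf <- n_frames(stack)
  pages <- vector("list", nf)
  if (bits %in% c(8L, 16L)) {
    top <- 2^bits - 1
    rng <- range(stack$frames)
    if (rng[1] < 0 || rng[2] > top) {
      stop("intensities outside [0, ", top, "]; rescale or use bits = 32",
           call. = FALSE)
    }
    for (k in seq_len(nf)) pages[[k]] <- stack$frames[, , k] / top
  } else {
    rng <- range(stack$frames)
    if (rng[1] < 0 || rng[2] > 1) {
      stop("float TIFF stores intensities in [0, 1]; rescale before writing",
           call. = FALSE)
    }
    for (k in seq_len(nf)) pages[[k]] <- stack$frames[, , k]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  invisible(path)
}
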
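#' Time-lapse image sequence
#'
#' Container for an ordered grayscale time-lapse: a list of integer matrices
#' of constant shape plus acquisition metadata. The spatial calibration
#' (`pixel_size`, micrometres per pixel) and the time step interval between
#' stored frames are carried along so downstream statistics can be reported
#' in physical units.
#'
#' `origin_interval` is the interval of the original acquisition before any
#' temporal subsampling, and `origin_duration` its total duration
#' (`frames x origin_interval`); both are preserved by
#' [subsample_sequence()] so that the trajectory duration filter can keep
#' referring to the experiment as acquired. `frame_index` records, for every
#' stored frame, its 1-based index in the original acquisition.
#'
#' @param frames list of 2-D numeric/integer matrices, all the same shape.
#' @param pixel_size pixel size in micrometres per pixel.
#' @param interval time step interval in seconds between stored frames.
#' @param origin_interval interval of the original acquisition (defaults to
#'   `interval`).
#' @param origin_duration total duration in seconds of the original
#'   acquisition (defaults to `length(frames) * interval`).
#' @param frame_index integer vector mapping stored frames to original
#'   acquisition frame numbers (defaults to `1:length(frames)`).
#' @param bit_depth 8 or 16.
#' @return An object of class `pt_sequence`.
#' @export
image_sequence <- function(frames, pixel_size, interval,
                           origin_interval = interval,
                           origin_duration = length(frames) * interval,
                           frame_index = seq_along(frames),
                           bit_depth = 8L) {
  if (length(frames) < 1) stop("an image sequence needs at least one frame")
  if (is.null(pixel_size) || !is.finite(pixel_size) || pixel_size <= 0)
    stop_config("pixel_size must be a positive number (um/px)")
  if (is.null(interval) || !is.finite(interval) || interval <= 0)
    stop_config("interval must be a positive number of seconds")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have the same shape")
  k <- interval / origin_interval
  if (abs(k - round(k)) > 1e-9)
    stop("interval must be an integer multiple of origin_interval")
  structure(list(frames = frames,
                 pixel_size = pixel_size,
                 interval = interval,
                 origin_interval = origin_interval,
                 origin_duration = origin_duration,
                 frame_index = as.integer(frame_index),
                 bit_depth = as.integer(bit_depth)),
            class = "pt_sequence")
}

#' @export
length.pt_sequence <- function(x) length(x$frames)

#' @export
dim.pt_sequence <- function(x) dim(x$frames[[1]])

#' @export
print.pt_sequence <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "Phase-contrast time-lapse: %d frames of %d x %d px (%d-bit)\n",
    length(x), d[1], d[2], x$bit_depth))
  cat(sprintf("  pixel size %.3g um/px, interval %g s (acquired at %g s, %.2f h total)\n",
              x$pixel_size, x$interval, x$origin_interval,
              x$origin_duration / 3600))
  invisible(x)
}

#' Acquisition times of stored frames
#'
#' @param seq a [image_sequence()].
#' @return numeric vector of times in seconds (first acquired frame at 0).
#' @export
frame_times <- function(seq) (seq$frame_index - 1) * seq$origin_interval

#' Temporally subsample a sequence
#'
#' Keeps frames `1, 1+k, 1+2k, ...` and drops the intermediates, emulating
#' acquisition at a `k`-fold larger time step interval. The original
#' acquisition's interval and duration are retained as metadata so the
#' trajectory duration threshold stays anchored to the experiment as run.
#'
#' @param seq a [image_sequence()].
#' @param k positive integer subsampling factor.
#' @return a new `pt_sequence` with `ceiling(length(seq)/k)` frames and
#'   interval `k * seq$interval`.
#' @export
subsample_sequence <- function(seq, k) {
  if (length(k) != 1 || !is.finite(k) || k < 1 || abs(k - round(k)) > 1e-9)
    stop_config("subsampling factor k must be a positive integer")
  k <- as.integer(round(k))
  keep <- seq.int(1L, length(seq), by = k)
  image_sequence(seq$frames[keep],
                 pixel_size = seq$pixel_size,
                 interval = seq$interval * k,
                 origin_interval = seq$origin_interval,
                 origin_duration = seq$origin_duration,
                 frame_index = seq$frame_index[keep],
                 bit_depth = seq$bit_depth)
}
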
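#' Read a time-lapse sequence from TIFF
#'
#' Accepts either a multi-page grayscale TIFF (frames in page order) or a
#' directory of single-frame images read in lexicographic filename order.
#' Pixel values are read at native bit depth.
#'
#' @param path multi-page TIFF file or a directory of `.tif`/`.tiff` files.
#' @param pixel_size pixel size in um/px (required; TIFF tags are not relied
#'   upon for spatial calibration).
#' @param interval time step interval in seconds between frames.
#' @param ... passed to [image_sequence()] (e.g. `origin_interval`).
#' @return a [image_sequence()].
#' @export
read_sequence <- function(path, pixel_size, interval, ...) {
  if (missing(pixel_size) || missing(interval))
    stop_config("pixel_size and interval metadata are required")
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (length(files) == 0) stop("no TIFF files found in ", path)
    pages <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]      # collapse greyscale-as-RGB
    storage.mode(p) <- "integer"
    p
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames in ", path, " have mixed shapes")
  depth <- if (max(vapply(frames, max, numeric(1))) > 255) 16L else 8L
  image_sequence(frames, pixel_size = pixel_size, interval = interval,
                 bit_depth = depth, ...)
}

#' Write a sequence as a multi-page TIFF
#'
#' @param seq a [image_sequence()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  maxv <- 2^seq$bit_depth - 1
  pages <- lapply(seq$frames, function(f) f / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = seq$bit_depth,
                  compression = "none")
  invisible(path)
}

#' Write trajectories to CSV
#'
#' One row per (track, frame) with columns `track_id, frame, time_s, row_px,
#' col_px`. Positions are stored to 3 decimal pixels; the round trip through
#' [read_trajectories()] is lossless at that precision and a second write is
#' byte-identical.
#'
#' @param trajs a `pt_tracks` object (see [build_trajectories()]).
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  df <- as.data.frame(trajs)
  out <- data.frame(track_id = df$track_id,
                    frame = df$frame,
                    time_s = sprintf("%.1f", df$time_s),
                    row_px = sprintf("%.3f", df$row),
                    col_px = sprintf("%.3f", df$col))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trajectories from CSV
#'
#' @param path CSV written by [write_trajectories()].
#' @param interval seconds between consecutive track points (recovered from
#'   time stamps when omitted).
#' @param origin_duration total experiment duration in seconds (optional).
#' @return a `pt_tracks` object.
#' @export
read_trajectories <- function(path, interval = NULL, origin_duration = NULL) {
  df <- read.csv(path)
  if (nrow(df) == 0) {
    tracks <- data.frame(track_id = integer(), frame = integer(),
                         time_s = numeric(), row = numeric(), col = numeric())
  } else {
    tracks <- data.frame(track_id = df$track_id, frame = df$frame,
                         time_s = as.numeric(df$time_s),
                         row = as.numeric(df$row_px),
                         col = as.numeric(df$col_px))
  }
  if (is.null(interval)) {
    dts <- with(tracks, unlist(tapply(time_s, track_id, diff)))
    interval <- if (length(dts)) min(dts) else NA_real_
  }
  new_tracks(tracks, interval = interval, origin_duration = origin_duration)
}

#' Write / read ground-truth cell paths
#'
#' CSV with columns `cell_id, frame, row_px, col_px`, the simulator's
#' ground-truth table format.
#'
#' @param gt a `pt_ground_truth` object ([simulate_motion()]).
#' @param path CSV file.
#' @return `path` / a `pt_ground_truth`.
#' @export
write_ground_truth <- function(gt, path) {
  df <- as.data.frame(gt)
  out <- data.frame(cell_id = df$cell_id, frame = df$frame,
                    row_px = sprintf("%.3f", df$row),
                    col_px = sprintf("%.3f", df$col))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- read.csv(path)
  new_ground_truth(data.frame(cell_id = df$cell_id, frame = df$frame,
                              row = as.numeric(df$row_px),
                              col = as.numeric(df$col_px)))
}

#' Write / read a run configuration file
#'
#' Flat YAML mapping mirroring the [run_config()] fields.
#'
#' @param config a [run_config()].
#' @param path YAML file.
#' @return `path` / a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}
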
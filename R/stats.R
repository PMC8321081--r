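#' Directional migration statistics
#'
#' A trajectory is south-moving iff its ending point lies strictly below
#' its starting point (`end_row > start_row`), and east-moving iff strictly
#' to the right (`end_col > start_col`); exact ties count as neither.
#' Percentages are rounded half-up to one decimal, matching migration
#' summary tables. For a chemoattractant placed at the south, directed
#' migration shows up as a south-moving share well above 50%, while
#' unbiased random walks vary around 50%.
#'
#' @param trajs a `pt_tracks` whose tracks have >= 2 points.
#' @return a `pt_migration` list: `n_tracks, n_south, pct_south, n_east,
#'   pct_east, interval`.
#' @export
directional_stats <- function(trajs) {
  v <- star_plot_vectors(trajs)
  n <- nrow(v)
  n_south <- sum(v$drow > 0)
  n_east <- sum(v$dcol > 0)
  structure(list(n_tracks = n,
                 n_south = n_south, pct_south = pct_of(n_south, n),
                 n_east = n_east, pct_east = pct_of(n_east, n),
                 interval = attr(trajs, "interval")),
            class = "pt_migration")
}

#' @export
print.pt_migration <- function(x, ...) {
  cat(sprintf("%d trajectories at %g s interval\n", x$n_tracks, x$interval))
  cat(sprintf("  south-moving: %d (%s%%)   east-moving: %d (%s%%)\n",
              x$n_south, format(x$pct_south), x$n_east, format(x$pct_east)))
  invisible(x)
}

#' Net displacement vectors (star plot data)
#'
#' One origin-anchored vector per trajectory, from its starting point to
#' its ending point - the data behind a star plot in which all starting
#' points are overlaid at the centre.
#'
#' @param trajs a `pt_tracks`.
#' @return data frame `track_id, drow, dcol` (px); one row per track.
#' @export
star_plot_vectors <- function(trajs) {
  if (nrow(trajs) == 0)
    return(data.frame(track_id = integer(), drow = numeric(),
                      dcol = numeric()))
  o <- trajs[order(trajs$track_id, trajs$frame), ]
  first <- o[!duplicated(o$track_id), ]
  last <- o[!duplicated(o$track_id, fromLast = TRUE), ]
  data.frame(track_id = first$track_id,
             drow = last$row - first$row,
             dcol = last$col - first$col)
}

#' Star plot of net trajectory displacements
#'
#' @param trajs a `pt_tracks`.
#' @param ... passed to [plot.window()].
#' @return the displacement vectors, invisibly.
#' @export
star_plot <- function(trajs, ...) {
  v <- star_plot_vectors(trajs)
  lim <- max(1, abs(c(v$drow, v$dcol)))
  plot.new()
  plot.window(xlim = c(-lim, lim), ylim = c(lim, -lim), asp = 1, ...)
  axis(1); axis(2); box()
  title(xlab = "east displacement (px)", ylab = "south displacement (px)")
  abline(h = 0, v = 0, col = "grey80")
  if (nrow(v))
    arrows(0, 0, v$dcol, v$drow, length = 0.05, col = "steelblue")
  invisible(v)
}

#' Plot trajectories over the view plane
#'
#' @param x a `pt_tracks`.
#' @param y ignored.
#' @param ... passed to [plot.window()].
#' @export
plot.pt_tracks <- function(x, y, ...) {
  plot.new()
  rng_r <- range(x$row, 0); rng_c <- range(x$col, 0)
  plot.window(xlim = rng_c, ylim = rev(rng_r), asp = 1, ...)
  axis(1); axis(2); box()
  title(xlab = "col (px, east)", ylab = "row (px, south)")
  for (id in unique(x$track_id)) {
    tr <- x[x$track_id == id, ]
    lines(tr$col, tr$row, col = "steelblue")
  }
  invisible(x)
}

#' Confluence of a segmented frame
#'
#' The ratio between the area covered by cells and the total view plane.
#'
#' @param mask logical matrix.
#' @return percentage of foreground pixels.
#' @export
compute_confluence <- function(mask) 100 * sum(mask) / length(mask)

#' Confluence range over a sequence of masks
#'
#' @param masks list of logical matrices.
#' @return `(min, max)` per-frame confluence in percent.
#' @export
confluence_range <- function(masks) {
  range(vapply(masks, compute_confluence, numeric(1)))
}

#' Strict tracking accuracy against ground truth
#'
#' Every track point is assigned to the nearest ground-truth cell present
#' at that acquisition frame, provided it lies within `match_radius`. A
#' track is correct only if every point is assigned and all assignments
#' name the same cell - a single identity switch (tracking a different
#' cell) or an unassignable point makes the whole track a failure.
#'
#' @param trajs a `pt_tracks` (frames refer to original acquisition frame
#'   numbers, as produced by the pipeline).
#' @param gt a `pt_ground_truth`.
#' @param match_radius positive matching radius in px; a natural choice is
#'   the linking threshold `D` used at that interval.
#' @return a `pt_accuracy` list: `n_tracks, n_correct, accuracy` (percent,
#'   1 decimal) and `per_track` data frame with `track_id, correct,
#'   first_error_frame`.
#' @export
evaluate_accuracy <- function(trajs, gt, match_radius) {
  if (match_radius <= 0) stop_config("match_radius must be > 0")
  ids <- unique(trajs$track_id)
  gt_by_frame <- split(as.data.frame(gt)[c("cell_id", "row", "col")],
                       gt$frame)
  # nearest gt cell (or NA) for every track point, computed frame-by-frame
  assigned <- rep(NA_integer_, nrow(trajs))
  for (fr in unique(trajs$frame)) {
    sel <- which(trajs$frame == fr)
    g <- gt_by_frame[[as.character(fr)]]
    if (is.null(g) || nrow(g) == 0) next
    d2 <- outer(trajs$row[sel], g$row, `-`)^2 +
      outer(trajs$col[sel], g$col, `-`)^2
    nearest <- max.col(-d2, ties.method = "first")
    ok <- d2[cbind(seq_along(sel), nearest)] <= match_radius^2
    assigned[sel][ok] <- g$cell_id[nearest[ok]]
  }
  per <- lapply(ids, function(id) {
    sel <- which(trajs$track_id == id)
    sel <- sel[order(trajs$frame[sel])]
    a <- assigned[sel]
    bad <- is.na(a) | a != a[1]
    data.frame(track_id = id, correct = !any(bad),
               first_error_frame = if (any(bad))
                 trajs$frame[sel][which(bad)[1]] else NA_integer_)
  })
  per <- do.call(rbind, per)
  n <- length(ids)
  nc <- sum(per$correct)
  structure(list(n_tracks = n, n_correct = nc,
                 accuracy = pct_of(nc, n), per_track = per),
            class = "pt_accuracy")
}

#' @export
print.pt_accuracy <- function(x, ...) {
  cat(sprintf("strict accuracy: %d / %d tracks correct (%s%%)\n",
              x$n_correct, x$n_tracks, format(x$accuracy)))
  invisible(x)
}

#' Run configuration
#'
#' Bundles the pipeline parameters for [interval_sweep()] and the CLI.
#'
#' @param segmentation_backend `"bgsub"` or `"contour"`.
#' @param area_bounds inclusive object area bounds, px^2.
#' @param duration_fraction minimum track duration as a fraction of the
#'   experiment duration (default 0.15, in (0, 1)).
#' @param D_anchors linking-threshold anchors for [threshold_rule()].
#' @param intervals_to_sweep intervals (s) for the sweep; defaults to the
#'   canonical 30 s - 15 min ladder.
#' @param match_radius accuracy matching radius (px); `NULL` uses the `D`
#'   of each interval.
#' @param tau background-subtraction threshold; `NULL` estimates it.
#' @return a `run_config` list.
#' @export
run_config <- function(segmentation_backend = c("bgsub", "contour"),
                       area_bounds = c(20, 5000),
                       duration_fraction = 0.15,
                       D_anchors = rbind(c(30, 10), c(900, 50)),
                       intervals_to_sweep = c(30, 60, 120, 180, 300, 450,
                                              600, 900),
                       match_radius = NULL, tau = NULL) {
  segmentation_backend <- match.arg(segmentation_backend)
  if (duration_fraction <= 0 || duration_fraction >= 1)
    stop_config("duration_fraction must lie in (0, 1)")
  # column-major length-4 vectors (e.g. from a YAML round trip) are accepted
  D_anchors <- matrix(as.numeric(unlist(D_anchors)), 2, 2)
  rule <- threshold_rule(D_anchors)     # validates the anchors
  structure(list(segmentation_backend = segmentation_backend,
                 area_bounds = area_bounds,
                 duration_fraction = duration_fraction,
                 D_anchors = rule$anchors,
                 intervals_to_sweep = intervals_to_sweep,
                 match_radius = match_radius, tau = tau),
            class = "run_config")
}

#' Time-step-interval sweep
#'
#' Reruns the full pipeline at each requested interval: subsample the
#' 30 s-class acquisition, segment, link with the interval-scaled
#' threshold, filter by the duration threshold of the ORIGINAL experiment,
#' and tabulate directional statistics (plus strict accuracy when ground
#' truth is supplied). One row per interval, as in a tracking summary
#' table. With the background-subtraction backend the temporal-mode
#' background is reconstructed once from the full acquisition and shared
#' across intervals.
#'
#' @param seq a [image_sequence()] at the base interval.
#' @param gt optional `pt_ground_truth` for accuracy scoring.
#' @param config a [run_config()].
#' @return a `pt_sweep` data frame with columns `interval_s, n_tracks,
#'   n_south, pct_south, n_east, pct_east, accuracy`, plus attributes
#'   `confluence` (min-max % over frames at base interval) and `tracks`
#'   (list of `pt_tracks` per interval).
#' @export
interval_sweep <- function(seq, gt = NULL, config = run_config()) {
  rule <- threshold_rule(config$D_anchors)
  ks <- config$intervals_to_sweep / seq$interval
  if (any(abs(ks - round(ks)) > 1e-9))
    stop_config("every swept interval must be an integer multiple of ",
                seq$interval, " s")
  bg <- NULL
  tau <- config$tau
  if (config$segmentation_backend == "bgsub") {
    bg <- reconstruct_background(seq)
    if (is.null(tau)) tau <- estimate_tau(seq, bg)
  }
  rows <- vector("list", length(ks))
  tracks_out <- vector("list", length(ks))
  confl <- NULL
  for (z in seq_along(ks)) {
    k <- as.integer(round(ks[z]))
    sub <- subsample_sequence(seq, k)
    D <- threshold_for_interval(rule, sub$interval)
    tr <- if (config$segmentation_backend == "bgsub") {
      track_cells(sub, backend = "bgsub", D = D,
                  area_bounds = config$area_bounds,
                  duration_fraction = config$duration_fraction,
                  tau = tau, bg = bg)
    } else {
      track_cells(sub, backend = "contour", D = D,
                  area_bounds = config$area_bounds,
                  duration_fraction = config$duration_fraction)
    }
    if (k == 1) confl <- confluence_range(attr(tr, "masks"))
    ms <- directional_stats(tr)
    acc <- NA_real_
    if (!is.null(gt) && ms$n_tracks > 0) {
      mr <- if (is.null(config$match_radius)) D else config$match_radius
      acc <- evaluate_accuracy(tr, gt, mr)$accuracy
    }
    attr(tr, "masks") <- NULL
    tracks_out[[z]] <- tr
    rows[[z]] <- data.frame(interval_s = sub$interval,
                            n_tracks = ms$n_tracks, n_south = ms$n_south,
                            pct_south = ms$pct_south, n_east = ms$n_east,
                            pct_east = ms$pct_east, accuracy = acc)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$interval_s), ]
  rownames(df) <- NULL
  structure(df, confluence = confl, tracks = tracks_out,
            class = c("pt_sweep", "data.frame"))
}

#' @export
print.pt_sweep <- function(x, ...) {
  cat("Time-step-interval sweep\n")
  if (!is.null(attr(x, "confluence")))
    cat(sprintf("  confluence %.2f-%.2f%% at base interval\n",
                attr(x, "confluence")[1], attr(x, "confluence")[2]))
  hdr <- sprintf("%10s %6s %6s %8s %6s %8s %9s",
                 "interval", "tracks", "south", "%south", "east", "%east",
                 "accuracy")
  cat(hdr, "\n")
  for (r in seq_len(nrow(x))) {
    iv <- x$interval_s[r]
    lab <- if (iv < 60) sprintf("%g s", iv) else sprintf("%g min", iv / 60)
    cat(sprintf("%10s %6d %6d %8s %6d %8s %9s\n", lab, x$n_tracks[r],
                x$n_south[r], format(x$pct_south[r]), x$n_east[r],
                format(x$pct_east[r]),
                ifelse(is.na(x$accuracy[r]), "-", format(x$accuracy[r]))))
  }
  invisible(x)
}
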
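#' Extract labelled objects and centroids from a binary mask
#'
#' 8-connected component labelling (diagonally touching halo pixels belong
#' to the same object), followed by an area filter that discards noise and
#' fragments outside `area_bounds`. Each surviving object is reduced to the
#' unweighted centre of mass of its pixels - the particle representation
#' used for tracking.
#'
#' @param mask logical matrix.
#' @param area_bounds inclusive `(min, max)` object area in px^2.
#' @param frame_index acquisition frame number carried as metadata.
#' @return a `pt_objects` data frame with columns `label, area, row, col`.
#' @export
mask_to_objects <- function(mask, area_bounds = c(20, 5000),
                            frame_index = NA_integer_) {
  if (area_bounds[1] > area_bounds[2])
    stop_config("min_area must not exceed max_area")
  lab <- label_components(mask)
  nl <- max(lab)
  if (nl == 0) {
    return(new_objects(data.frame(label = integer(), area = numeric(),
                                  row = numeric(), col = numeric()),
                       frame_index))
  }
  px <- which(lab > 0)
  l <- lab[px]
  areas <- tabulate(l, nbins = nl)
  ri <- (px - 1) %% nrow(mask) + 1
  ci <- (px - 1) %/% nrow(mask) + 1
  rowsum_r <- rowsum(ri, l)
  rowsum_c <- rowsum(ci, l)
  ids <- as.integer(rownames(rowsum_r))
  df <- data.frame(label = ids, area = areas[ids],
                   row = rowsum_r[, 1] / areas[ids],
                   col = rowsum_c[, 1] / areas[ids])
  keep <- df$area >= area_bounds[1] & df$area <= area_bounds[2]
  new_objects(df[keep, ], frame_index)
}

new_objects <- function(df, frame_index = NA_integer_) {
  rownames(df) <- NULL
  structure(df, frame_index = frame_index,
            class = c("pt_objects", "data.frame"))
}

#' @export
print.pt_objects <- function(x, ...) {
  cat(sprintf("%d segmented objects (frame %s)\n", nrow(x),
              attr(x, "frame_index")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

#' Greedy global-minimum centroid linking between two frames
#'
#' Builds the `N_A x N_B` array of Euclidean centroid distances
#' `d_ij = |C_A,i - C_B,j|` and links recursively: the globally smallest
#' remaining entry is linked, its row and column are removed, and the
#' selection repeats until the smallest remaining distance exceeds the
#' plausibility threshold `D` or the array is exhausted. This is the exact
#' recursive greedy procedure - deliberately *not* an optimal-assignment
#' solver - encoding the assumption that a cell moves to the closest target
#' within the vicinity `D`. Ties are broken toward the lexicographically
#' smallest `(i, j)` for determinism.
#'
#' @param A,B `pt_objects` for two consecutive frames (order matters).
#' @param D positive distance threshold in px; links longer than `D` are
#'   implausible and never created.
#' @return a `pt_links` data frame with columns `i, j, dist` (indices into
#'   the rows of `A` and `B`).
#' @export
link_frames <- function(A, B, D) {
  if (D <= 0) stop_config("D must be > 0")
  na <- nrow(A); nb <- nrow(B)
  if (na == 0 || nb == 0)
    return(new_links(data.frame(i = integer(), j = integer(),
                                dist = numeric())))
  dm <- sqrt(outer(A$row, B$row, `-`)^2 + outer(A$col, B$col, `-`)^2)
  is <- integer(0); js <- integer(0); ds <- numeric(0)
  for (rep in seq_len(min(na, nb))) {
    mn <- min(dm)
    if (!is.finite(mn) || mn > D) break
    cand <- which(dm == mn, arr.ind = TRUE)
    sel <- cand[order(cand[, 1], cand[, 2])[1], ]
    is <- c(is, sel[1]); js <- c(js, sel[2]); ds <- c(ds, mn)
    dm[sel[1], ] <- Inf
    dm[, sel[2]] <- Inf
  }
  new_links(data.frame(i = is, j = js, dist = ds))
}

new_links <- function(df) {
  rownames(df) <- NULL
  structure(df, class = c("pt_links", "data.frame"))
}

#' Assemble trajectories from frame-to-frame link sets
#'
#' Chains links sharing object endpoints into tracks. Every object that
#' receives no incoming link starts a new track at its frame; a track ends
#' at the first frame where its object has no outgoing link. There is no
#' gap closing. Single-point tracks are materialised (and later rejected by
#' the duration filter), so the assembly conserves objects.
#'
#' @param object_sets list of `pt_objects`, one per stored frame, in order.
#' @param link_sets list of `pt_links` between consecutive object sets
#'   (`length(object_sets) - 1` of them).
#' @param seq the [image_sequence()] the objects came from (supplies frame
#'   numbering, interval and original experiment duration).
#' @return a `pt_tracks` object: data frame `track_id, frame, time_s, row,
#'   col` with attributes `interval` and `origin_duration`.
#' @export
build_trajectories <- function(object_sets, link_sets, seq = NULL) {
  nt <- length(object_sets)
  if (length(link_sets) != nt - 1)
    stop("need exactly one link set per consecutive frame pair")
  frame_ids <- if (!is.null(seq)) seq$frame_index else seq_len(nt)
  interval <- if (!is.null(seq)) seq$interval else 1
  origin_interval <- if (!is.null(seq)) seq$origin_interval else 1
  origin_duration <- if (!is.null(seq)) seq$origin_duration else nt
  times <- (frame_ids - 1) * origin_interval

  next_id <- 0L
  rows_out <- vector("list", nt)
  # track id carried by each object of the current frame
  carry <- integer(0)
  for (t in seq_len(nt)) {
    objs <- object_sets[[t]]
    n <- nrow(objs)
    ids <- rep(NA_integer_, n)
    if (t > 1 && n > 0) {
      lk <- link_sets[[t - 1]]
      if (nrow(lk) > 0) ids[lk$j] <- carry[lk$i]
    }
    fresh <- which(is.na(ids))
    if (length(fresh) > 0) {
      ids[fresh] <- next_id + seq_along(fresh)
      next_id <- next_id + length(fresh)
    }
    if (n > 0) {
      rows_out[[t]] <- data.frame(track_id = ids, frame = frame_ids[t],
                                  time_s = times[t], row = objs$row,
                                  col = objs$col)
    }
    carry <- ids
  }
  df <- do.call(rbind, rows_out)
  if (is.null(df)) {
    df <- data.frame(track_id = integer(), frame = integer(),
                     time_s = numeric(), row = numeric(), col = numeric())
  }
  df <- df[order(df$track_id, df$frame), ]
  new_tracks(df, interval = interval, origin_duration = origin_duration)
}

new_tracks <- function(df, interval, origin_duration = NULL) {
  rownames(df) <- NULL
  structure(df, interval = interval, origin_duration = origin_duration,
            class = c("pt_tracks", "data.frame"))
}

#' @export
print.pt_tracks <- function(x, ...) {
  n <- length(unique(x$track_id))
  cat(sprintf("%d trajectories (%d points, interval %g s)\n",
              n, nrow(x), attr(x, "interval")))
  invisible(x)
}

#' Number of tracks
#' @param trajs a `pt_tracks`.
#' @return integer count.
#' @export
n_tracks <- function(trajs) length(unique(trajs$track_id))

#' Per-track durations in seconds
#'
#' A track observed at `p` points separated by interval `dt` has duration
#' `(p - 1) * dt`: the elapsed time between first and last sighting.
#'
#' @param trajs a `pt_tracks`.
#' @return named numeric vector of durations (names are track ids).
#' @export
track_durations <- function(trajs) {
  if (nrow(trajs) == 0) return(setNames(numeric(0), character(0)))
  p <- table(trajs$track_id)
  setNames((as.vector(p) - 1) * attr(trajs, "interval"), names(p))
}

#' Reject short trajectories
#'
#' Keeps tracks whose duration is at least `duration_fraction` of the
#' experiment duration (with the canonical 15% of a 24 h acquisition this
#' is 3.6 h). The experiment duration is that of the ORIGINAL acquisition
#' and is unchanged by temporal subsampling. The bound is inclusive and
#' there is no upper bound.
#'
#' @param trajs a `pt_tracks`.
#' @param duration_fraction fraction in (0, 1), default 0.15.
#' @param experiment_duration_s total experiment duration in seconds;
#'   defaults to the `origin_duration` recorded on `trajs`.
#' @return filtered `pt_tracks`.
#' @export
filter_trajectories <- function(trajs, duration_fraction = 0.15,
                                experiment_duration_s = NULL) {
  if (duration_fraction <= 0 || duration_fraction >= 1)
    stop_config("duration_fraction must lie in (0, 1)")
  if (is.null(experiment_duration_s))
    experiment_duration_s <- attr(trajs, "origin_duration")
  if (is.null(experiment_duration_s))
    stop("experiment duration unknown; pass experiment_duration_s")
  thr <- duration_fraction * experiment_duration_s
  dur <- track_durations(trajs)
  keep_ids <- names(dur)[dur >= thr - 1e-9]
  out <- trajs[as.character(trajs$track_id) %in% keep_ids, ]
  new_tracks(as.data.frame(out), interval = attr(trajs, "interval"),
             origin_duration = attr(trajs, "origin_duration"))
}

#' Interval-scaled linking threshold
#'
#' The plausibility threshold `D` grows with the time step interval: 10 px
#' (about 16.1 um at 1.61 um/px) at 30 s, rising to about 50 px (about
#' 83 um) at 15 min. Between (and beyond) the two anchors the rule
#' interpolates linearly and clamps.
#'
#' @param anchors 2x2 matrix `rbind(c(interval_s, D_px), c(interval_s,
#'   D_px))` with intervals increasing.
#' @return a `pt_threshold_rule`.
#' @export
threshold_rule <- function(anchors = rbind(c(30, 10), c(900, 50))) {
  anchors <- as.matrix(anchors)
  if (any(anchors <= 0) || anchors[2, 1] <= anchors[1, 1] ||
      anchors[2, 2] < anchors[1, 2])
    stop_config("anchors must be positive with D non-decreasing in interval")
  structure(list(anchors = anchors), class = "pt_threshold_rule")
}

#' @rdname threshold_rule
#' @param rule a `pt_threshold_rule`.
#' @param interval_s time step interval in seconds.
#' @return `D` in px (piecewise-linear, clamped, monotone non-decreasing).
#' @export
threshold_for_interval <- function(rule, interval_s) {
  a <- rule$anchors
  approx(a[, 1], a[, 2], xout = interval_s, rule = 2)$y
}

#' Track cells through a sequence
#'
#' The full pipeline behind one table row: segment every frame, extract
#' area-filtered centroids, link consecutive frames with the greedy
#' global-minimum linker at threshold `D`, assemble trajectories, and
#' (optionally) reject those shorter than the duration threshold.
#'
#' @param seq a [image_sequence()].
#' @param backend `"bgsub"` or `"contour"`; ignored when `masks` given.
#' @param masks optional precomputed list of logical masks.
#' @param D linking threshold in px; when `NULL`, derived from `rule` at
#'   the sequence's interval.
#' @param rule a [threshold_rule()].
#' @param area_bounds inclusive object area bounds, px^2.
#' @param duration_fraction minimum track duration as a fraction of the
#'   original experiment duration; `NULL` skips the filter.
#' @param ... extra arguments for the segmentation backend
#'   ([segment_bgsub()] or [segment_contour()]).
#' @return a filtered `pt_tracks`; the unfiltered set is kept in attribute
#'   `unfiltered`, the masks in attribute `masks`.
#' @export
track_cells <- function(seq, backend = c("bgsub", "contour"), masks = NULL,
                        D = NULL, rule = threshold_rule(),
                        area_bounds = c(20, 5000),
                        duration_fraction = 0.15, ...) {
  backend <- match.arg(backend)
  if (is.null(masks)) {
    masks <- switch(backend,
                    bgsub = segment_bgsub(seq, ...),
                    contour = segment_contour(seq, ...))
  }
  if (is.null(D)) D <- threshold_for_interval(rule, seq$interval)
  objs <- lapply(seq_along(masks), function(t) {
    mask_to_objects(masks[[t]], area_bounds, frame_index = seq$frame_index[t])
  })
  links <- lapply(seq_len(length(objs) - 1), function(t) {
    link_frames(objs[[t]], objs[[t + 1]], D)
  })
  tr <- build_trajectories(objs, links, seq)
  out <- if (is.null(duration_fraction)) tr else
    filter_trajectories(tr, duration_fraction)
  attr(out, "unfiltered") <- tr
  attr(out, "masks") <- masks
  attr(out, "D") <- D
  out
}
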
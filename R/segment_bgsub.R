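#' Reconstruct the static background by the temporal mode
#'
#' For every pixel, takes the mode of the intensity values occurring across
#' all frames. Because cells keep moving and the culture is sparse, the
#' modal value at a pixel is (almost always) the background, including any
#' stationary artefact that can be treated as background. Ties are broken
#' toward the smaller intensity so the result is deterministic.
#'
#' Intensities must be integer-valued. When a sequence holds more than 4096
#' distinct grey levels (possible for 16-bit data), the histogram falls back
#' to 256 equal-width bins and the bin centre is returned.
#'
#' @param seq a [image_sequence()] with at least 2 frames.
#' @return integer (or numeric, in the binned regime) matrix of per-pixel
#'   modal intensity, class `pt_background`.
#' @export
reconstruct_background <- function(seq) {
  if (length(seq) < 2)
    stop("background mode is undefined for a single frame")
  dims <- dim(seq)
  npix <- prod(dims)
  nf <- length(seq)
  v <- unlist(seq$frames, use.names = FALSE)
  levels <- sort(unique(v))
  if (length(levels) <= 4096) {
    code <- findInterval(v, levels)        # exact: every value is a level
    vals <- levels
  } else {
    brk <- seq(min(v), max(v), length.out = 257)
    code <- findInterval(v, brk, rightmost.closed = TRUE)
    vals <- (brk[-257] + brk[-1]) / 2      # bin centres
  }
  nl <- length(vals)
  counts <- tabulate(rep_len(seq_len(npix), npix * nf) + npix * (code - 1),
                     nbins = npix * nl)
  # running arg-max over intensity levels, first (smallest) level wins ties
  best_cnt <- counts[seq_len(npix)]
  best_lvl <- rep(1L, npix)
  for (l in seq_len(nl - 1L)) {
    ci <- counts[(l * npix + 1L):((l + 1L) * npix)]
    upd <- ci > best_cnt
    if (any(upd)) {
      best_cnt[upd] <- ci[upd]
      best_lvl[upd] <- l + 1L
    }
  }
  bg <- matrix(vals[best_lvl], dims[1], dims[2])
  structure(bg, class = c("pt_background", class(bg)))
}

#' Foreground by background subtraction
#'
#' Flags pixels whose absolute difference from the reconstructed background
#' exceeds `tau`. The absolute difference is essential in phase contrast:
#' cell interiors may be darker or brighter than the background while halos
#' are always brighter.
#'
#' @param frame integer matrix.
#' @param bg background from [reconstruct_background()] (same shape).
#' @param tau non-negative grayscale threshold.
#' @return logical foreground mask.
#' @export
subtract_and_threshold <- function(frame, bg, tau) {
  if (tau < 0) stop_config("tau must be >= 0")
  if (!all(dim(frame) == dim(bg))) stop("frame and background shapes differ")
  abs(frame - bg) > tau
}

#' Default subtraction threshold from the residual noise level
#'
#' Estimates the noise s.d. robustly as 1.4826 x the median absolute
#' frame-minus-background difference (pooled over frames) and returns three
#' times that value.
#'
#' @param seq a [image_sequence()].
#' @param bg reconstructed background.
#' @param n_sample number of frames to pool (evenly spaced).
#' @return numeric threshold.
#' @export
estimate_tau <- function(seq, bg, n_sample = 16L) {
  idx <- unique(round(seq.int(1, length(seq), length.out = min(n_sample, length(seq)))))
  res <- unlist(lapply(seq$frames[idx], function(f) abs(f - bg)),
                use.names = FALSE)
  3 * 1.4826 * median(res)
}

#' Segment a sequence by background reconstruction and subtraction
#'
#' @param seq a [image_sequence()].
#' @param tau grayscale threshold; default estimated by [estimate_tau()].
#' @param bg optional precomputed background (e.g. reconstructed once from
#'   the full acquisition and reused for subsampled versions).
#' @return list of logical masks, one per frame, with attributes
#'   `background` and `tau`.
#' @export
segment_bgsub <- function(seq, tau = NULL, bg = NULL) {
  if (is.null(bg)) bg <- reconstruct_background(seq)
  if (is.null(tau)) tau <- estimate_tau(seq, bg)
  masks <- lapply(seq$frames, subtract_and_threshold, bg = bg, tau = tau)
  structure(masks, background = bg, tau = tau)
}
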
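#' Motion model configuration for the synthetic time-lapse simulator
#'
#' Cells follow a Gaussian-step random walk with an optional constant drift:
#' the displacement of cell `c` over one frame of `dt` seconds is
#' `drift * dt + N(0, sigma_c^2 I)`, where the per-axis step s.d. `sigma_c`
#' is calibrated so the expected step length equals `s_c * dt` for the
#' cell's own speed `s_c ~ N(speed_mean, speed_sd)` (truncated at 0):
#' for an isotropic bivariate Gaussian, `E|step| = sigma * sqrt(pi/2)`.
#' Slow-moving adherent cells (HT1080, nHEK) move at under 1 um/min, about
#' one cell-body length per hour; drift models chemotactically directed
#' migration, with positive row drift pointing south (down the image).
#'
#' @param n_cells number of simulated cells.
#' @param frame_count number of frames (>= 2).
#' @param base_interval seconds between frames.
#' @param pixel_size um/px spatial calibration.
#' @param speed_mean,speed_sd mean and s.d. of per-cell random-walk speed,
#'   um/min. `speed_mean = 0` disables the random component.
#' @param drift length-2 drift velocity (row, col) in um/min; positive row
#'   drift is southward.
#' @param image_shape `(rows, cols)` of the view plane in px.
#' @param boundary_mode `"open"` (cells wander off the view plane and are
#'   dropped from the ground truth while outside) or `"reflect"` (closed
#'   box, useful for controlled tests).
#' @param min_separation minimum centre-to-centre distance (px) between
#'   cells at seeding. Adherent cells occupy space and do not stack, so
#'   initial positions are drawn with hard-core exclusion; 0 disables it.
#'   Later motion is interaction-free, so cells may still meet.
#' @param seed integer seed making the motion draw reproducible; `NULL`
#'   uses (and advances) the current RNG state.
#' @return a `pt_motion_config` list.
#' @export
motion_config <- function(n_cells, frame_count = 480L, base_interval = 30,
                          pixel_size = 1.61, speed_mean = 0.8,
                          speed_sd = 0, drift = c(0, 0),
                          image_shape = c(256L, 256L),
                          boundary_mode = c("open", "reflect"),
                          min_separation = 0,
                          seed = NULL) {
  boundary_mode <- match.arg(boundary_mode)
  if (n_cells < 0) stop_config("n_cells must be >= 0")
  if (frame_count < 2) stop_config("frame_count must be >= 2")
  if (pixel_size <= 0) stop_config("pixel_size must be positive")
  if (speed_mean < 0) stop_config("speed_mean must be >= 0")
  if (length(drift) != 2) stop_config("drift must be a (row, col) 2-vector")
  structure(list(n_cells = as.integer(n_cells),
                 frame_count = as.integer(frame_count),
                 base_interval = base_interval, pixel_size = pixel_size,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 drift = as.numeric(drift),
                 image_shape = as.integer(image_shape),
                 boundary_mode = boundary_mode,
                 min_separation = min_separation, seed = seed),
            class = "pt_motion_config")
}

#' Phase-contrast rendering configuration
#'
#' Each cell is rendered as an interior disk (intensity drawn per cell per
#' frame from `interior_intensity_range`, emulating interiors that flip
#' between dark and bright) surrounded by a bright halo annulus of width
#' `halo_width`, on a uniform background with additive Gaussian noise.
#'
#' @param cell_radius_mean,cell_radius_sd per-cell body radius, px.
#' @param interior_intensity_range grayscale `(lo, hi)`; interiors are drawn
#'   uniformly from this range.
#' @param halo_intensity grayscale value of the halo ring (must exceed the
#'   background).
#' @param halo_width halo annulus width, px (> 0).
#' @param background_level uniform background grayscale value.
#' @param noise_sd additive Gaussian noise s.d., grayscale units.
#' @param bit_depth 8 or 16.
#' @param radius_jitter_sd optional per-frame radius jitter s.d. (px),
#'   a crude stand-in for cell-area changes such as filopodia growth.
#' @return a `pt_render_config` list.
#' @export
render_config <- function(cell_radius_mean = 7, cell_radius_sd = 1,
                          interior_intensity_range = c(30, 220),
                          halo_intensity = 200, halo_width = 2,
                          background_level = 100, noise_sd = 3,
                          bit_depth = 8L, radius_jitter_sd = 0) {
  if (halo_width <= 0) stop_config("halo_width must be > 0")
  if (!(halo_intensity > background_level))
    stop_config("halo_intensity must exceed background_level")
  if (!(background_level > min(interior_intensity_range)))
    stop_config("background_level must exceed the darkest interior intensity")
  structure(list(cell_radius_mean = cell_radius_mean,
                 cell_radius_sd = cell_radius_sd,
                 interior_intensity_range = as.numeric(interior_intensity_range),
                 halo_intensity = halo_intensity, halo_width = halo_width,
                 background_level = background_level, noise_sd = noise_sd,
                 bit_depth = as.integer(bit_depth),
                 radius_jitter_sd = radius_jitter_sd),
            class = "pt_render_config")
}

new_ground_truth <- function(df, n_cells = NULL, frame_count = NULL) {
  rownames(df) <- NULL
  structure(df,
            n_cells = if (is.null(n_cells)) length(unique(df$cell_id)) else n_cells,
            frame_count = if (is.null(frame_count)) max(df$frame, 0) else frame_count,
            class = c("pt_ground_truth", "data.frame"))
}

#' @export
print.pt_ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d cells over %d frames (%d positions)\n",
              attr(x, "n_cells"), attr(x, "frame_count"), nrow(x)))
  invisible(x)
}

#' Simulate cell motion
#'
#' Draws per-cell trajectories under the biased Gaussian random walk of
#' [motion_config()]. Initial positions are uniform over the view plane.
#' With `boundary_mode = "open"` a cell is absent from the ground truth on
#' frames where its centre lies outside the view plane (it may re-enter);
#' with `"reflect"` positions are folded back at the borders.
#'
#' @param config a [motion_config()].
#' @return a `pt_ground_truth` data frame with columns
#'   `cell_id, frame, row, col` (centre positions in px, 1-based).
#' @export
simulate_motion <- function(config) {
  stopifnot(inherits(config, "pt_motion_config"))
  local_seed(config$seed)
  n <- config$n_cells
  f <- config$frame_count
  sh <- config$image_shape
  if (n == 0) {
    return(new_ground_truth(
      data.frame(cell_id = integer(), frame = integer(),
                 row = numeric(), col = numeric()),
      n_cells = 0L, frame_count = f))
  }
  dt_min <- config$base_interval / 60
  drift_px <- config$drift * dt_min / config$pixel_size
  speeds <- pmax(0, rnorm(n, config$speed_mean, config$speed_sd))
  sigma_px <- speeds * dt_min / sqrt(pi / 2) / config$pixel_size

  rows <- matrix(NA_real_, f, n)
  cols <- matrix(NA_real_, f, n)
  init <- seed_positions(n, sh, config$min_separation)
  rows[1, ] <- init[, 1]
  cols[1, ] <- init[, 2]
  for (t in 2:f) {
    rows[t, ] <- rows[t - 1, ] + drift_px[1] + rnorm(n, 0, sigma_px)
    cols[t, ] <- cols[t - 1, ] + drift_px[2] + rnorm(n, 0, sigma_px)
    if (config$boundary_mode == "reflect") {
      rows[t, ] <- reflect_into(rows[t, ], sh[1])
      cols[t, ] <- reflect_into(cols[t, ], sh[2])
    }
  }
  df <- data.frame(cell_id = rep(seq_len(n), each = f),
                   frame = rep(seq_len(f), n),
                   row = as.vector(rows), col = as.vector(cols))
  if (config$boundary_mode == "open") {
    inside <- df$row >= 1 & df$row <= sh[1] & df$col >= 1 & df$col <= sh[2]
    df <- df[inside, ]
  }
  new_ground_truth(df, n_cells = n, frame_count = f)
}

# uniform seeding with hard-core exclusion (dart throwing)
seed_positions <- function(n, sh, min_sep) {
  pos <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    cand <- c(runif(1, 1, sh[1]), runif(1, 1, sh[2]))
    ok <- placed == 0 || min_sep <= 0 ||
      min((pos[seq_len(placed), 1] - cand[1])^2 +
            (pos[seq_len(placed), 2] - cand[2])^2) >= min_sep^2
    attempts <- attempts + 1L
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    } else if (attempts > 200L * n) {
      stop_config("cannot seed ", n, " cells at min_separation ", min_sep,
                  " px in a ", sh[1], " x ", sh[2], " view plane")
    }
  }
  pos
}

reflect_into <- function(x, upper) {
  # fold into [1, upper]; repeat for steps larger than the box
  repeat {
    below <- x < 1
    above <- x > upper
    if (!any(below | above)) return(x)
    x[below] <- 2 - x[below]
    x[above] <- 2 * upper - x[above]
  }
}

#' Render a simulated sequence as phase-contrast-like images
#'
#' Draws every cell present on a frame as an interior disk plus bright halo
#' annulus, adds Gaussian noise, and clips/rounds to the configured bit
#' depth. The rendering consumes its own RNG sub-stream (`seed`), so the
#' motion draw is unchanged by rendering settings.
#'
#' @param gt a `pt_ground_truth` from [simulate_motion()].
#' @param rcfg a [render_config()].
#' @param mcfg the [motion_config()] used for the ground truth (supplies
#'   image shape, interval and pixel size).
#' @param seed integer seed for the rendering sub-stream (radii, interior
#'   intensities, noise); `NULL` uses the current RNG state.
#' @return a [image_sequence()].
#' @export
render_sequence <- function(gt, rcfg, mcfg, seed = NULL) {
  stopifnot(inherits(rcfg, "pt_render_config"),
            inherits(mcfg, "pt_motion_config"))
  local_seed(seed)
  sh <- mcfg$image_shape
  f <- mcfg$frame_count
  n <- attr(gt, "n_cells")
  maxv <- 2^rcfg$bit_depth - 1
  radii <- pmax(2, rnorm(n, rcfg$cell_radius_mean, rcfg$cell_radius_sd))
  by_frame <- split(gt[c("cell_id", "row", "col")], gt$frame)
  frames <- vector("list", f)
  for (t in seq_len(f)) {
    img <- matrix(rcfg$background_level, sh[1], sh[2])
    cells <- by_frame[[as.character(t)]]
    if (!is.null(cells) && nrow(cells) > 0) {
      ints <- runif(nrow(cells), rcfg$interior_intensity_range[1],
                    rcfg$interior_intensity_range[2])
      jit <- if (rcfg$radius_jitter_sd > 0)
        rnorm(nrow(cells), 0, rcfg$radius_jitter_sd) else numeric(nrow(cells))
      for (ci in seq_len(nrow(cells))) {
        r <- max(1, radii[cells$cell_id[ci]] + jit[ci])
        img <- draw_cell(img, cells$row[ci], cells$col[ci], r,
                         rcfg$halo_width, ints[ci], rcfg$halo_intensity)
      }
    }
    if (rcfg$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, rcfg$noise_sd), sh[1], sh[2])
    img <- round(pmin(pmax(img, 0), maxv))
    storage.mode(img) <- "integer"
    frames[[t]] <- img
  }
  image_sequence(frames, pixel_size = mcfg$pixel_size,
                 interval = mcfg$base_interval, bit_depth = rcfg$bit_depth)
}

# paint one cell (interior disk + halo annulus) into img, clipped at borders
draw_cell <- function(img, r0, c0, radius, halo_w, interior, halo) {
  ext <- ceiling(radius + halo_w)
  rr <- max(1, floor(r0 - ext)):min(nrow(img), ceiling(r0 + ext))
  cc <- max(1, floor(c0 - ext)):min(ncol(img), ceiling(c0 + ext))
  if (length(rr) == 0 || length(cc) == 0) return(img)
  d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, `+`))
  patch <- img[rr, cc]
  patch[d > radius & d <= radius + halo_w] <- halo
  patch[d <= radius] <- interior
  img[rr, cc] <- patch
  img
}

#' Preset synthetic datasets
#'
#' Four scenarios emulating chemotaxis-chamber experiments with two
#' slow-moving adherent cell lines, imaged at 4x phase contrast
#' (1.61 um/px) with a 30 s base interval:
#'
#' * `random_HT1080` - HT1080 fibrosarcoma, uniform serum, unbiased random
#'   walk (26 cells).
#' * `directed_HT1080` - HT1080 under a serum gradient placed at the south
#'   of the view plane: southward drift of 0.4 um/min on top of the random
#'   walk; the densest scenario (60 cells).
#' * `random_nHEK_gradient` - keratinocytes under a growth-factor gradient
#'   that elicits no chemotactic response: zero drift (20 cells).
#' * `random_nHEK` - keratinocytes, uniform medium, zero drift (23 cells).
#'
#' HT1080 random-walk speed defaults to 0.8 um/min and nHEK to 0.5 um/min,
#' both under the 1 um/min ceiling characteristic of mesenchymal migration.
#'
#' @param scenario one of the four names above.
#' @param seed integer seed; motion and rendering consume derived
#'   sub-streams so the same seed reproduces the dataset exactly.
#' @param frame_count frames to simulate (default 480, i.e. 4 h at 30 s;
#'   full-length 24 h acquisitions use 2880).
#' @param image_shape view plane in px.
#' @return list with elements `sequence` ([image_sequence()]),
#'   `ground_truth` (`pt_ground_truth`), `motion_config`, `render_config`.
#' @export
make_dataset <- function(scenario = c("random_HT1080", "directed_HT1080",
                                      "random_nHEK_gradient", "random_nHEK"),
                         seed = 1L, frame_count = 480L,
                         image_shape = c(256L, 256L)) {
  scenario <- match.arg(scenario)
  preset <- switch(scenario,
    random_HT1080        = list(n = 26L, speed = 0.8, sd = 0.2, drift = c(0, 0)),
    directed_HT1080      = list(n = 60L, speed = 0.8, sd = 0.2, drift = c(0.4, 0)),
    random_nHEK_gradient = list(n = 20L, speed = 0.5, sd = 0.15, drift = c(0, 0)),
    random_nHEK          = list(n = 23L, speed = 0.5, sd = 0.15, drift = c(0, 0)))
  mcfg <- motion_config(n_cells = preset$n, frame_count = frame_count,
                        base_interval = 30, pixel_size = 1.61,
                        speed_mean = preset$speed, speed_sd = preset$sd,
                        drift = preset$drift, image_shape = image_shape,
                        boundary_mode = "open", min_separation = 20,
                        seed = seed)
  rcfg <- render_config()
  gt <- simulate_motion(mcfg)
  # distinct sub-stream for rendering so motion is invariant to render settings
  seq <- render_sequence(gt, rcfg, mcfg, seed = seed + 1000003L)
  list(sequence = seq, ground_truth = gt,
       motion_config = mcfg, render_config = rcfg)
}

#' Construct a ground-truth table
#'
#' @param cell_id,frame,row,col parallel vectors: cell identity, 1-based
#'   frame number, and centre position in px.
#' @return a `pt_ground_truth` data frame.
#' @export
ground_truth <- function(cell_id, frame, row, col) {
  new_ground_truth(data.frame(cell_id = cell_id, frame = frame,
                              row = row, col = col))
}

#' Mixed-speed scene for adaptive-interval demonstrations
#'
#' Composes two subpopulations in one view plane: slowly migrating
#' mesenchymal-type cells (drift 0.8 um/min southward plus a mild random
#' walk) that the linker carries at any interval in the 30 s - 15 min
#' range, and fast amoeboid-type cells (10 um/min random walk, the speed
#' class of immune cells) whose diffusive step length grows with the
#' interval and overwhelms a fixed linking threshold at long intervals.
#' Link quality therefore falls with the interval in a controlled way:
#' near 1 at short intervals, dropping by roughly the fast-cell fraction
#' times their step-loss probability at long ones. Used to demonstrate
#' closed-loop interval control.
#'
#' @param seed integer seed.
#' @param frame_count frames at the 30 s base interval.
#' @param n_slow,n_fast subpopulation sizes.
#' @param image_shape view plane in px.
#' @return list with `sequence`, `ground_truth`, and the two motion
#'   configurations (`slow_config`, `fast_config`).
#' @export
make_speed_mix_dataset <- function(seed = 1L, frame_count = 480L,
                                   n_slow = 15L, n_fast = 40L,
                                   image_shape = c(400L, 400L)) {
  slow <- motion_config(n_cells = n_slow, frame_count = frame_count,
                        base_interval = 30, pixel_size = 1.61,
                        speed_mean = 0.2, speed_sd = 0, drift = c(0.8, 0),
                        image_shape = image_shape, boundary_mode = "open",
                        min_separation = 25, seed = seed)
  fast <- motion_config(n_cells = n_fast, frame_count = frame_count,
                        base_interval = 30, pixel_size = 1.61,
                        speed_mean = 10, speed_sd = 0, drift = c(0, 0),
                        image_shape = image_shape, boundary_mode = "open",
                        min_separation = 25, seed = seed + 500009L)
  gt <- merge_ground_truth(simulate_motion(slow), simulate_motion(fast))
  rcfg <- render_config()
  seq <- render_sequence(gt, rcfg, slow, seed = seed + 1000003L)
  list(sequence = seq, ground_truth = gt, slow_config = slow,
       fast_config = fast, render_config = rcfg)
}

#' Pool several ground truths into one scene
#'
#' Utility for composing mixed cell populations (e.g. a slow and a fast
#' subpopulation simulated with different [motion_config()]s but rendered
#' into one sequence). Cell ids of later sets are shifted to stay unique.
#'
#' @param ... `pt_ground_truth` objects over the same frame range.
#' @return a combined `pt_ground_truth`.
#' @export
merge_ground_truth <- function(...) {
  gts <- list(...)
  offset <- 0L
  out <- lapply(gts, function(g) {
    g$cell_id <- g$cell_id + offset
    offset <<- offset + attr(g, "n_cells")
    as.data.frame(g)
  })
  new_ground_truth(do.call(rbind, out), n_cells = offset,
                   frame_count = max(vapply(gts, attr, 0, "frame_count")))
}
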
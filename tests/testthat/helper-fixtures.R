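# Shared fixtures and independent oracles, built in code at test time.

# Independent brute-force replay of the recursive greedy linker: at every
# step the FULL remaining distance array is re-listed and re-sorted (by
# distance, then (i, j) lexicographically), the head is linked if within D,
# and its row/column entries are struck out. Kept deliberately naive and
# separate from the implementation it checks.
brute_force_links <- function(A, B, D) {
  na <- nrow(A); nb <- nrow(B)
  out <- data.frame(i = integer(), j = integer(), dist = numeric())
  if (na == 0 || nb == 0) return(out)
  entries <- expand.grid(i = seq_len(na), j = seq_len(nb))
  entries$dist <- sqrt((A$row[entries$i] - B$row[entries$j])^2 +
                         (A$col[entries$i] - B$col[entries$j])^2)
  repeat {
    if (nrow(entries) == 0) break
    entries <- entries[order(entries$dist, entries$i, entries$j), ]
    top <- entries[1, ]
    if (top$dist > D) break
    out <- rbind(out, data.frame(i = top$i, j = top$j, dist = top$dist))
    entries <- entries[entries$i != top$i & entries$j != top$j, ]
  }
  rownames(out) <- NULL
  out
}

random_objects <- function(n, extent = 20) {
  phasetrack:::new_objects(
    data.frame(label = seq_len(n), area = rep(25, n),
               row = runif(n, 0, extent), col = runif(n, 0, extent)))
}

objects_at <- function(pos) {
  # pos: list of c(row, col)
  if (length(pos) == 0) {
    return(phasetrack:::new_objects(
      data.frame(label = integer(), area = numeric(),
                 row = numeric(), col = numeric())))
  }
  m <- do.call(rbind, pos)
  phasetrack:::new_objects(
    data.frame(label = seq_len(nrow(m)), area = rep(25, nrow(m)),
               row = m[, 1], col = m[, 2]))
}

# hand-built tracks object
tracks_from <- function(points, interval = 30, origin_duration = NULL) {
  # points: data.frame(track_id, frame, row, col)
  points$time_s <- (points$frame - 1) * interval
  phasetrack:::new_tracks(points[c("track_id", "frame", "time_s",
                                   "row", "col")],
                          interval = interval,
                          origin_duration = origin_duration)
}

# small noise-free rendered scene with well-separated cells
tiny_scene <- function(n_frames = 6, noise_sd = 0, drift = c(0.8, 0),
                       n_cells = 3, shape = c(96L, 96L), seed = 7,
                       speed_mean = 0, speed_sd = 0, min_sep = 30,
                       boundary = "reflect") {
  mcfg <- motion_config(n_cells = n_cells, frame_count = n_frames,
                        base_interval = 30, pixel_size = 1.61,
                        speed_mean = speed_mean, speed_sd = speed_sd,
                        drift = drift, image_shape = shape,
                        boundary_mode = boundary,
                        min_separation = min_sep, seed = seed)
  rcfg <- render_config(noise_sd = noise_sd, cell_radius_sd = 0.5)
  gt <- simulate_motion(mcfg)
  list(seq = render_sequence(gt, rcfg, mcfg, seed = seed + 1),
       gt = gt, mcfg = mcfg, rcfg = rcfg)
}

# two cells whose halo rims nearly touch (3 px gap), plus one far cell
touching_pair_frame <- function(shape = c(80L, 120L), radius = 10,
                                halo_w = 2, gap = 3, background = 100,
                                interior = c(40, 210), halo = 200) {
  img <- matrix(background, shape[1], shape[2])
  centre_dist <- 2 * (radius + halo_w) + gap
  c1 <- c(40, 35)
  c2 <- c(40, 35 + centre_dist)
  c3 <- c(20, 95)
  img <- phasetrack:::draw_cell(img, c1[1], c1[2], radius, halo_w,
                                interior[1], halo)
  img <- phasetrack:::draw_cell(img, c2[1], c2[2], radius, halo_w,
                                interior[2], halo)
  img <- phasetrack:::draw_cell(img, c3[1], c3[2], radius, halo_w,
                                interior[1], halo)
  storage.mode(img) <- "integer"
  list(frame = img, centres = rbind(c1, c2, c3), background = background,
       radius = radius, halo_w = halo_w)
}
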
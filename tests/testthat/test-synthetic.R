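test_that("noise-free drift moves every cell exactly drift * dt", {
  cfg <- motion_config(n_cells = 5, frame_count = 10, base_interval = 30,
                       pixel_size = 1.61, speed_mean = 0, speed_sd = 0,
                       drift = c(0.8, 0), image_shape = c(200L, 200L),
                       boundary_mode = "reflect", seed = 11)
  gt <- simulate_motion(cfg)
  step_px <- 0.8 * 0.5 / 1.61          # 0.4 um per 30 s frame -> px
  for (id in 1:5) {
    p <- gt[gt$cell_id == id, ]
    expect_equal(diff(p$row), rep(step_px, 9), tolerance = 1e-12)
    expect_equal(diff(p$col), rep(0, 9), tolerance = 1e-12)
  }
  expect_equal(step_px, 0.248, tolerance = 1e-2)
})

test_that("motion is deterministic given a seed and symmetric without drift", {
  cfg <- motion_config(n_cells = 200, frame_count = 50, speed_mean = 0.8,
                       image_shape = c(3000L, 3000L),
                       boundary_mode = "reflect", seed = 42)
  g1 <- simulate_motion(cfg)
  g2 <- simulate_motion(cfg)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  # zero drift: mean net displacement ~ 0 and southward fraction near 1/2
  v <- do.call(rbind, lapply(split(g1, g1$cell_id), function(p) {
    c(p$row[nrow(p)] - p$row[1], p$col[nrow(p)] - p$col[1])
  }))
  expect_lt(abs(mean(v[, 1])), 1)
  expect_lt(abs(mean(v[, 2])), 1)
  p_south <- mean(v[, 1] > 0)
  expect_gt(p_south, 0.5 - 2.576 * sqrt(0.25 / 200))
  expect_lt(p_south, 0.5 + 2.576 * sqrt(0.25 / 200))
})

test_that("empirical mean speed recovers speed_mean within 5%", {
  cfg <- motion_config(n_cells = 60, frame_count = 120, speed_mean = 0.8,
                       speed_sd = 0, image_shape = c(4000L, 4000L),
                       boundary_mode = "reflect", seed = 5)
  gt <- simulate_motion(cfg)
  path <- vapply(split(gt, gt$cell_id), function(p) {
    sum(sqrt(diff(p$row)^2 + diff(p$col)^2))
  }, numeric(1)) * 1.61                       # px -> um
  speed <- sum(path) / (60 * 119 * 0.5)       # um per minute
  expect_equal(speed, 0.8, tolerance = 0.05)
})

test_that("configuration errors are rejected", {
  expect_error(motion_config(n_cells = 5, frame_count = 1), "frame_count")
  expect_error(motion_config(n_cells = 5, pixel_size = 0), "pixel_size")
  expect_error(render_config(halo_width = 0), "halo_width")
  expect_error(render_config(halo_intensity = 90, background_level = 100),
               "halo_intensity")
})

test_that("empty and static scenes render exactly", {
  cfg0 <- motion_config(n_cells = 0, frame_count = 3,
                        image_shape = c(40L, 40L), seed = 1)
  rc <- render_config(noise_sd = 0)
  seq0 <- render_sequence(simulate_motion(cfg0), rc, cfg0)
  for (f in seq0$frames) expect_true(all(f == rc$background_level))

  # static cell, no noise, fixed interior intensity -> identical frames
  cfg1 <- motion_config(n_cells = 1, frame_count = 4, speed_mean = 0,
                        image_shape = c(64L, 64L),
                        boundary_mode = "reflect", seed = 2)
  rc1 <- render_config(noise_sd = 0, interior_intensity_range = c(60, 60))
  seq1 <- render_sequence(simulate_motion(cfg1), rc1, cfg1, seed = 3)
  for (t in 2:4) expect_identical(seq1$frames[[t]], seq1$frames[[1]])
})

test_that("halo is the brightest ring along a ray from the cell centre", {
  cfg <- motion_config(n_cells = 1, frame_count = 2, speed_mean = 0,
                       image_shape = c(64L, 64L),
                       boundary_mode = "reflect", seed = 3)
  gt <- simulate_motion(cfg)
  rc <- render_config(noise_sd = 0, cell_radius_mean = 8, cell_radius_sd = 0,
                      interior_intensity_range = c(30, 60))
  seq <- render_sequence(gt, rc, cfg, seed = 4)
  img <- seq$frames[[1]]
  ctr <- gt[gt$frame == 1, c("row", "col")]
  d <- sqrt(outer((seq_len(64) - ctr$row)^2, (seq_len(64) - ctr$col)^2, `+`))
  inside <- d <= 8 + rc$halo_width + 3
  peak_d <- d[inside][which.max(img[inside])]
  expect_gte(peak_d, 8)
  expect_lte(peak_d, 8 + rc$halo_width)
})

test_that("rendered foreground area matches the analytic disk sum within 10%", {
  sc <- tiny_scene(n_frames = 2, drift = c(0, 0), n_cells = 4,
                   shape = c(200L, 200L), seed = 9)
  img <- sc$seq$frames[[1]]
  fg <- sum(img != sc$rcfg$background_level)
  radii <- pmax(2, withr::with_seed(10, # mirrors render's radius draw
    rnorm(4, sc$rcfg$cell_radius_mean, sc$rcfg$cell_radius_sd)))
  analytic <- sum(pi * (radii + sc$rcfg$halo_width)^2)
  expect_equal(fg, analytic, tolerance = 0.10)
})

test_that("scenario presets encode the experimental design", {
  d2 <- make_dataset("directed_HT1080", seed = 1, frame_count = 6)
  expect_gt(d2$motion_config$drift[1], 0)       # chemoattractant at south
  d1 <- make_dataset("random_HT1080", seed = 1, frame_count = 6)
  expect_identical(d1$motion_config$drift, c(0, 0))
  for (ds in list(d1, d2)) {
    expect_equal(ds$sequence$pixel_size, 1.61)
    expect_equal(ds$sequence$interval, 30)
  }
  expect_error(make_dataset("mystery_cells", seed = 1), "arg")
  # same seed twice -> identical dataset; rendering has its own sub-stream
  d2b <- make_dataset("directed_HT1080", seed = 1, frame_count = 6)
  expect_identical(d2$sequence$frames, d2b$sequence$frames)
  expect_identical(as.data.frame(d2$ground_truth),
                   as.data.frame(d2b$ground_truth))
})

test_that("open boundaries drop cells outside the view plane", {
  cfg <- motion_config(n_cells = 40, frame_count = 30, speed_mean = 0,
                       speed_sd = 0, drift = c(8, 0),   # strong southward push
                       image_shape = c(50L, 50L), base_interval = 300,
                       boundary_mode = "open", seed = 8)
  gt <- simulate_motion(cfg)
  expect_lt(sum(gt$frame == 30), sum(gt$frame == 1))
  expect_true(all(gt$row >= 1 & gt$row <= 50))
  # frames strictly increasing per cell
  for (p in split(gt$frame, gt$cell_id)) expect_true(all(diff(p) > 0))
})

test_that("merge_ground_truth pools populations with unique ids", {
  a <- simulate_motion(motion_config(n_cells = 3, frame_count = 4,
                                     boundary_mode = "reflect", seed = 1))
  b <- simulate_motion(motion_config(n_cells = 2, frame_count = 4,
                                     boundary_mode = "reflect", seed = 2))
  m <- merge_ground_truth(a, b)
  expect_equal(attr(m, "n_cells"), 5)
  expect_setequal(unique(m$cell_id), 1:5)
})
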
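test_that("south/east calls use strict inequalities on net displacement", {
  tr <- tracks_from(data.frame(
    track_id = c(1, 1, 2, 2, 3, 3),
    frame = c(1, 2, 1, 2, 1, 2),
    row = c(0, 5, 0, 0, 10, 9),
    col = c(0, -3, 0, 0, 0, 4)))
  ms <- directional_stats(tr)
  expect_equal(ms$n_tracks, 3)
  expect_equal(ms$n_south, 1)                 # down 5 yes; tie no; up no
  expect_equal(ms$n_east, 1)                  # left no; tie no; right yes
  # zero net displacement counts as neither
  still <- tracks_from(data.frame(track_id = c(1, 1), frame = 1:2,
                                  row = c(3, 3), col = c(4, 4)))
  ms0 <- directional_stats(still)
  expect_equal(c(ms0$n_south, ms0$n_east), c(0, 0))
})

test_that("percentages reproduce printed table arithmetic", {
  expect_equal(pct_of(73, 93), 78.5)
  expect_equal(pct_of(35, 60), 58.3)
  expect_true(is.na(pct_of(0, 0)))
  expect_equal(round_half_up(0.05, 1), 0.1)   # halves go up
})

test_that("star plot vectors are end-minus-start, one per track", {
  tr <- tracks_from(data.frame(track_id = c(1, 1, 1, 2, 2),
                               frame = c(1, 2, 3, 1, 2),
                               row = c(10, 14, 20, 7, 7),
                               col = c(10, 30, 15, 2, 2)))
  v <- star_plot_vectors(tr)
  expect_equal(nrow(v), n_tracks(tr))
  expect_equal(v$drow, c(10, 0))
  expect_equal(v$dcol, c(5, 0))
})

test_that("confluence is the covered fraction of the view plane", {
  expect_equal(compute_confluence(matrix(FALSE, 10, 10)), 0)
  half <- matrix(c(TRUE, FALSE), 10, 10)
  expect_equal(compute_confluence(half), 50)
  m <- matrix(FALSE, 100, 100)
  m[seq_len(500)] <- TRUE
  expect_equal(compute_confluence(m), 5.0)
  expect_equal(confluence_range(list(matrix(FALSE, 2, 2), half)), c(0, 50))
})

test_that("strict accuracy fails a track on one identity switch or lost point", {
  gt <- phasetrack:::new_ground_truth(data.frame(
    cell_id = rep(1:2, each = 3), frame = rep(1:3, 2),
    row = c(10, 11, 12, 40, 41, 42), col = rep(5, 6)))
  faithful <- tracks_from(data.frame(track_id = 1, frame = 1:3,
                                     row = c(10, 11, 12), col = 5))
  expect_equal(evaluate_accuracy(faithful, gt, 5)$accuracy, 100)

  switcher <- tracks_from(data.frame(track_id = 2, frame = 1:3,
                                     row = c(10, 11, 42), col = 5))
  cols <- c("track_id", "frame", "row", "col")
  both <- tracks_from(rbind(as.data.frame(faithful)[cols],
                            as.data.frame(switcher)[cols]))
  r <- evaluate_accuracy(both, gt, 5)
  expect_equal(r$accuracy, 50)
  expect_equal(r$per_track$first_error_frame[r$per_track$track_id == 2], 3)

  # a point farther than match_radius from every cell is a failure
  lost <- tracks_from(data.frame(track_id = 1, frame = 1:3,
                                 row = c(10, 25, 12), col = 5))
  expect_equal(evaluate_accuracy(lost, gt, 5)$accuracy, 0)
  expect_error(evaluate_accuracy(faithful, gt, 0), "match_radius")
})

test_that("accuracy is invariant to track relabelling and row order", {
  set.seed(14)
  gt <- phasetrack:::new_ground_truth(data.frame(
    cell_id = rep(1:4, each = 5), frame = rep(1:5, 4),
    row = as.vector(replicate(4, cumsum(c(runif(1, 10, 90), rnorm(4))))),
    col = as.vector(replicate(4, cumsum(c(runif(1, 10, 90), rnorm(4)))))))
  tr <- tracks_from(data.frame(track_id = gt$cell_id, frame = gt$frame,
                               row = gt$row + rnorm(20, 0, 0.3),
                               col = gt$col + rnorm(20, 0, 0.3)))
  base <- evaluate_accuracy(tr, gt, 5)
  relab <- tr
  relab$track_id <- c(9, 2, 7, 5)[relab$track_id]
  shuf <- relab[sample(nrow(relab)), ]
  shuffled <- tracks_from(as.data.frame(shuf))
  r2 <- evaluate_accuracy(shuffled, gt, 5)
  expect_equal(r2$accuracy, base$accuracy)
  expect_equal(r2$n_correct, base$n_correct)
})

test_that("the interval sweep emits one ordered row per requested interval", {
  sc <- tiny_scene(n_frames = 24, noise_sd = 2, drift = c(2, 0),
                   n_cells = 4, shape = c(220L, 120L))
  cfg <- run_config(intervals_to_sweep = c(120, 30, 60),
                    duration_fraction = 0.3)
  sw <- interval_sweep(sc$seq, sc$gt, cfg)
  expect_s3_class(sw, "pt_sweep")
  expect_equal(sw$interval_s, c(30, 60, 120))
  expect_true(all(sw$n_south <= sw$n_tracks))
  expect_error(interval_sweep(sc$seq, sc$gt,
                              run_config(intervals_to_sweep = c(45))),
               "multiple")
  # the k = 1 row reproduces a direct unsubsampled run
  direct <- track_cells(sc$seq, "bgsub", D = 10, duration_fraction = 0.3)
  expect_equal(sw$n_tracks[1], n_tracks(direct))
})
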
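test_that("mask_to_objects filters by area and averages pixel coordinates", {
  m <- matrix(FALSE, 30, 30)
  m[2:11, 2:6] <- TRUE                        # 50 px
  m[20:21, 20:24] <- TRUE                     # 10 px
  o <- mask_to_objects(m, c(20, 5000))
  expect_equal(nrow(o), 1)
  expect_equal(o$area, 50)

  m2 <- matrix(FALSE, 10, 10)
  m2[1:3, 1:3] <- TRUE                        # 3x3 square at rows/cols 1-3
  o2 <- mask_to_objects(m2, c(1, 100))
  expect_equal(c(o2$row, o2$col), c(2, 2))

  expect_equal(nrow(mask_to_objects(matrix(FALSE, 5, 5), c(1, 10))), 0)
  expect_error(mask_to_objects(m, c(10, 5)), "min_area")
})

test_that("labelling is 8-connected: diagonal halo pixels join", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE; m[4, 2] <- TRUE
  o <- mask_to_objects(m, c(1, 100))
  expect_equal(nrow(o), 1)
  expect_equal(o$area, 3)
})

test_that("links respect the plausibility threshold D", {
  A <- objects_at(list(c(0, 0)))
  B <- objects_at(list(c(1, 0)))
  l1 <- link_frames(A, B, 5)
  expect_equal(nrow(l1), 1)
  expect_equal(l1$dist, 1)
  B9 <- objects_at(list(c(9, 0)))
  expect_equal(nrow(link_frames(A, B9, 5)), 0)
  expect_equal(nrow(link_frames(objects_at(list()), B, 5)), 0)
  expect_error(link_frames(A, B, 0), "D")
})

test_that("the linker is greedy on the global minimum, not an optimal assignment", {
  A <- objects_at(list(c(0, 0), c(2, 0)))
  B <- objects_at(list(c(1, 0), c(-3, 0)))
  l <- link_frames(A, B, 5)
  # greedy picks (1,1) at d=1 first, forcing (2,2) at d=5: total 6,
  # although the assignment (1,2)+(2,1) would total 4
  expect_equal(l$i, c(1, 2))
  expect_equal(l$j, c(1, 2))
  expect_equal(l$dist, c(1, 5))
  expect_gt(sum(l$dist), 4)
})

test_that("greedy linking matches the re-sort-every-step brute force oracle", {
  set.seed(99)
  for (rep in 1:300) {
    A <- random_objects(sample(0:6, 1))
    B <- random_objects(sample(0:6, 1))
    D <- runif(1, 2, 15)
    got <- link_frames(A, B, D)
    want <- brute_force_links(A, B, D)
    expect_identical(got$i, want$i)
    expect_identical(got$j, want$j)
    expect_equal(got$dist, want$dist)
    # injectivity and threshold invariants on every draw
    expect_false(any(duplicated(got$i)) || any(duplicated(got$j)))
    expect_true(all(got$dist <= D))
  }
})

test_that("distance ties break toward the smallest (i, j)", {
  A <- objects_at(list(c(0, 0), c(0, 4)))
  B <- objects_at(list(c(0, 2)))              # equidistant from both
  l <- link_frames(A, B, 5)
  expect_equal(l$i, 1)
  # and deterministically so
  expect_identical(link_frames(A, B, 5), l)
})

test_that("trajectory assembly chains links and starts tracks at unlinked objects", {
  o1 <- objects_at(list(c(0, 0)))
  o2 <- objects_at(list(c(1, 0)))
  o3 <- objects_at(list(c(2, 0), c(50, 50)))
  links <- list(link_frames(o1, o2, 5), link_frames(o2, o3, 5))
  tr <- build_trajectories(list(o1, o2, o3), links)
  expect_equal(n_tracks(tr), 2)
  expect_equal(sum(tr$track_id == 1), 3)      # a -> b -> c
  expect_equal(sum(tr$track_id == 2), 1)      # the frame-3 newcomer

  # a break ends the first track and the stranded object starts another
  o3b <- objects_at(list(c(50, 50)))
  tr2 <- build_trajectories(list(o1, o2, o3b),
                            list(link_frames(o1, o2, 5),
                                 link_frames(o2, o3b, 5)))
  expect_equal(n_tracks(tr2), 2)
  expect_equal(as.vector(table(tr2$track_id)), c(2, 1))

  # no links at all -> one single-point track per object
  empty <- phasetrack:::new_links(data.frame(i = integer(), j = integer(),
                                             dist = numeric()))
  tr3 <- build_trajectories(list(o3, o3), list(empty))
  expect_equal(n_tracks(tr3), 4)
  expect_true(all(table(tr3$track_id) == 1))
})

test_that("duration filter keeps tracks of at least 15% of the experiment", {
  expect_equal(0.15 * 24 * 3600, 3.6 * 3600)  # 24 h experiment -> 3.6 h
  mk <- function(minutes, id) {
    n <- minutes * 2 + 1                      # 30 s spacing
    data.frame(track_id = id, frame = seq_len(n), row = 0, col = 0)
  }
  tr <- tracks_from(rbind(mk(216, 1), mk(215.5, 2)),   # 3.6 h vs 3.595 h
                    interval = 30, origin_duration = 24 * 3600)
  kept <- filter_trajectories(tr, 0.15)
  expect_equal(unique(kept$track_id), 1)
  expect_equal(n_tracks(filter_trajectories(tr[0, ], 0.15,
                                            experiment_duration_s = 86400)), 0)
  expect_error(filter_trajectories(tr, 1.5), "duration_fraction")
})

test_that("duration threshold follows the original acquisition, not the subsample", {
  sc <- tiny_scene(n_frames = 20, noise_sd = 0, drift = c(2, 0),
                   n_cells = 2, shape = c(200L, 100L))
  sub <- subsample_sequence(sc$seq, 4)
  tr <- track_cells(sub, "bgsub", tau = 5, duration_fraction = NULL)
  expect_equal(attr(tr, "origin_duration"), 20 * 30)
  thr_keep <- filter_trajectories(tr, 0.5)     # 300 s of a 600 s experiment
  durs <- track_durations(thr_keep)
  expect_true(all(durs >= 300))
})

test_that("threshold rule interpolates the printed anchors linearly", {
  rule <- threshold_rule()
  expect_equal(threshold_for_interval(rule, 30), 10)
  expect_equal(threshold_for_interval(rule, 900), 50)
  expect_equal(threshold_for_interval(rule, 300),
               10 + 40 * (300 - 30) / (900 - 30), tolerance = 1e-9)
  expect_equal(threshold_for_interval(rule, 300), 22.41, tolerance = 1e-3)
  # clamped outside, monotone inside
  expect_equal(threshold_for_interval(rule, 10), 10)
  expect_equal(threshold_for_interval(rule, 3600), 50)
  iv <- seq(30, 900, by = 30)
  expect_true(all(diff(threshold_for_interval(rule, iv)) >= 0))
})

test_that("tracking a clean drifting scene recovers every cell exactly", {
  # drift fast enough that cells vacate their footprint over the clip,
  # keeping the temporal-mode background free of ghosts
  sc <- tiny_scene(n_frames = 24, noise_sd = 0, drift = c(6, 0),
                   n_cells = 3, shape = c(200L, 100L), boundary = "open")
  tr <- track_cells(sc$seq, "bgsub", tau = 5, duration_fraction = NULL)
  expect_equal(n_tracks(tr), 3)
  acc <- evaluate_accuracy(tr, sc$gt, match_radius = 10)
  expect_equal(acc$accuracy, 100)
})
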
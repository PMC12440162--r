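no_events <- data.frame(bee_a = integer(0), bee_b = integer(0),
                        start_frame = integer(0), end_frame = integer(0))

test_that("a 40-frame close moving pair yields one interaction per focal", {
  traj <- make_pair_traj(40, sep = 15)
  sp <- instantaneous_speeds(traj)
  ints <- find_proximity_interactions(traj, no_events, sp)
  expect_identical(nrow(ints), 2L)  # once per focal perspective
  expect_setequal(ints$focal_id, 1:2)
  expect_true(all(ints$length == 40))
})

test_that("distance above R_max or runs below L_min yield nothing", {
  far <- make_pair_traj(40, sep = 30)
  sp <- instantaneous_speeds(far)
  expect_identical(nrow(find_proximity_interactions(far, no_events, sp)), 0L)

  short <- make_pair_traj(30, sep = 15)  # 29 speedful frames + frame 0
  # frame 0 has no incoming speed record but both bees are detected; the run
  # is 30 frames of detections -> qualifies; trim to 29 by dropping frame 0
  short29 <- short[short$frame > 0, ]
  attr(short29, "fs") <- 1
  sp29 <- instantaneous_speeds(short29)
  expect_identical(nrow(find_proximity_interactions(short29, no_events, sp29)),
                   0L)
})

test_that("only the first qualifying interaction per pair is kept", {
  a <- make_pair_traj(40, sep = 15)
  gap <- make_traj(bee_id = 1:2, frame = c(45, 45), x = c(0, 200),
                   y = c(0, 0))  # far apart: breaks the run
  b <- make_pair_traj(40, sep = 15)
  b$frame <- b$frame + 50
  b$x_mm <- b$x_mm + 3
  traj <- rbind(a, gap, b)
  attr(traj, "fs") <- 1
  sp <- instantaneous_speeds(traj)
  ints <- find_proximity_interactions(traj, no_events, sp)
  i1 <- ints[ints$focal_id == 1, ]
  expect_identical(nrow(i1), 1L)
  expect_equal(i1$start_frame, 0)
  all_ints <- find_proximity_interactions(
    traj, no_events, sp, proximity_params(first_interaction_only = FALSE))
  expect_identical(nrow(all_ints[all_ints$focal_id == 1, ]), 2L)
})

test_that("low-speed frames break contiguity", {
  traj <- make_pair_traj(80, sep = 15)
  # freeze bee 2 for frames 40..44 (sub-threshold displacement and turn)
  frz <- traj$bee_id == 2 & traj$frame %in% 40:44
  traj$x_mm[frz] <- traj$x_mm[traj$bee_id == 2 & traj$frame == 39] + 0.5
  sp <- instantaneous_speeds(traj)
  ints <- find_proximity_interactions(traj, no_events, sp)
  # distance grows while bee 2 is frozen; remaining within-radius runs are
  # shorter than before but the pre-freeze run of 40 frames must survive
  i1 <- ints[ints$focal_id == 1, ]
  expect_true(all(i1$end_frame < 40))
  expect_error(find_proximity_interactions(traj, no_events, NULL),
               "speeds table")
})

test_that("trophallaxis frames of the pair are excluded, third-party is not", {
  traj <- make_pair_traj(100, sep = 15)
  ev <- data.frame(bee_a = 1, bee_b = 2, start_frame = 0, end_frame = 65,
                   duration_s = 66)
  sp <- instantaneous_speeds(traj)
  ints <- find_proximity_interactions(traj, ev, sp)
  expect_true(all(ints$start_frame >= 66))
  ev3 <- data.frame(bee_a = 1, bee_b = 3, start_frame = 0, end_frame = 65,
                    duration_s = 66)
  ints3 <- find_proximity_interactions(traj, ev3, sp)
  expect_true(any(ints3$start_frame == 0))
})

test_that("every returned interaction passes a full re-scan of the rules", {
  fx <- synthetic_fixture(seed = 2, n_bees = 10, n_frames = 1800)
  traj <- fx$inputs$trajectories
  sp <- instantaneous_speeds(traj)
  ev <- filter_events(merge_raw_events(fx$inputs$raw_trophallaxis))
  prm <- proximity_params()
  ints <- find_proximity_interactions(traj, ev, sp, prm)
  expect_gt(nrow(ints), 0)
  low <- sp[!sp$recorded, c("bee_id", "frame")]
  for (r in seq_len(nrow(ints))) {
    f <- ints$start_frame[r]:ints$end_frame[r]
    expect_gte(length(f), prm$L_min_frames)
    s <- build_bivariate_series(traj, ints$focal_id[r], ints$neighbor_id[r],
                                ints$start_frame[r], ints$end_frame[r], "X")
    sy <- build_bivariate_series(traj, ints$focal_id[r], ints$neighbor_id[r],
                                 ints$start_frame[r], ints$end_frame[r], "Y")
    d <- sqrt((s[, 1] - s[, 2])^2 + (sy[, 1] - sy[, 2])^2)
    expect_true(all(d <= prm$R_max_mm))
    for (id in c(ints$focal_id[r], ints$neighbor_id[r]))
      expect_false(any(low$bee_id == id & low$frame %in% f))
    pe <- ev[ev$bee_a == min(ints$focal_id[r], ints$neighbor_id[r]) &
             ev$bee_b == max(ints$focal_id[r], ints$neighbor_id[r]), ]
    for (j in seq_len(nrow(pe)))
      expect_false(any(f >= pe$start_frame[j] & f <= pe$end_frame[j]))
  }
  # neighbors are distinct under the first-only rule
  expect_false(any(duplicated(ints[c("focal_id", "neighbor_id")])))
})

test_that("tightening the thresholds never adds interactions", {
  fx <- synthetic_fixture(seed = 3, n_bees = 10, n_frames = 1800)
  traj <- fx$inputs$trajectories
  sp <- instantaneous_speeds(traj)
  ev <- filter_events(merge_raw_events(fx$inputs$raw_trophallaxis))
  n_base <- nrow(find_proximity_interactions(traj, ev, sp,
                                             proximity_params()))
  n_tight_r <- nrow(find_proximity_interactions(
    traj, ev, sp, proximity_params(R_max_mm = 10)))
  n_tight_l <- nrow(find_proximity_interactions(
    traj, ev, sp, proximity_params(L_min_frames = 45)))
  expect_lte(n_tight_r, n_base)
  expect_lte(n_tight_l, n_base)
})

test_that("bivariate series reproduce stored coordinates exactly", {
  traj <- make_pair_traj(40, sep = 15)
  s <- build_bivariate_series(traj, 1, 2, 0, 39, "X")
  expect_identical(dim(s), c(40L, 2L))
  expect_equal(s[, "focal"], traj$x_mm[traj$bee_id == 1])
  # swapping focal and neighbor transposes the pair
  s2 <- build_bivariate_series(traj, 2, 1, 0, 39, "X")
  expect_equal(s2[, "focal"], s[, "neighbor"])
  expect_error(build_bivariate_series(traj, 1, 2, 0, 39, "Z"))
  expect_error(build_bivariate_series(traj, 1, 2, 0, 45, "X"), "missing")
})
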
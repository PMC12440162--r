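test_that("trajectory generation is deterministic given the seed", {
  p <- colony_sim_params(n_bees = 4, n_frames = 300, seed = 7)
  a <- simulate_trajectories(p)
  b <- simulate_trajectories(p)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$truth$trophallaxis_events, b$truth$trophallaxis_events)
  c_ <- simulate_trajectories(colony_sim_params(n_bees = 4, n_frames = 300,
                                                seed = 8))
  expect_false(identical(a$trajectories, c_$trajectories))
})

test_that("generator rejects invalid parameters", {
  expect_error(colony_sim_params(n_bees = 1), "n_bees")
  expect_error(colony_sim_params(hive_width_mm = -1), "dimensions")
  expect_error(colony_sim_params(dropout_prob = 1), "dropout")
  expect_error(colony_sim_params(
    coupling = data.frame(leader = 1, follower = 2, c = 1.2)), "\\|c\\| < 1")
  expect_error(colony_sim_params(
    n_bees = 2, coupling = data.frame(leader = 1, follower = 9, c = 0.5)),
    "unknown bee ids")
})

test_that("positions stay inside the hive and orientations in range", {
  p <- colony_sim_params(n_bees = 6, n_frames = 500, seed = 3)
  traj <- simulate_trajectories(p)$trajectories
  expect_true(all(traj$x_mm >= 0 & traj$x_mm <= p$hive_width_mm))
  expect_true(all(traj$y_mm >= 0 & traj$y_mm <= p$hive_height_mm))
  expect_true(all(traj$orientation_deg >= 0 & traj$orientation_deg < 360))
  expect_false(anyDuplicated(traj[c("bee_id", "frame")]) > 0)
})

test_that("uncoupled pairs have near-zero lag-1 displacement correlation", {
  p <- colony_sim_params(n_bees = 2, n_frames = 10000, dropout_prob = 0,
                         stationary_prob = 0, trophallaxis_rate = 0,
                         seed = 11)
  traj <- simulate_trajectories(p)$trajectories
  expect_lt(abs(lag1_displacement_cor(traj, 1, 2)), 0.05)
})

test_that("leader-follower coupling produces positive lag-1 correlation", {
  p <- colony_sim_params(n_bees = 2, n_frames = 10000, dropout_prob = 0,
                         stationary_prob = 0, trophallaxis_rate = 0,
                         encounter_rate = 0,
                         coupling = data.frame(leader = 1, follower = 2,
                                               c = 0.5),
                         seed = 12)
  traj <- simulate_trajectories(p)$trajectories
  r <- lag1_displacement_cor(traj, 1, 2)
  expect_gt(r, 0.2)
  # the forward direction clearly dominates the reverse one (the reverse is
  # not exactly zero: persistent velocities echo the coupling backwards)
  expect_gt(r, abs(lag1_displacement_cor(traj, 2, 1)) + 0.1)
})

test_that("injected trophallaxis episodes hold partners close and still", {
  p <- colony_sim_params(n_bees = 6, n_frames = 2000, dropout_prob = 0,
                         trophallaxis_rate = 4, seed = 5)
  sim <- simulate_trajectories(p)
  ev <- sim$truth$trophallaxis_events
  expect_gt(nrow(ev), 0)
  traj <- sim$trajectories
  for (i in seq_len(min(5, nrow(ev)))) {
    fr <- ev$start_frame[i]:ev$end_frame[i]
    a <- traj[traj$bee_id == ev$bee_a[i] & traj$frame %in% fr, ]
    b <- traj[traj$bee_id == ev$bee_b[i] & traj$frame %in% fr, ]
    frames <- intersect(a$frame, b$frame)
    d <- sqrt((a$x_mm[match(frames, a$frame)] - b$x_mm[match(frames, b$frame)])^2 +
              (a$y_mm[match(frames, a$frame)] - b$y_mm[match(frames, b$frame)])^2)
    expect_true(all(d <= 7.4))
  }
})

test_that("simulate_var matches white-noise covariance for zero coefficients", {
  y <- simulate_var(list(matrix(0, 2, 2)), diag(2), 20000, seed = 1)
  expect_lt(max(abs(stats::cov(y) - diag(2))), 0.05)
})

test_that("simulate_var stationary covariance matches Lyapunov fixed point", {
  A <- matrix(c(0.5, 0.3, 0, 0.5), 2)
  y <- simulate_var(list(A), diag(2), 50000, seed = 2)
  # independent oracle: fixed-point iteration of S = A S A' + Q
  S <- diag(2)
  for (i in 1:500) S <- A %*% S %*% t(A) + diag(2)
  expect_lt(max(abs(stats::cov(y) - S)), 0.05)
})

test_that("unstable VAR coefficients are rejected", {
  expect_error(simulate_var(list(diag(c(1.1, 0.5))), diag(2), 100),
               "unstable")
  expect_error(simulate_var(list(matrix(0, 2, 2)),
                            matrix(c(1, 2, 3, 1), 2), 100), "symmetric")
})

test_that("trip log satisfies / violates the forager rule as designed", {
  tl <- simulate_trip_log(n_bees = 8, n_days = 5, forager_ids = c(1, 2),
                          seed = 4)
  fl <- classify_forager(tl$trips, bee_ids = 1:8)
  expect_identical(fl$forager, tl$truth$is_forager)
  expect_true(all(!is.na(tl$truth$violated[!tl$truth$is_forager])))
  # every violation mode is represented among 6 non-foragers
  expect_setequal(unique(tl$truth$violated[!tl$truth$is_forager]),
                  c("too_few_total", "one_heavy_day", "off_peak", "no_trips"))
})

test_that("zero-day trip log is empty", {
  tl <- simulate_trip_log(n_bees = 3, n_days = 0, seed = 1)
  expect_identical(nrow(tl$trips), 0L)
})

test_that("assay simulation matches its target labels by construction", {
  labels <- c("guard", "nurse", "non_responder", "baseline", "generalist")
  as_ <- simulate_assay(labels, seed = 9)
  dur <- function(b, beh) sum(as_$total_duration_s[as_$bee_id == b &
                                                   as_$behavior %in% beh])
  expect_gte(dur(1, c("bite", "sting")), 20)
  expect_lt(dur(1, c("feed", "inspect")), 20)
  expect_gte(dur(2, c("feed", "inspect")), 20)
  expect_identical(sum(as_$total_duration_s[as_$bee_id == 3]), 0)
  b4 <- as_[as_$bee_id == 4, ]
  expect_true(any(b4$behavior %in% c("fan", "wax", "vibrate")))
  expect_gte(dur(5, c("bite", "sting")), 20)
  expect_gte(dur(5, c("feed", "inspect")), 20)
  expect_error(simulate_assay("queen"), "unknown label")
})

test_that("genotype simulation: PRS ground truth equals the loop oracle", {
  g <- simulate_genotypes(10, 25, effect_sizes = rnorm(25), seed = 3)
  expect_true(all(g$dosages %in% 0:2))
  expect_equal(polygenic_score(g$dosages, g$effects), g$true_prs)
  g0 <- simulate_genotypes(5, 10, effect_sizes = rep(0, 10), seed = 3)
  expect_equal(unname(g0$true_prs), rep(0, 5))
})
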
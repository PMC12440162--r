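test_that("VAR least squares recovers generating coefficients", {
  A <- matrix(c(0.5, 0.3, 0, 0.5), 2)
  y <- simulate_var(list(A), diag(2), 50000, seed = 41)
  fit <- fit_var(y, order = 1)
  expect_lt(max(abs(fit$A[[1]] - A)), 0.02)
  expect_lt(max(abs(fit$Sigma - diag(2))), 0.05)
  # cross-check against the independent base-R estimator
  ref <- stats::ar.ols(y, aic = FALSE, order.max = 1, demean = TRUE,
                       intercept = FALSE)
  expect_lt(max(abs(fit$A[[1]] - ref$ar[1, , ])), 1e-6)
})

test_that("white noise fits to near-zero coefficients", {
  y <- simulate_var(list(matrix(0, 2, 2)), diag(2), 20000, seed = 42)
  fit <- fit_var(y, order = 1)
  expect_lt(max(abs(fit$A[[1]])), 0.05)
})

test_that("degenerate and too-short series raise errors", {
  expect_error(fit_var(cbind(rep(1, 50), rnorm(50)), order = 1), "constant")
  expect_error(fit_var(cbind(rnorm(5), rnorm(5)), order = 3), "too short")
  expect_error(fit_var(cbind(c(1, 2, NA, 4), rnorm(4)), order = 1),
               "non-finite")
})

test_that("automatic order selection finds higher-order structure", {
  # VAR(2) with strong lag-2 signature
  A1 <- matrix(c(0.2, 0, 0, 0.2), 2)
  A2 <- matrix(c(0.5, 0.2, 0, 0.4), 2)
  y <- simulate_var(list(A1, A2), diag(2), 4000, seed = 43)
  fit <- fit_var(y, order = "auto", p_max = 3)
  expect_identical(fit$p, 2L)
  y1 <- simulate_var(list(matrix(c(0.6, 0.2, 0, 0.5), 2)), diag(2), 4000,
                     seed = 44)
  expect_identical(fit_var(y1, order = "auto", p_max = 3)$p, 1L)
})

test_that("iPDC matches the hand-evaluated point and structural zero", {
  m <- structure(list(p = 1L, A = list(matrix(c(0.5, 0.3, 0, 0.5), 2)),
                      Sigma = diag(2), n_obs = 100L, n_used = 99L, k = 2L,
                      ic_table = NULL), class = "var_model")
  sp <- ipdc_spectrum(m, n_freqs = 64, fs = 1)
  # at f = 0: Abar = [[0.5, 0], [-0.3, 0.5]]; 1->2: 0.09 / 0.34
  expect_equal(spectrum_direction(sp, 1, 2)[1], 0.09 / 0.34,
               tolerance = 1e-12)
  expect_true(all(spectrum_direction(sp, 2, 1) == 0))
})

test_that("gPDC equals iPDC for diagonal innovation covariance", {
  set.seed(45)
  mod <- random_stable_var(2, 2)
  m <- structure(list(p = 2L, A = mod$A, Sigma = diag(c(1.7, 0.4)),
                      n_obs = 100L, n_used = 99L, k = 2L, ic_table = NULL),
                 class = "var_model")
  expect_equal(ipdc_spectrum(m, 33, variant = "ipdc")$values,
               ipdc_spectrum(m, 33, variant = "gpdc")$values,
               tolerance = 1e-12)
})

test_that("classic PDC columns are normalized to one", {
  set.seed(46)
  mod <- random_stable_var(2, 3)
  m <- structure(list(p = 3L, A = mod$A, Sigma = mod$Sigma, n_obs = 200L,
                      n_used = 197L, k = 2L, ic_table = NULL),
                 class = "var_model")
  sp <- ipdc_spectrum(m, 33, variant = "pdc")
  v <- sp$values
  # off-diagonal value plus the independently computed diagonal term must
  # sum to 1 for every source column j at every frequency
  for (fi in seq_along(sp$freqs)) for (j in 1:2) {
    z <- exp(-2i * pi * sp$freqs[fi] * (1:3))
    Abar <- diag(2) + 0i
    for (mm in 1:3) Abar <- Abar - mod$A[[mm]] * z[mm]
    diag_term <- Mod(Abar[j, j])^2 / sum(Mod(Abar[, j])^2)
    i <- setdiff(1:2, j)
    expect_equal(v[fi, i, j] + diag_term, 1, tolerance = 1e-12)
  }
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
})

test_that("iPDC stays within [0, 1] across random stable models", {
  set.seed(47)
  for (i in 1:200) {
    p <- sample(1:3, 1)
    mod <- random_stable_var(2, p)
    m <- structure(list(p = p, A = mod$A, Sigma = mod$Sigma, n_obs = 500L,
                        n_used = 497L, k = 2L, ic_table = NULL),
                   class = "var_model")
    v <- ipdc_spectrum(m, 17)$values
    expect_true(all(v >= 0 & v <= 1 + 1e-12, na.rm = TRUE))
  }
})

test_that("information flow reproduces closed forms", {
  f <- seq(0, 0.5, length.out = 128)
  expect_identical(information_flow(rep(0, 128), freqs = f, fs = 1), 0)
  expect_equal(information_flow(rep(0.5, 128), freqs = f, fs = 1), 0.5,
               tolerance = 1e-9)
  f2 <- seq(0, 1, length.out = 128)
  expect_equal(information_flow(rep(0.75, 128), freqs = f2, fs = 2), 1,
               tolerance = 1e-9)
  expect_error(information_flow(rep(1.5, 128), freqs = f, fs = 1),
               "values >= 1")
  expect_error(information_flow(rep(-0.1, 128), freqs = f, fs = 1),
               "negative")
})

test_that("doubling the frequency grid barely changes the flow", {
  set.seed(48)
  mod <- random_stable_var(2, 2)
  m <- structure(list(p = 2L, A = mod$A, Sigma = mod$Sigma, n_obs = 500L,
                      n_used = 497L, k = 2L, ic_table = NULL),
                 class = "var_model")
  f1 <- information_flow(ipdc_spectrum(m, 128), 1, 2)
  f2 <- information_flow(ipdc_spectrum(m, 256), 1, 2)
  expect_lt(abs(f1 - f2), 1e-3)
  expect_gte(f1, 0)
})

test_that("averaging over interactions is an identity for duplicates", {
  traj <- simulate_trajectories(
    colony_sim_params(n_bees = 2, n_frames = 100, dropout_prob = 0,
                      stationary_prob = 0, trophallaxis_rate = 0,
                      encounter_rate = 0, seed = 49))$trajectories
  one <- data.frame(focal_id = 1, neighbor_id = 2, start_frame = 20,
                    end_frame = 79, length = 60)
  two <- rbind(one, one)
  r1 <- social_influence(traj, one, 1)
  r2 <- social_influence(traj, two, 1)
  expect_equal(r1$i_flow_out, r2$i_flow_out)
  expect_equal(r1$i_flow_in, r2$i_flow_in)
  expect_identical(r2$n_interactions, 2L)
  # final flow is the mean of the axis components
  expect_equal(r1$i_flow_out, (r1$i_out_x + r1$i_out_y) / 2)
})

test_that("all-constant interactions produce a diagnostic NA result", {
  traj <- make_traj(bee_id = rep(1:2, each = 40), frame = rep(0:39, 2),
                    x = rep(c(10, 20), each = 40),
                    y = rep(c(10, 20), each = 40), o = 0)
  ints <- data.frame(focal_id = 1, neighbor_id = 2, start_frame = 0,
                     end_frame = 39, length = 40)
  expect_warning(res <- social_influence(traj, ints, 1), "failed to fit")
  expect_true(is.na(res$i_flow_out))
  expect_identical(res$n_failed, 1L)
})

test_that("directional coupling is recovered in the estimated flows", {
  rec <- influence_recovery_experiment(c_values = c(0, 0.6), n_reps = 25,
                                       seed = 50)
  m0 <- rec[rec$c == 0, ]
  m6 <- rec[rec$c == 0.6, ]
  expect_gt(mean(m6$i_leader_to_follower), mean(m0$i_leader_to_follower))
  expect_gt(mean(m6$i_leader_to_follower > m6$i_follower_to_leader), 0.8)
})
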
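# builders for small hand-constructed inputs used across test files

make_traj <- function(bee_id, frame, x, y, o = 0, fs = 1,
                      bounds = c(width_mm = 430, height_mm = 250)) {
  n <- max(length(bee_id), length(frame), length(x), length(y))
  df <- data.frame(bee_id = bee_id, frame = frame, x_mm = x, y_mm = y,
                   orientation_deg = rep(o %% 360, length.out = n))
  attr(df, "fs") <- fs
  attr(df, "hive_bounds") <- bounds
  df
}

# two bees side by side at fixed separation, both stepping `step` mm per
# frame along x (so both are always above the stationarity threshold)
make_pair_traj <- function(n_frames, sep = 15, step = 6, fs = 1) {
  f <- 0:(n_frames - 1)
  rbind_traj <- make_traj(
    bee_id = rep(1:2, each = n_frames),
    frame = c(f, f),
    x = c(10 + step * f, 10 + step * f),
    y = c(rep(100, n_frames), rep(100 + sep, n_frames)),
    o = 0, fs = fs)
  rbind_traj
}

raw_event <- function(a, b, s, e) data.frame(bee_a = a, bee_b = b,
                                             start_frame = s, end_frame = e)

# brute-force upper-tail hypergeometric probability P(X >= k) by direct
# mass summation (independent of stats::phyper)
hyper_tail_enum <- function(k, na, nb, N) {
  ks <- max(0, na + nb - N):min(na, nb)
  mass <- vapply(ks, function(x)
    choose(na, x) * choose(N - na, nb - x) / choose(N, nb), numeric(1))
  sum(mass[ks >= k])
}

# lag-1 cross-correlation of per-frame displacement between two bees,
# computed directly from a trajectory table (independent of the package's
# influence machinery)
lag1_displacement_cor <- function(traj, lead, follow) {
  tl <- traj[traj$bee_id == lead, ]
  tf <- traj[traj$bee_id == follow, ]
  frames <- intersect(tl$frame, tf$frame)
  dl <- diff(tl$x_mm[match(frames, tl$frame)])
  df_ <- diff(tf$x_mm[match(frames, tf$frame)])
  stats::cor(dl[-length(dl)], df_[-1])
}
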
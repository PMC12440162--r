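#' Parameters for the synthetic colony generator
#'
#' Bundles the conditions under which a synthetic colony is simulated. The
#' defaults emulate the recording design the analysis assumes: positional
#' detections at 1 frame/s of individually identified bees on a single
#' observation frame, with detection dropout, stationary bouts, and injected
#' trophallaxis episodes.
#'
#' @param n_bees number of bees (>= 2).
#' @param n_frames recording length in frames.
#' @param fs frame rate, frames per second.
#' @param hive_width_mm,hive_height_mm hive bounds; origin at the upper-left
#'   corner, y increasing downward. Defaults approximate a single deep
#'   observation frame.
#' @param coupling data.frame with columns \code{leader}, \code{follower},
#'   \code{c}: directional movement-coupling coefficients (|c| < 1). The
#'   follower's velocity at frame t gains \code{c} times the leader's
#'   displacement at frame t-1, per axis.
#' @param dropout_prob per-frame probability that a detection is missing.
#' @param stationary_prob per-frame probability of entering a stationary bout
#'   (mean bout length 30 s); during a bout per-frame displacement and turn
#'   stay below the 4.9 mm / 60 degree stationarity thresholds.
#' @param trophallaxis_rate expected raw trophallaxis events per bee-hour.
#' @param encounter_rate expected paired proximal encounters per bee-hour.
#'   During an encounter two bees walk tightly around a common centre (as in
#'   natural following/antennation bouts), each displacing above the
#'   stationarity threshold every frame while staying within the proximity
#'   radius; this is what makes qualifying proximal-interaction windows
#'   exist at all, since independent walkers cannot stay within 20 mm for
#'   30 s while each moving at least 4.9 mm/s. Encounter phase and turning
#'   direction are randomized per encounter, so displacement series of
#'   uncoupled pairs remain uncorrelated on average.
#' @param phi velocity AR(1) coefficient of the movement model.
#' @param sigma_v innovation standard deviation of the velocity process
#'   (mm/frame, per axis).
#' @param cohesion attraction rate toward a bee's cluster anchor point
#'   (per frame). Bees on a comb aggregate rather than diffuse; this weak
#'   mean-reversion reproduces realistic pair-encounter rates while keeping
#'   the movement process linear.
#' @param cluster_sd_mm spread of the per-bee anchor points around the hive
#'   center.
#' @param seed integer seed; every generator in this package is deterministic
#'   given its seed.
#' @return a list of class \code{"colony_sim_params"}.
#' @export
colony_sim_params <- function(n_bees = 20L, n_frames = 7200L, fs = 1,
                              hive_width_mm = 430, hive_height_mm = 250,
                              coupling = NULL, dropout_prob = 0.02,
                              stationary_prob = 0.02, trophallaxis_rate = 1,
                              encounter_rate = 3, phi = 0.6, sigma_v = 4,
                              cohesion = 0.02, cluster_sd_mm = 30,
                              seed = 1L) {
  if (n_bees < 2) stop("n_bees must be >= 2")
  if (fs <= 0) stop("fs must be positive")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (hive_width_mm <= 0 || hive_height_mm <= 0) stop("non-positive hive dimensions")
  if (dropout_prob < 0 || dropout_prob >= 1) stop("dropout_prob must be in [0, 1)")
  if (stationary_prob < 0 || stationary_prob > 1) stop("invalid stationary_prob")
  if (!is.null(coupling)) {
    stopifnot(is.data.frame(coupling),
              all(c("leader", "follower", "c") %in% names(coupling)))
    if (any(abs(coupling$c) >= 1)) stop("all coupling coefficients must satisfy |c| < 1")
    bad <- setdiff(c(coupling$leader, coupling$follower), seq_len(n_bees))
    if (length(bad)) stop("coupling references unknown bee ids: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(n_bees = as.integer(n_bees), n_frames = as.integer(n_frames),
                 fs = fs, hive_width_mm = hive_width_mm,
                 hive_height_mm = hive_height_mm, coupling = coupling,
                 dropout_prob = dropout_prob, stationary_prob = stationary_prob,
                 trophallaxis_rate = trophallaxis_rate,
                 encounter_rate = encounter_rate, phi = phi,
                 sigma_v = sigma_v, cohesion = cohesion,
                 cluster_sd_mm = cluster_sd_mm, seed = as.integer(seed)),
            class = "colony_sim_params")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate trajectories of a coupled synthetic colony
#'
#' Each bee moves by a stable AR(1) process on per-frame velocity (per axis);
#' for a coupled ordered pair the follower's velocity at frame t adds
#' \code{c} times the leader's displacement at frame t-1, so positions of a
#' coupled pair are exactly a bivariate VAR. Positions reflect at the hive
#' walls. Stationary bouts produce sub-threshold jitter (< 4.9 mm, < 60
#' degrees per frame). Injected trophallaxis episodes hold both partners
#' stationary within the detector's pairing distance (<= 7.4 mm). Detections
#' are dropped independently per frame with \code{dropout_prob}.
#'
#' @param params a \code{\link{colony_sim_params}} object.
#' @return list with \code{trajectories} — data.frame \code{bee_id},
#'   \code{frame} (0-based), \code{x_mm}, \code{y_mm}, \code{orientation_deg},
#'   with attributes \code{fs} and \code{hive_bounds} — and \code{truth}: the
#'   coupling table, the injected raw trophallaxis event log
#'   (\code{bee_a}, \code{bee_b}, \code{start_frame}, \code{end_frame}),
#'   per-bee stationary-bout masks, and the parameters.
#' @export
simulate_trajectories <- function(params) {
  stopifnot(inherits(params, "colony_sim_params"))
  with_seed(params$seed, {
    nb <- params$n_bees; nf <- params$n_frames
    W <- params$hive_width_mm; H <- params$hive_height_mm
    phi <- params$phi; sv <- params$sigma_v

    # trophallaxis episodes: Poisson count over bee-hours, random pairs
    hours <- nf / params$fs / 3600
    n_ev <- stats::rpois(1, params$trophallaxis_rate * nb * hours)
    ev <- NULL
    if (n_ev > 0) {
      dur <- pmin(nf, pmax(3L, as.integer(round(stats::rexp(n_ev, 1 / 20) + 4))))
      start <- vapply(dur, function(d)
        sample.int(max(1L, nf - d), 1L) - 1L, integer(1))
      pair <- t(vapply(seq_len(n_ev), function(i) sort(sample.int(nb, 2L)),
                       integer(2)))
      ev <- data.frame(bee_a = pair[, 1], bee_b = pair[, 2],
                       start_frame = start, end_frame = start + dur - 1L)
    }

    # stationary bouts: two-state Markov chain per bee
    stay <- 1 - 1 / (30 * params$fs)   # mean bout length 30 s
    stationary <- matrix(FALSE, nf, nb)
    for (b in seq_len(nb)) {
      s <- FALSE
      u <- stats::runif(nf)
      for (t in seq_len(nf)) {
        s <- if (s) u[t] < stay else u[t] < params$stationary_prob
        stationary[t, b] <- s
      }
    }
    # trophallaxis frames force both partners stationary
    troph_mask <- matrix(FALSE, nf, nb)
    if (!is.null(ev)) for (i in seq_len(nrow(ev))) {
      fr <- (ev$start_frame[i]:ev$end_frame[i]) + 1L
      troph_mask[fr, ev$bee_a[i]] <- TRUE
      troph_mask[fr, ev$bee_b[i]] <- TRUE
    }
    still <- stationary | troph_mask

    cpl <- params$coupling
    kap <- params$cohesion
    ax <- pmin(0.9 * W, pmax(0.1 * W,
               stats::rnorm(nb, W / 2, params$cluster_sd_mm)))
    ay <- pmin(0.9 * H, pmax(0.1 * H,
               stats::rnorm(nb, H / 2, params$cluster_sd_mm)))
    X <- matrix(0, nf, nb); Y <- matrix(0, nf, nb); O <- matrix(0, nf, nb)
    X[1, ] <- ax + stats::rnorm(nb, 0, 10)
    Y[1, ] <- ay + stats::rnorm(nb, 0, 10)
    O[1, ] <- stats::runif(nb, 0, 360)
    vx <- stats::rnorm(nb, 0, sv); vy <- stats::rnorm(nb, 0, sv)
    ex <- matrix(stats::rnorm(nf * nb, 0, sv), nf, nb)
    ey <- matrix(stats::rnorm(nf * nb, 0, sv), nf, nb)
    jx <- matrix(stats::rnorm(nf * nb, 0, 0.3), nf, nb)
    jy <- matrix(stats::rnorm(nf * nb, 0, 0.3), nf, nb)
    turn <- matrix(stats::rnorm(nf * nb, 0, 25), nf, nb)
    jturn <- matrix(stats::rnorm(nf * nb, 0, 3), nf, nb)

    reflect <- function(z, lim) {
      z <- abs(z)
      z <- lim - abs(lim - z %% (2 * lim))
      z
    }

    for (t in 2L:nf) {
      dxl <- X[t - 1L, ] - (if (t > 2L) X[t - 2L, ] else X[t - 1L, ])
      dyl <- Y[t - 1L, ] - (if (t > 2L) Y[t - 2L, ] else Y[t - 1L, ])
      vx <- phi * vx + kap * (ax - X[t - 1L, ]) + ex[t, ]
      vy <- phi * vy + kap * (ay - Y[t - 1L, ]) + ey[t, ]
      if (!is.null(cpl)) for (i in seq_len(nrow(cpl))) {
        f <- cpl$follower[i]; l <- cpl$leader[i]
        vx[f] <- vx[f] + cpl$c[i] * dxl[l]
        vy[f] <- vy[f] + cpl$c[i] * dyl[l]
      }
      mv <- !still[t, ]
      X[t, ] <- ifelse(mv, X[t - 1L, ] + vx, X[t - 1L, ] + jx[t, ])
      Y[t, ] <- ifelse(mv, Y[t - 1L, ] + vy, Y[t - 1L, ] + jy[t, ])
      O[t, ] <- (O[t - 1L, ] + ifelse(mv, turn[t, ], jturn[t, ])) %% 360
      vx[!mv] <- 0; vy[!mv] <- 0     # bouts reset the velocity state
      X[t, ] <- reflect(X[t, ], W)
      Y[t, ] <- reflect(Y[t, ], H)
    }

    # paired proximal encounters: both bees walk a tight orbit around a
    # common drifting centre, displacing >= threshold every frame while
    # staying within the proximity radius; phase and turning direction are
    # random per encounter
    busy <- troph_mask
    n_pe <- stats::rpois(1, params$encounter_rate * nb * hours / 2)
    enc <- NULL
    if (n_pe > 0) {
      queue <- sample.int(nb)
      qpos <- 1L
      next_pair <- function() {
        if (qpos + 1L > length(queue)) { queue <<- sample.int(nb); qpos <<- 1L }
        pr <- queue[qpos + 0:1]; qpos <<- qpos + 2L
        pr
      }
      for (i in seq_len(n_pe)) {
        pr <- next_pair()
        dur <- sample(45:90, 1L)
        placed <- FALSE
        for (try in 1:20) {
          s0 <- sample.int(max(1L, nf - dur - 1L), 1L)
          fr <- s0:(s0 + dur - 1L)
          if (!any(busy[fr, pr])) { placed <- TRUE; break }
        }
        if (!placed) next
        busy[fr, pr] <- TRUE
        cx0 <- X[s0, pr[1]]; cy0 <- Y[s0, pr[1]]
        cx <- cx0 + cumsum(stats::rnorm(dur, 0, 0.8))
        cy <- cy0 + cumsum(stats::rnorm(dur, 0, 0.8))
        for (wi in 1:2) {
          b <- pr[wi]
          r <- stats::runif(1, 5, 8)
          d_star <- stats::runif(1, 5.5, min(8, 2 * r * 0.95))
          om <- 2 * asin(d_star / (2 * r)) * sample(c(-1, 1), 1)
          th <- stats::runif(1, 0, 2 * pi) + om * (seq_len(dur) - 1L)
          X[fr, b] <- reflect(cx + r * cos(th), W)
          Y[fr, b] <- reflect(cy + r * sin(th), H)
          O[fr, b] <- (th * 180 / pi + 90 * sign(om)) %% 360
        }
        enc <- rbind(enc, data.frame(bee_a = min(pr), bee_b = max(pr),
                                     start_frame = s0 - 1L,
                                     end_frame = s0 + dur - 2L))
      }
    }

    # pin trophallaxis partners together (within 7.4 mm) for each episode
    if (!is.null(ev)) for (i in seq_len(nrow(ev))) {
      fr <- (ev$start_frame[i]:ev$end_frame[i]) + 1L
      a <- ev$bee_a[i]; b <- ev$bee_b[i]
      ang <- stats::runif(1, 0, 2 * pi)
      X[fr, b] <- reflect(X[fr, a] + 4 * cos(ang) + jx[fr, b], W)
      Y[fr, b] <- reflect(Y[fr, a] + 4 * sin(ang) + jy[fr, b], H)
    }

    keep <- matrix(stats::runif(nf * nb) >= params$dropout_prob, nf, nb)
    traj <- data.frame(
      bee_id = rep(seq_len(nb), each = nf),
      frame = rep(0:(nf - 1L), nb),
      x_mm = as.vector(X), y_mm = as.vector(Y),
      orientation_deg = as.vector(O))
    traj <- traj[as.vector(keep), , drop = FALSE]
    traj <- traj[order(traj$bee_id, traj$frame), , drop = FALSE]
    rownames(traj) <- NULL
    attr(traj, "fs") <- params$fs
    attr(traj, "hive_bounds") <- c(width_mm = W, height_mm = H)
    list(trajectories = traj,
         truth = list(coupling = cpl, trophallaxis_events = ev,
                      encounters = enc, stationary = stationary,
                      params = params))
  })
}

#' Simulate an exact vector autoregressive process
#'
#' Draws \code{n} samples from \eqn{y_t = \sum_m A_m y_{t-m} + w_t},
#' \eqn{w_t \sim N(0, \Sigma)}, after a burn-in, rejecting unstable
#' coefficient sets (companion-matrix spectral radius >= 1).
#'
#' @param coefficients list of k-by-k coefficient matrices \eqn{A_1..A_p}.
#' @param innovation_cov k-by-k symmetric positive semi-definite covariance.
#' @param n number of samples returned.
#' @param seed integer seed.
#' @param burn_in samples discarded before recording.
#' @return n-by-k numeric matrix.
#' @export
simulate_var <- function(coefficients, innovation_cov, n, seed = 1L,
                         burn_in = 200L) {
  stopifnot(is.list(coefficients), length(coefficients) >= 1)
  k <- nrow(coefficients[[1]])
  p <- length(coefficients)
  for (A in coefficients) stopifnot(is.matrix(A), all(dim(A) == k))
  if (max(abs(innovation_cov - t(innovation_cov))) > 1e-10)
    stop("innovation_cov must be symmetric")
  if (companion_spectral_radius(coefficients) >= 1)
    stop("unstable VAR coefficients (companion spectral radius >= 1)")
  ee <- eigen(innovation_cov, symmetric = TRUE)
  if (min(ee$values) < -1e-10) stop("innovation_cov must be PSD")
  L <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), k)
  with_seed(seed, {
    total <- n + burn_in + p
    w <- matrix(stats::rnorm(total * k), total, k) %*% t(L)
    y <- matrix(0, total, k)
    for (t in (p + 1L):total) {
      acc <- w[t, ]
      for (m in seq_len(p)) acc <- acc + coefficients[[m]] %*% y[t - m, ]
      y[t, ] <- acc
    }
    y[(burn_in + p + 1L):total, , drop = FALSE]
  })
}

#' Spectral radius of the companion matrix of a VAR coefficient set
#'
#' @param coefficients list of k-by-k matrices.
#' @return largest eigenvalue modulus of the companion form; the process is
#'   stable iff this is < 1.
#' @export
companion_spectral_radius <- function(coefficients) {
  k <- nrow(coefficients[[1]])
  p <- length(coefficients)
  C <- matrix(0, k * p, k * p)
  C[seq_len(k), ] <- do.call(cbind, coefficients)
  if (p > 1) C[(k + 1):(k * p), seq_len(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Simulate a hive-entrance trip log
#'
#' Designated foragers receive trip patterns satisfying the forager rule
#' (total >= 6 trips, >= 2 days with >= 4 trips, >= 25\% of trips in
#' 10:00-15:00); all other bees receive a pattern violating at least one
#' clause, cycling through the four violation modes (too few trips, only one
#' heavy day, off-peak timing, no trips at all) so every clause is exercised.
#'
#' @param n_bees number of bees (ids 1..n_bees).
#' @param n_days number of recording days.
#' @param forager_ids bee ids that should satisfy the forager rule.
#' @param seed integer seed.
#' @param start_date first recording day.
#' @return list with \code{trips} — data.frame \code{bee_id}, \code{date},
#'   \code{time} ("HH:MM:SS") — and \code{truth}: per-bee logical
#'   \code{is_forager} plus, for non-foragers, which clause their pattern
#'   violates.
#' @export
simulate_trip_log <- function(n_bees, n_days, forager_ids = integer(0),
                              seed = 1L, start_date = as.Date("2017-08-20")) {
  stopifnot(all(forager_ids %in% seq_len(n_bees)))
  if (n_days == 0)
    return(list(trips = data.frame(bee_id = integer(0),
                                   date = as.Date(character(0)),
                                   time = character(0)),
                truth = data.frame(bee_id = seq_len(n_bees),
                                   is_forager = FALSE,
                                   violated = "no_trips")))
  with_seed(seed, {
    peak_time <- function(n) sprintf("%02d:%02d:%02d",
                                     sample(10:14, n, TRUE),
                                     sample(0:59, n, TRUE),
                                     sample(0:59, n, TRUE))
    off_time <- function(n) sprintf("%02d:%02d:%02d",
                                    sample(c(7:9, 15:18), n, TRUE),
                                    sample(0:59, n, TRUE),
                                    sample(0:59, n, TRUE))
    rows <- list()
    violated <- rep(NA_character_, n_bees)
    modes <- c("too_few_total", "one_heavy_day", "off_peak", "no_trips")
    nonf <- setdiff(seq_len(n_bees), forager_ids)
    for (b in seq_len(n_bees)) {
      if (b %in% forager_ids) {
        days <- if (n_days >= 2) sample.int(n_days, 2) else 1L
        for (d in days) {
          n_tr <- sample(4:7, 1)
          n_peak <- max(2L, ceiling(0.5 * n_tr))
          tms <- c(peak_time(n_peak), off_time(n_tr - n_peak))
          rows[[length(rows) + 1L]] <- data.frame(
            bee_id = b, date = start_date + d - 1L, time = tms)
        }
      } else {
        mode <- modes[(match(b, nonf) - 1L) %% length(modes) + 1L]
        violated[b] <- mode
        if (mode == "too_few_total") {
          # two light days: per-day clause fails too few; total 4 < 6
          for (d in seq_len(min(2L, n_days)))
            rows[[length(rows) + 1L]] <- data.frame(
              bee_id = b, date = start_date + d - 1L, time = peak_time(2))
        } else if (mode == "one_heavy_day") {
          rows[[length(rows) + 1L]] <- data.frame(
            bee_id = b, date = start_date, time = peak_time(5))
          if (n_days >= 2)
            rows[[length(rows) + 1L]] <- data.frame(
              bee_id = b, date = start_date + 1L, time = peak_time(1))
        } else if (mode == "off_peak") {
          for (d in seq_len(min(2L, n_days)))
            rows[[length(rows) + 1L]] <- data.frame(
              bee_id = b, date = start_date + d - 1L, time = off_time(4))
        } # no_trips: emit nothing
      }
    }
    trips <- if (length(rows)) do.call(rbind, rows) else
      data.frame(bee_id = integer(0), date = as.Date(character(0)),
                 time = character(0))
    rownames(trips) <- NULL
    list(trips = trips,
         truth = data.frame(bee_id = seq_len(n_bees),
                            is_forager = seq_len(n_bees) %in% forager_ids,
                            violated = violated))
  })
}

behavior_labels <- c("generalist", "forager", "nurse", "guard",
                     "non_responder", "baseline")

#' Simulate laboratory assay observations consistent with target labels
#'
#' Produces intruder (aggression) and larva (care) dish-assay observation
#' rows whose durations satisfy the classification rule for each bee's
#' assigned label: guards get >= 20 s of biting/stinging, nurses >= 20 s of
#' larval feeding, non-responders 0 s everywhere, baselines sub-threshold
#' responsiveness plus a fanning/wax/vibration record, and generalists two
#' qualifying behaviors. For the labels \code{forager} and (optionally)
#' \code{generalist}, trip-log evidence must be supplied separately (see
#' \code{\link{simulate_behavior_inputs}}); here \code{generalist} bees get
#' both assay behaviors above threshold so the label is assay-derivable.
#'
#' @param labels character vector of labels, one per bee (bee ids 1..n).
#' @param seed integer seed.
#' @return data.frame \code{bee_id}, \code{assay} (intruder/larva),
#'   \code{behavior} (bite, sting, feed, inspect, fan, wax, vibrate),
#'   \code{total_duration_s}.
#' @export
simulate_assay <- function(labels, seed = 1L) {
  bad <- setdiff(labels, behavior_labels)
  if (length(bad)) stop("unknown label(s): ", paste(unique(bad), collapse = ", "))
  with_seed(seed, {
    rows <- list()
    add <- function(b, assay, behavior, dur)
      rows[[length(rows) + 1L]] <<- data.frame(
        bee_id = b, assay = assay, behavior = behavior, total_duration_s = dur)
    for (b in seq_along(labels)) {
      lab <- labels[b]
      agg <- 0; care <- 0
      if (lab == "guard") agg <- stats::runif(1, 22, 60)
      if (lab == "nurse") care <- stats::runif(1, 22, 60)
      if (lab == "generalist") { agg <- stats::runif(1, 22, 60)
                                 care <- stats::runif(1, 22, 60) }
      if (lab == "baseline") {
        if (stats::runif(1) < 0.5) agg <- stats::runif(1, 2, 15)
        else care <- stats::runif(1, 2, 15)
        add(b, "intruder", sample(c("fan", "wax", "vibrate"), 1),
            stats::runif(1, 5, 30))
      }
      if (lab == "forager" && stats::runif(1) < 0.3)
        care <- stats::runif(1, 1, 10)      # mild responsiveness allowed
      if (agg > 0) {
        bite <- stats::runif(1, 0.3, 0.7) * agg
        add(b, "intruder", "bite", bite)
        add(b, "intruder", "sting", agg - bite)
      } else add(b, "intruder", "bite", 0)
      if (care > 0) {
        feed <- stats::runif(1, 0.6, 0.9) * care
        add(b, "larva", "feed", feed)
        add(b, "larva", "inspect", care - feed)
      } else add(b, "larva", "feed", 0)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate coordinated behavioral-state inputs (trips + assays)
#'
#' Builds a trip log and assay table jointly consistent with a ground-truth
#' label per bee: \code{forager} bees (and generalists whose second behavior
#' is foraging) satisfy the trip rule; assay durations follow
#' \code{\link{simulate_assay}}.
#'
#' @param labels character vector of target labels (bee ids 1..n).
#' @param n_days trip-log length in days.
#' @param seed integer seed.
#' @return list \code{trips}, \code{assays}, \code{truth} (data.frame
#'   \code{bee_id}, \code{label}).
#' @export
simulate_behavior_inputs <- function(labels, n_days = 7L, seed = 1L) {
  forager_ids <- which(labels == "forager")
  tl <- simulate_trip_log(length(labels), n_days, forager_ids, seed = seed)
  assays <- simulate_assay(labels, seed = seed + 1L)
  list(trips = tl$trips, assays = assays,
       truth = data.frame(bee_id = seq_along(labels), label = labels))
}

#' Simulate biallelic SNP dosages and ground-truth polygenic scores
#'
#' Dosages are drawn per SNP as Binomial(2, MAF) with MAF uniform in
#' \code{maf_range}. The ground-truth polygenic score is computed by an
#' explicit double loop over bees and SNPs, independent of the package's
#' matrix-product implementation, so the two can be cross-checked.
#'
#' @param n_bees,n_snps matrix dimensions.
#' @param effect_sizes numeric vector of per-SNP effect sizes (length
#'   \code{n_snps}).
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param seed integer seed.
#' @return list: \code{dosages} (bees-by-SNPs integer matrix, dimnames set),
#'   \code{effects} (data.frame \code{snp_id}, \code{beta}),
#'   \code{true_prs} (per-bee score from the loop oracle).
#' @export
simulate_genotypes <- function(n_bees, n_snps, effect_sizes,
                               maf_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(length(effect_sizes) == n_snps,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  with_seed(seed, {
    maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
    d <- vapply(seq_len(n_snps),
                function(s) stats::rbinom(n_bees, 2L, maf[s]),
                integer(n_bees))
    if (n_bees == 1) d <- matrix(d, nrow = 1)
    dimnames(d) <- list(paste0("bee_", seq_len(n_bees)),
                        paste0("snp_", seq_len(n_snps)))
    prs <- numeric(n_bees)
    for (b in seq_len(n_bees)) {
      acc <- 0
      for (s in seq_len(n_snps)) acc <- acc + d[b, s] * effect_sizes[s]
      prs[b] <- acc
    }
    names(prs) <- rownames(d)
    list(dosages = d,
         effects = data.frame(snp_id = colnames(d), beta = effect_sizes),
         true_prs = prs)
  })
}
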
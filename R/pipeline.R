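#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis in one place. Defaults
#' are the study's printed values: 1 frame/s; 4.9 mm / 60 degree
#' stationarity; trophallaxis merge gap < 60 s, duration in [3 s, 180 s];
#' proximity radius 20 mm for >= 30 frames; forager rule 6 trips / 4 per
#' day on 2 days / 25\% in 10:00-15:00; 20 s assay threshold.
#'
#' @param fs frames per second.
#' @param hive_width_mm,hive_height_mm hive bounds (origin upper-left, y
#'   downward).
#' @param kinematics \code{\link{kinematic_thresholds}} list.
#' @param troph_max_gap_s,troph_min_s,troph_max_s trophallaxis merge and
#'   duration-filter constants (seconds).
#' @param proximity \code{\link{proximity_params}} list.
#' @param forager list of forager-rule constants (\code{peak_start},
#'   \code{peak_end}, \code{min_total}, \code{min_per_day}, \code{min_days},
#'   \code{min_peak_fraction}).
#' @param assay_min_s qualifying assay duration (seconds).
#' @param window analysis frame window \code{c(first, last)}, or NULL for
#'   the last 2 days of the recording (clamped to the recording length).
#' @param influence \code{\link{influence_settings}} list.
#' @param seed integer seed for any simulation the pipeline performs.
#' @param output_dir optional directory for CSV outputs and the run
#'   manifest.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(fs = 1, hive_width_mm = 430, hive_height_mm = 250,
                            kinematics = kinematic_thresholds(),
                            troph_max_gap_s = 60, troph_min_s = 3,
                            troph_max_s = 180,
                            proximity = proximity_params(),
                            forager = list(peak_start = "10:00",
                                           peak_end = "15:00", min_total = 6L,
                                           min_per_day = 4L, min_days = 2L,
                                           min_peak_fraction = 0.25),
                            assay_min_s = 20,
                            window = NULL,
                            influence = influence_settings(),
                            seed = 1L, output_dir = NULL) {
  stopifnot(fs > 0, troph_max_gap_s > 0, troph_min_s > 0,
            troph_max_s > troph_min_s, assay_min_s > 0)
  structure(list(fs = fs, hive_width_mm = hive_width_mm,
                 hive_height_mm = hive_height_mm, kinematics = kinematics,
                 troph_max_gap_s = troph_max_gap_s, troph_min_s = troph_min_s,
                 troph_max_s = troph_max_s, proximity = proximity,
                 forager = forager, assay_min_s = assay_min_s,
                 window = window, influence = influence, seed = seed,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys present in the file override the built-in defaults of
#' \code{\link{pipeline_config}}; nested sections (\code{kinematics},
#' \code{proximity}, \code{forager}, \code{influence}) override field-wise.
#'
#' @param path YAML file path.
#' @return a \code{"pipeline_config"} object.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (key in names(raw)) {
    if (!key %in% names(cfg)) stop("unknown configuration key: ", key)
    if (key %in% c("kinematics", "proximity", "forager", "influence")) {
      for (sub in names(raw[[key]])) {
        if (!sub %in% names(cfg[[key]]))
          stop("unknown configuration key: ", key, "$", sub)
        cfg[[key]][[sub]] <- raw[[key]][[sub]]
      }
    } else {
      cfg[[key]] <- raw[[key]]
    }
  }
  cfg
}

#' Validate input tables against the pipeline schemas
#'
#' Checks column presence, key uniqueness, coordinate bounds, orientation
#' range and interval sanity. Returns a report data.frame with one row per
#' problem (zero rows = valid).
#'
#' @param tables named list with any of \code{trajectories},
#'   \code{raw_trophallaxis}, \code{trips}, \code{assays}; elements may be
#'   data.frames or CSV paths.
#' @param config a \code{\link{pipeline_config}} (for hive bounds).
#' @return data.frame \code{table}, \code{row}, \code{problem}.
#' @export
validate_tables <- function(tables, config = pipeline_config()) {
  probs <- list()
  note <- function(tab, row, msg)
    probs[[length(probs) + 1L]] <<- data.frame(table = tab, row = row,
                                               problem = msg)
  load_tab <- function(x, tab) {
    if (is.character(x)) {
      if (!file.exists(x)) stop("unreadable file: ", x)
      utils::read.csv(x)
    } else x
  }
  need <- function(df, tab, cols) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      note(tab, NA_integer_, paste("missing columns:",
                                   paste(miss, collapse = ", ")))
      FALSE
    } else TRUE
  }
  if (!is.null(tables$trajectories)) {
    df <- load_tab(tables$trajectories, "trajectories")
    if (need(df, "trajectories",
             c("bee_id", "frame", "x_mm", "y_mm", "orientation_deg"))) {
      dup <- which(duplicated(df[c("bee_id", "frame")]))
      for (r in dup) note("trajectories", r, "duplicate (bee_id, frame) key")
      oob <- which(df$x_mm < 0 | df$x_mm > config$hive_width_mm |
                   df$y_mm < 0 | df$y_mm > config$hive_height_mm)
      for (r in utils::head(oob, 50))
        note("trajectories", r, "coordinates outside hive bounds")
      bad_o <- which(df$orientation_deg < 0 | df$orientation_deg >= 360)
      for (r in utils::head(bad_o, 50))
        note("trajectories", r, "orientation outside [0, 360)")
      if (any(df$frame != as.integer(df$frame)))
        note("trajectories", NA_integer_, "non-integer frame indices")
    }
  }
  if (!is.null(tables$raw_trophallaxis)) {
    df <- load_tab(tables$raw_trophallaxis, "raw_trophallaxis")
    if (need(df, "raw_trophallaxis",
             c("bee_a", "bee_b", "start_frame", "end_frame"))) {
      for (r in which(df$start_frame > df$end_frame))
        note("raw_trophallaxis", r, "start_frame > end_frame")
      for (r in which(df$bee_a == df$bee_b))
        note("raw_trophallaxis", r, "event pairs a bee with itself")
    }
  }
  if (!is.null(tables$trips)) {
    df <- load_tab(tables$trips, "trips")
    if (need(df, "trips", c("bee_id", "date", "time"))) {
      bad_t <- which(!grepl("^([01][0-9]|2[0-3]):[0-5][0-9](:[0-5][0-9])?$",
                            df$time))
      for (r in utils::head(bad_t, 50)) note("trips", r, "invalid clock time")
    }
  }
  if (!is.null(tables$assays)) {
    df <- load_tab(tables$assays, "assays")
    if (need(df, "assays",
             c("bee_id", "assay", "behavior", "total_duration_s"))) {
      for (r in which(df$total_duration_s < 0))
        note("assays", r, "negative duration")
    }
  }
  if (!length(probs))
    return(data.frame(table = character(0), row = integer(0),
                      problem = character(0)))
  out <- do.call(rbind, probs)
  rownames(out) <- NULL
  out
}

#' Run the full sociability analysis pipeline
#'
#' Executes kinematics, trophallaxis processing, proximity extraction,
#' social-influence estimation, behavioral-state classification and (when
#' genotypes are supplied) polygenic scoring, and joins everything into one
#' per-bee table. Deterministic given (inputs, config): the analysis stages
#' contain no randomness.
#'
#' @param inputs named list: \code{trajectories} (required),
#'   \code{raw_trophallaxis} (required), \code{trips} (optional),
#'   \code{assays} (optional), \code{dosages} + \code{effects} (optional).
#' @param config a \code{\link{pipeline_config}}.
#' @return list of class \code{"pipeline_result"}: \code{per_bee} (joined
#'   table), \code{events}, \code{speeds}, \code{interactions},
#'   \code{influence}, \code{labels}, \code{manifest} (stage row counts,
#'   config hash, analysis window).
#' @export
run_pipeline <- function(inputs, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(inputs$trajectories) || is.null(inputs$raw_trophallaxis))
    stop("inputs must include trajectories and raw_trophallaxis")
  rep_ <- validate_tables(inputs[c("trajectories", "raw_trophallaxis",
                                   "trips", "assays")], config)
  if (nrow(rep_))
    stop("input validation failed:\n",
         paste(utils::capture.output(print(rep_)), collapse = "\n"))
  traj <- inputs$trajectories
  if (is.null(attr(traj, "fs"))) attr(traj, "fs") <- config$fs
  fs <- config$fs
  bees <- sort(unique(traj$bee_id))

  speeds <- instantaneous_speeds(traj, config$kinematics, fs = fs)
  merged <- merge_raw_events(inputs$raw_trophallaxis, fs = fs,
                             max_gap_s = config$troph_max_gap_s)
  events <- filter_events(merged, fs = fs, min_s = config$troph_min_s,
                          max_s = config$troph_max_s)

  window <- config$window
  if (is.null(window)) {
    f1 <- max(traj$frame)
    window <- c(max(min(traj$frame), f1 - 2 * 86400 * fs + 1), f1)
  }
  soc <- trophallaxis_frequency(events, window, fs = fs, bee_ids = bees)
  spd <- mean_speeds(speeds, window = window, bee_ids = bees)

  interactions <- find_proximity_interactions(traj, events, speeds,
                                              config$proximity)
  infl <- if (nrow(interactions))
    social_influence_all(traj, interactions, config$influence)
  else data.frame(bee_id = integer(0), i_flow_out = numeric(0),
                  i_flow_in = numeric(0), i_out_x = numeric(0),
                  i_out_y = numeric(0), i_in_x = numeric(0),
                  i_in_y = numeric(0), n_interactions = integer(0),
                  n_failed = integer(0))

  labels <- NULL
  if (!is.null(inputs$assays)) {
    ff <- if (!is.null(inputs$trips)) {
      do.call(classify_forager, c(list(trips = inputs$trips,
                                       bee_ids = bees), config$forager))
    } else {
      warning("no trip log supplied: labels restricted to assay-derivable ",
              "states (foragers cannot be identified)")
      NULL
    }
    labels <- classify_states(inputs$assays, ff,
                              aggression_min_s = config$assay_min_s,
                              care_min_s = config$assay_min_s,
                              bee_ids = bees)
  }

  prs <- NULL
  if (!is.null(inputs$dosages) && !is.null(inputs$effects))
    prs <- data.frame(bee_id = bees,
                      polygenic_score = unname(polygenic_score(inputs$dosages,
                                                               inputs$effects)))

  per_bee <- merge(soc, spd, by = "bee_id", all = TRUE)
  per_bee <- merge(per_bee,
                   infl[c("bee_id", "i_flow_out", "i_flow_in",
                          "n_interactions")],
                   by = "bee_id", all.x = TRUE)
  if (!is.null(labels))
    per_bee <- merge(per_bee, labels[c("bee_id", "label")],
                     by = "bee_id", all.x = TRUE)
  if (!is.null(prs)) per_bee <- merge(per_bee, prs, by = "bee_id", all.x = TRUE)
  per_bee <- per_bee[order(per_bee$bee_id), , drop = FALSE]
  rownames(per_bee) <- NULL

  # conservation identity re-checked at run time
  in_win <- events[events$start_frame >= window[1] &
                   events$start_frame <= window[2], , drop = FALSE]
  days <- (window[2] - window[1] + 1) / fs / 86400
  stopifnot(isTRUE(all.equal(sum(soc$trophallaxis_frequency) * days,
                             2 * nrow(in_win))))

  manifest <- list(
    config_hash = config_digest(config),
    seed = config$seed,
    window = window,
    rows = list(trajectories = nrow(traj), speeds = nrow(speeds),
                raw_events = nrow(inputs$raw_trophallaxis),
                merged_events = nrow(merged), filtered_events = nrow(events),
                interactions = nrow(interactions),
                influence = nrow(infl), per_bee = nrow(per_bee)))

  res <- structure(list(per_bee = per_bee, events = events, speeds = speeds,
                        interactions = interactions, influence = infl,
                        labels = labels, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_result(res, config$output_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result:", nrow(x$per_bee), "bees,",
      nrow(x$events), "trophallaxis events,",
      nrow(x$interactions), "proximal interactions\n")
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits \code{per_bee.csv}, \code{events.csv}, \code{interactions.csv},
#' \code{influence.csv}, \code{labels.csv} (when present) and a JSON run
#' manifest.
#'
#' @param result a \code{"pipeline_result"}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name),
                                           row.names = FALSE)
  w(result$per_bee, "per_bee.csv")
  w(result$events, "events.csv")
  w(result$interactions, "interactions.csv")
  w(result$influence, "influence.csv")
  if (!is.null(result$labels)) w(result$labels, "labels.csv")
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

config_digest <- function(config) {
  config$output_dir <- NULL   # paths are not part of the analysis identity
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  # small stable checksum without extra dependencies
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)) %% 2147483647
}

#' Generate the packaged synthetic colony fixture
#'
#' A 20-bee, 2-simulated-hour colony with a few known leader-follower
#' couplings, dropout, stationary bouts and injected trophallaxis episodes;
#' together with coordinated trip-log/assay inputs and genotypes, this is
#' the standard end-to-end test input.
#'
#' @param seed integer seed.
#' @param n_bees,n_frames colony size and recording length.
#' @return list: \code{inputs} (ready for \code{\link{run_pipeline}}),
#'   \code{truth} (generator ground truth).
#' @export
synthetic_fixture <- function(seed = 1L, n_bees = 20L, n_frames = 7200L) {
  coupling <- data.frame(leader = c(1L, 3L, 5L), follower = c(2L, 4L, 6L),
                         c = c(0.6, 0.4, 0.2))
  params <- colony_sim_params(n_bees = n_bees, n_frames = n_frames,
                              coupling = coupling, seed = seed)
  sim <- simulate_trajectories(params)
  labels <- rep(c("forager", "guard", "nurse", "generalist", "non_responder",
                  "baseline"), length.out = n_bees)
  beh <- simulate_behavior_inputs(labels, n_days = 7L, seed = seed + 1L)
  gen <- simulate_genotypes(n_bees, 50L,
                            effect_sizes = with_seed(seed + 2L,
                                                     stats::rnorm(50, 0, 0.3)),
                            seed = seed + 3L)
  raw <- sim$truth$trophallaxis_events
  if (is.null(raw))
    raw <- data.frame(bee_a = integer(0), bee_b = integer(0),
                      start_frame = integer(0), end_frame = integer(0))
  list(inputs = list(trajectories = sim$trajectories,
                     raw_trophallaxis = raw,
                     trips = beh$trips, assays = beh$assays,
                     dosages = gen$dosages, effects = gen$effects),
       truth = list(colony = sim$truth, labels = beh$truth,
                    prs = gen$true_prs))
}
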
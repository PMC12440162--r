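#' Parameters for proximal-interaction extraction
#'
#' @param R_max_mm maximum pair distance (default 2 cm, about twice a bee's
#'   body length).
#' @param L_min_frames minimum contiguous duration (default 30 frames, 30 s
#'   at 1 frame/s: enough samples to fit a VAR).
#' @param exclude_low_speed drop frames where either bee is stationary
#'   (its incoming kinematic pair was not recorded under the 4.9 mm / 60
#'   degree rule).
#' @param exclude_trophallaxis drop frames inside a filtered trophallaxis
#'   event of this pair (third-party trophallaxis does not exclude).
#' @param first_interaction_only keep only the earliest qualifying
#'   interaction per (focal, neighbor) pair.
#' @return a list of class \code{"proximity_params"}.
#' @export
proximity_params <- function(R_max_mm = 20, L_min_frames = 30L,
                             exclude_low_speed = TRUE,
                             exclude_trophallaxis = TRUE,
                             first_interaction_only = TRUE) {
  stopifnot(R_max_mm > 0, L_min_frames >= 2)
  structure(list(R_max_mm = R_max_mm, L_min_frames = as.integer(L_min_frames),
                 exclude_low_speed = exclude_low_speed,
                 exclude_trophallaxis = exclude_trophallaxis,
                 first_interaction_only = first_interaction_only),
            class = "proximity_params")
}

#' Find proximal interactions between bee pairs
#'
#' For each focal bee and each other bee, finds maximal runs of contiguous
#' frames where (i) both bees are detected, (ii) their Euclidean distance is
#' at most \code{R_max_mm}, (iii) neither bee is in a low-speed frame, and
#' (iv) the pair is not inside one of its filtered trophallaxis events.
#' Excluded frames break contiguity. Runs of at least \code{L_min_frames}
#' included frames become interactions; with
#' \code{first_interaction_only} only the earliest per (focal, neighbor)
#' pair is kept. Every bee serves as focal, so a physical encounter appears
#' once per focal perspective.
#'
#' @param traj trajectory table.
#' @param events filtered trophallaxis events (may have zero rows); required
#'   when \code{exclude_trophallaxis}.
#' @param speeds output of \code{\link{instantaneous_speeds}}; required when
#'   \code{exclude_low_speed} (error if missing).
#' @param params a \code{\link{proximity_params}} list.
#' @return data.frame \code{focal_id}, \code{neighbor_id},
#'   \code{start_frame}, \code{end_frame}, \code{length}.
#' @export
find_proximity_interactions <- function(traj, events = NULL, speeds = NULL,
                                        params = proximity_params()) {
  stopifnot(inherits(params, "proximity_params"))
  if (params$exclude_low_speed && is.null(speeds))
    stop("speeds table required to apply the low-speed exclusion")
  if (params$exclude_trophallaxis && is.null(events))
    stop("events table required to apply the trophallaxis exclusion")
  bees <- sort(unique(traj$bee_id))
  f0 <- min(traj$frame); f1 <- max(traj$frame)
  nf <- f1 - f0 + 1L
  col <- function(v, idx, frames) {
    m <- matrix(NA_real_, nf, length(bees))
    m[cbind(frames - f0 + 1L, idx)] <- v
    m
  }
  bi <- match(traj$bee_id, bees)
  X <- col(traj$x_mm, bi, traj$frame)
  Y <- col(traj$y_mm, bi, traj$frame)
  det <- !is.na(X)
  low <- matrix(FALSE, nf, length(bees))
  if (params$exclude_low_speed && nrow(speeds)) {
    ns <- speeds[!speeds$recorded, , drop = FALSE]
    if (nrow(ns)) {
      si <- match(ns$bee_id, bees)
      keep <- !is.na(si) & ns$frame >= f0 & ns$frame <= f1
      low[cbind(ns$frame[keep] - f0 + 1L, si[keep])] <- TRUE
    }
  }
  res <- list()
  for (ai in seq_along(bees)[-length(bees)]) for (bj in (ai + 1L):length(bees)) {
    ok <- det[, ai] & det[, bj] &
      (X[, ai] - X[, bj])^2 + (Y[, ai] - Y[, bj])^2 <= params$R_max_mm^2
    ok[is.na(ok)] <- FALSE
    if (params$exclude_low_speed) ok <- ok & !low[, ai] & !low[, bj]
    if (params$exclude_trophallaxis && nrow(events)) {
      pe <- events[events$bee_a == bees[ai] & events$bee_b == bees[bj], ,
                   drop = FALSE]
      for (r in seq_len(nrow(pe))) {
        lo <- max(pe$start_frame[r], f0); hi <- min(pe$end_frame[r], f1)
        if (lo <= hi) ok[(lo - f0 + 1L):(hi - f0 + 1L)] <- FALSE
      }
    }
    if (!any(ok)) next
    rl <- rle(ok)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    qual <- rl$values & rl$lengths >= params$L_min_frames
    if (!any(qual)) next
    runs <- data.frame(start_frame = starts[qual] + f0 - 1L,
                       end_frame = ends[qual] + f0 - 1L)
    if (params$first_interaction_only) runs <- runs[1, , drop = FALSE]
    for (r in seq_len(nrow(runs))) {
      res[[length(res) + 1L]] <- data.frame(
        focal_id = c(bees[ai], bees[bj]),
        neighbor_id = c(bees[bj], bees[ai]),
        start_frame = runs$start_frame[r], end_frame = runs$end_frame[r],
        length = runs$end_frame[r] - runs$start_frame[r] + 1L)
    }
  }
  if (!length(res))
    return(data.frame(focal_id = integer(0), neighbor_id = integer(0),
                      start_frame = integer(0), end_frame = integer(0),
                      length = integer(0)))
  out <- do.call(rbind, res)
  out <- out[order(out$focal_id, out$start_frame, out$neighbor_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Paired coordinate series for one proximal interaction
#'
#' Returns the focal and neighbor coordinates along one axis over the
#' interaction's frame interval, as the raw stored values (no detrending).
#'
#' @param traj trajectory table.
#' @param focal_id,neighbor_id the interacting pair.
#' @param start_frame,end_frame inclusive frame interval.
#' @param axis \code{"X"} or \code{"Y"}.
#' @return numeric matrix with columns \code{focal}, \code{neighbor}.
#' @export
build_bivariate_series <- function(traj, focal_id, neighbor_id,
                                   start_frame, end_frame, axis = c("X", "Y")) {
  axis <- match.arg(axis)
  cn <- if (axis == "X") "x_mm" else "y_mm"
  frames <- start_frame:end_frame
  pull <- function(id) {
    rows <- traj[traj$bee_id == id & traj$frame >= start_frame &
                 traj$frame <= end_frame, , drop = FALSE]
    v <- rows[[cn]][match(frames, rows$frame)]
    if (anyNA(v)) stop("bee ", id, " missing detections inside interaction ",
                       start_frame, "-", end_frame)
    v
  }
  cbind(focal = pull(focal_id), neighbor = pull(neighbor_id))
}
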
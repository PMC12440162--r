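#' Stationarity thresholds for kinematic recording
#'
#' A frame pair is treated as stationary (no speed measurement recorded) when
#' the bee moved less than one honeycomb-cell width (4.9 mm) AND turned less
#' than the angle from one cell corner to the next (60 degrees).
#'
#' @param min_displacement_mm displacement threshold, mm.
#' @param min_turn_deg turn threshold, degrees.
#' @return list with the two thresholds.
#' @export
kinematic_thresholds <- function(min_displacement_mm = 4.9, min_turn_deg = 60) {
  stopifnot(min_displacement_mm > 0, min_turn_deg > 0)
  list(min_displacement_mm = min_displacement_mm, min_turn_deg = min_turn_deg)
}

#' Instantaneous linear and angular speeds
#'
#' For each strictly consecutive detected frame pair (t, t+1) of a bee:
#' linear speed is the Euclidean displacement of the barcode center divided
#' by the inter-frame interval 1/fs; angular speed is the unsigned angle
#' between the orientation vectors at t and t+1 (wrapped to [0, 180]
#' degrees) divided by 1/fs. No record is produced for frame t+1 when the
#' bee was undetected at t. Pairs below both stationarity thresholds yield
#' \code{recorded = FALSE} and no speed values.
#'
#' @param traj trajectory table (\code{bee_id}, \code{frame}, \code{x_mm},
#'   \code{y_mm}, \code{orientation_deg}) with an \code{fs} attribute, or
#'   pass \code{fs} explicitly.
#' @param thresholds a \code{\link{kinematic_thresholds}} list.
#' @param fs frames per second; defaults to the table's attribute.
#' @return data.frame \code{bee_id}, \code{frame} (the later frame t+1),
#'   \code{linear_speed} (mm/s, NA when not recorded), \code{angular_speed}
#'   (deg/s, NA when not recorded), \code{recorded}.
#' @export
instantaneous_speeds <- function(traj, thresholds = kinematic_thresholds(),
                                 fs = attr(traj, "fs")) {
  if (is.null(fs)) stop("fs not supplied and not an attribute of traj")
  if (nrow(traj) == 0)
    return(data.frame(bee_id = integer(0), frame = integer(0),
                      linear_speed = numeric(0), angular_speed = numeric(0),
                      recorded = logical(0)))
  if (anyDuplicated(traj[c("bee_id", "frame")]))
    stop("duplicate (bee_id, frame) keys in trajectory table")
  traj <- traj[order(traj$bee_id, traj$frame), , drop = FALSE]
  same_bee <- traj$bee_id[-1] == traj$bee_id[-nrow(traj)]
  consec <- diff(traj$frame) == 1L & same_bee
  i2 <- which(consec) + 1L
  i1 <- i2 - 1L
  disp <- sqrt((traj$x_mm[i2] - traj$x_mm[i1])^2 +
               (traj$y_mm[i2] - traj$y_mm[i1])^2)
  dtheta <- abs(traj$orientation_deg[i2] - traj$orientation_deg[i1]) %% 360
  dtheta <- ifelse(dtheta > 180, 360 - dtheta, dtheta)
  recorded <- disp >= thresholds$min_displacement_mm |
              dtheta >= thresholds$min_turn_deg
  data.frame(bee_id = traj$bee_id[i2],
             frame = traj$frame[i2],
             linear_speed = ifelse(recorded, disp * fs, NA_real_),
             angular_speed = ifelse(recorded, dtheta * fs, NA_real_),
             recorded = recorded)
}

#' Mean per-bee speeds over a frame window
#'
#' Arithmetic mean of recorded instantaneous speeds per bee inside the
#' window. Bees without any recorded measurement in the window receive NA
#' (absent), never zero.
#'
#' @param speeds output of \code{\link{instantaneous_speeds}}.
#' @param window inclusive frame interval \code{c(first, last)}, or NULL for
#'   all frames.
#' @param bee_ids bees to report; defaults to those present in \code{speeds}.
#' @return data.frame \code{bee_id}, \code{mean_linear_speed},
#'   \code{mean_angular_speed}, \code{n_recorded}.
#' @export
mean_speeds <- function(speeds, window = NULL, bee_ids = NULL) {
  if (is.null(bee_ids)) bee_ids <- sort(unique(speeds$bee_id))
  s <- speeds[speeds$recorded, , drop = FALSE]
  if (!is.null(window))
    s <- s[s$frame >= window[1] & s$frame <= window[2], , drop = FALSE]
  out <- data.frame(bee_id = bee_ids, mean_linear_speed = NA_real_,
                    mean_angular_speed = NA_real_, n_recorded = 0L)
  if (nrow(s)) {
    lin <- tapply(s$linear_speed, s$bee_id, mean)
    ang <- tapply(s$angular_speed, s$bee_id, mean)
    cnt <- tapply(s$linear_speed, s$bee_id, length)
    m <- match(names(lin), as.character(bee_ids))
    ok <- !is.na(m)
    out$mean_linear_speed[m[ok]] <- lin[ok]
    out$mean_angular_speed[m[ok]] <- ang[ok]
    out$n_recorded[m[ok]] <- cnt[ok]
  }
  out
}
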
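#' Forager classification from an entrance trip log
#'
#' A bee is flagged a forager when its trip record satisfies all three
#' clauses: total trips >= \code{min_total}; at least \code{min_days}
#' distinct days each with more than three trips (i.e. >= \code{min_per_day});
#' and at least \code{min_peak_fraction} of ALL its trips started during the
#' peak foraging hours.
#'
#' @param trips data.frame \code{bee_id}, \code{date}, \code{time}
#'   ("HH:MM:SS" local clock).
#' @param peak_start,peak_end peak foraging window, "HH:MM" (trips with
#'   \code{peak_start <= time < peak_end} count as peak).
#' @param min_total minimum total trips (default 6).
#' @param min_per_day minimum trips for a day to count as heavy (default 4,
#'   the "more than three trips per day" clause).
#' @param min_days minimum number of heavy days (default 2).
#' @param min_peak_fraction minimum fraction of all trips in peak hours.
#' @param bee_ids bees to report; defaults to those in \code{trips}.
#' @return data.frame \code{bee_id}, \code{forager}, \code{n_trips},
#'   \code{n_heavy_days}, \code{peak_fraction}.
#' @export
classify_forager <- function(trips, peak_start = "10:00", peak_end = "15:00",
                             min_total = 6L, min_per_day = 4L, min_days = 2L,
                             min_peak_fraction = 0.25, bee_ids = NULL) {
  if (is.null(bee_ids)) bee_ids <- sort(unique(trips$bee_id))
  out <- data.frame(bee_id = bee_ids, forager = FALSE, n_trips = 0L,
                    n_heavy_days = 0L, peak_fraction = NA_real_)
  if (nrow(trips) == 0 || length(bee_ids) == 0) return(out)
  to_min <- function(hm) {
    p <- strsplit(hm, ":")[[1]]
    as.integer(p[1]) * 60L + as.integer(p[2])
  }
  tm <- vapply(strsplit(trips$time, ":"), function(p)
    as.integer(p[1]) * 60L + as.integer(p[2]), integer(1))
  in_peak <- tm >= to_min(peak_start) & tm < to_min(peak_end)
  for (i in seq_along(bee_ids)) {
    sel <- trips$bee_id == bee_ids[i]
    n <- sum(sel)
    if (n == 0) next
    per_day <- table(trips$date[sel])
    heavy <- sum(per_day >= min_per_day)
    pf <- sum(in_peak[sel]) / n
    out$n_trips[i] <- n
    out$n_heavy_days[i] <- heavy
    out$peak_fraction[i] <- pf
    out$forager[i] <- n >= min_total && heavy >= min_days &&
      pf >= min_peak_fraction
  }
  out
}

#' Behavioral-state classification from assays and forager flags
#'
#' Applies the rule set of the laboratory dish assays combined with the
#' entrance-monitor forager flag. Aggression is the summed duration of
#' biting and stinging in the intruder assay; care is the summed duration of
#' larval feeding and inspection in the larva assay; "other" behaviors are
#' fanning, wax-building and vibration signaling. With threshold \eqn{T}
#' (default 20 s, the permissive end of the 20-30 s criterion):
#' \itemize{
#'   \item \strong{generalist}: two or more of \{aggression >= T,
#'     care >= T, forager flag\};
#'   \item \strong{guard}: aggression >= T only;
#'   \item \strong{nurse}: care >= T only;
#'   \item \strong{forager}: forager flag only;
#'   \item \strong{non_responder}: zero response to both stimuli, no other
#'     behaviors, not a forager;
#'   \item \strong{baseline}: everything else — sub-threshold responsiveness
#'     (> 0 but < T) or other behaviors only.
#' }
#' The six labels are exhaustive and mutually exclusive.
#'
#' @param assays data.frame \code{bee_id}, \code{assay}, \code{behavior},
#'   \code{total_duration_s}.
#' @param forager_flags output of \code{\link{classify_forager}} (or a
#'   data.frame with \code{bee_id}, \code{forager}); bees absent from it are
#'   treated as non-foragers.
#' @param aggression_min_s,care_min_s qualifying thresholds (seconds).
#' @param bee_ids bees to label; defaults to the union of the two tables.
#'   Bees missing from the assay table get label NA with a diagnostic
#'   message.
#' @return data.frame \code{bee_id}, \code{label}, \code{aggression_s},
#'   \code{care_s}, \code{other_s}, \code{forager}.
#' @export
classify_states <- function(assays, forager_flags = NULL,
                            aggression_min_s = 20, care_min_s = 20,
                            bee_ids = NULL) {
  agg_beh <- c("bite", "sting")
  care_beh <- c("feed", "inspect")
  other_beh <- c("fan", "wax", "vibrate")
  if (is.null(bee_ids))
    bee_ids <- sort(unique(c(assays$bee_id,
                             if (!is.null(forager_flags)) forager_flags$bee_id)))
  sum_dur <- function(b, beh) sum(assays$total_duration_s[
    assays$bee_id == b & assays$behavior %in% beh])
  fl <- rep(FALSE, length(bee_ids))
  if (!is.null(forager_flags)) {
    m <- match(bee_ids, forager_flags$bee_id)
    fl[!is.na(m)] <- forager_flags$forager[m[!is.na(m)]]
  }
  out <- data.frame(bee_id = bee_ids, label = NA_character_,
                    aggression_s = NA_real_, care_s = NA_real_,
                    other_s = NA_real_, forager = fl)
  for (i in seq_along(bee_ids)) {
    b <- bee_ids[i]
    if (!b %in% assays$bee_id) {
      message("bee ", b, " missing from assay table: left unlabeled")
      next
    }
    agg <- sum_dur(b, agg_beh)
    care <- sum_dur(b, care_beh)
    other <- sum_dur(b, other_beh)
    qualifying <- (agg >= aggression_min_s) + (care >= care_min_s) + fl[i]
    label <- if (qualifying >= 2) "generalist"
      else if (agg >= aggression_min_s) "guard"
      else if (care >= care_min_s) "nurse"
      else if (fl[i]) "forager"
      else if (agg == 0 && care == 0 && other == 0) "non_responder"
      else "baseline"
    out$label[i] <- label
    out$aggression_s[i] <- agg
    out$care_s[i] <- care
    out$other_s[i] <- other
  }
  out
}
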
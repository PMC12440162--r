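#' Merge raw trophallaxis events
#'
#' Raw detector events for the same unordered bee pair are unioned
#' transitively whenever the gap between one event's end and the next
#' event's start is less than \code{max_gap_s} seconds (60 s = "< 1 min
#' apart"). Overlapping events are unioned as a gap of zero. Merging is per
#' pair: events of different pairs never merge.
#'
#' @param raw data.frame \code{bee_a}, \code{bee_b}, \code{start_frame},
#'   \code{end_frame} (inclusive frame intervals; the two ids must differ).
#' @param fs frames per second, for the frame-to-second conversion.
#' @param max_gap_s merge window in seconds.
#' @return data.frame of merged events, pair ids in canonical (sorted)
#'   order, sorted by pair then start frame.
#' @export
merge_raw_events <- function(raw, fs = 1, max_gap_s = 60) {
  cols <- c("bee_a", "bee_b", "start_frame", "end_frame")
  if (nrow(raw) == 0)
    return(data.frame(bee_a = integer(0), bee_b = integer(0),
                      start_frame = integer(0), end_frame = integer(0)))
  stopifnot(all(cols %in% names(raw)), fs > 0)
  if (any(raw$start_frame > raw$end_frame)) stop("event with start > end")
  if (any(raw$bee_a == raw$bee_b)) stop("event pairing a bee with itself")
  a <- pmin(raw$bee_a, raw$bee_b)
  b <- pmax(raw$bee_a, raw$bee_b)
  key <- paste(a, b, sep = "|")
  out <- lapply(split(seq_len(nrow(raw)), key), function(idx) {
    s <- raw$start_frame[idx]; e <- raw$end_frame[idx]
    o <- order(s, e)
    s <- s[o]; e <- e[o]
    ms <- s[1]; me <- e[1]
    res_s <- integer(0); res_e <- integer(0)
    for (i in seq_along(s)[-1]) {
      gap_s <- (s[i] - me) / fs
      if (gap_s < max_gap_s) {
        me <- max(me, e[i])
      } else {
        res_s <- c(res_s, ms); res_e <- c(res_e, me)
        ms <- s[i]; me <- e[i]
      }
    }
    res_s <- c(res_s, ms); res_e <- c(res_e, me)
    data.frame(bee_a = a[idx[1]], bee_b = b[idx[1]],
               start_frame = res_s, end_frame = res_e)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$bee_a, out$bee_b, out$start_frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Duration-filter merged trophallaxis events
#'
#' Keeps merged events lasting at least \code{min_s} seconds (shorter
#' contacts may involve no liquid transfer) and at most \code{max_s} seconds
#' (longer detections are spurious). Duration is the inclusive frame span
#' over fs: a single-frame event at fs = 1 lasts 1 s. Both bounds are
#' inclusive: an event of exactly \code{min_s} is kept.
#'
#' @param merged output of \code{\link{merge_raw_events}}.
#' @param fs frames per second.
#' @param min_s,max_s duration bounds in seconds (defaults 3 s and 180 s).
#' @return data.frame of events with an added \code{duration_s} column.
#' @export
filter_events <- function(merged, fs = 1, min_s = 3, max_s = 180) {
  if (nrow(merged) == 0)
    return(cbind(merged, duration_s = numeric(0)))
  dur <- (merged$end_frame - merged$start_frame + 1) / fs
  out <- merged[dur >= min_s & dur <= max_s, , drop = FALSE]
  out$duration_s <- dur[dur >= min_s & dur <= max_s]
  rownames(out) <- NULL
  out
}

#' Per-bee trophallaxis frequency (sociability score)
#'
#' Counts filtered events whose start frame falls inside the analysis window
#' (events straddling the boundary are assigned by start), crediting both
#' partners, and divides by the window length in days. This is the per-bee
#' sociability proxy: mean trophallaxis events per day.
#'
#' @param events filtered events (\code{\link{filter_events}}).
#' @param window inclusive frame interval \code{c(first, last)}.
#' @param fs frames per second.
#' @param bee_ids bees to report (so uninvolved bees get frequency 0);
#'   defaults to bees appearing in \code{events}.
#' @return data.frame \code{bee_id}, \code{n_events},
#'   \code{trophallaxis_frequency} (events/day).
#' @export
trophallaxis_frequency <- function(events, window, fs = 1, bee_ids = NULL) {
  stopifnot(length(window) == 2, window[2] >= window[1], fs > 0)
  days <- (window[2] - window[1] + 1) / fs / 86400
  ev <- events[events$start_frame >= window[1] &
               events$start_frame <= window[2], , drop = FALSE]
  if (is.null(bee_ids))
    bee_ids <- sort(unique(c(events$bee_a, events$bee_b)))
  cnt <- table(factor(c(ev$bee_a, ev$bee_b), levels = bee_ids))
  data.frame(bee_id = bee_ids,
             n_events = as.integer(cnt),
             trophallaxis_frequency = as.numeric(cnt) / days)
}
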
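# Reentry detection, rotation counting, vulnerable-window bookkeeping.

#' Detect reentry in an event stream
#'
#' Reentry is identified when a point in either medium is re-activated after
#' the final stimulus: with the S2-evoked (or last paced) beat counting as
#' the first activation, "at least two full rotations" requires some node to
#' reach three or more ascending crossings after `finalStimTime`. Rotations
#' are the maximum per-node activation count minus one. Duration runs from
#' the final stimulus to the last event (either direction); termination is
#' declared when a quiescent gap of at least `quiesceGap` precedes the
#' observation end.
#'
#' @param events Event `data.frame(medium, node, time, dir)` (a
#'   [SimulationTrace-class]'s `events`).
#' @param finalStimTime Time (ms) of the final stimulus onset.
#' @param observeEnd End (ms) of the observation window.
#' @param quiesceGap Gap (ms) defining self-termination; the drivers use
#'   1.25 x the longest calibrated APD.
#' @return A [ReentryReport-class].
#' @export
detectReentry <- function(events, finalStimTime, observeEnd,
                          quiesceGap = 250) {
  ev <- events[events$time > finalStimTime & events$time <= observeEnd, , drop = FALSE]
  up <- ev[ev$dir == 1L, , drop = FALSE]
  if (!nrow(up))
    return(new("ReentryReport", induced = FALSE, rotations = 0L,
               durationS = 0, terminated = TRUE))
  counts <- table(paste(up$medium, up$node))
  rotations <- as.integer(max(counts) - 1L)
  lastEvent <- max(ev$time)
  terminated <- (observeEnd - lastEvent) >= quiesceGap
  duration <- (if (terminated) lastEvent else observeEnd) - finalStimTime
  new("ReentryReport", induced = rotations >= 2L, rotations = rotations,
      durationS = max(0, duration) / 1000, terminated = terminated)
}

#' Vulnerable window from S1S2 scan classifications
#'
#' The first (largest) and last (smallest) S2 coupling intervals that
#' generated reentry. Non-contiguous reentrant bands are reported, not
#' hidden.
#'
#' @param classifications `data.frame(ci, outcome)` with outcome in
#'   `no_capture`, `capture_no_reentry`, `reentry`.
#' @return List with `first` (largest reentrant CI), `last` (smallest),
#'   `empty` flag and `contiguous` flag (reentrant CIs form one unbroken
#'   block of scanned CIs).
#' @export
vulnerableWindow <- function(classifications) {
  stopifnot(all(c("ci", "outcome") %in% names(classifications)))
  re <- classifications$ci[classifications$outcome == "reentry"]
  if (!length(re))
    return(list(first = NA_real_, last = NA_real_, empty = TRUE,
                contiguous = TRUE))
  scanned <- sort(unique(classifications$ci), decreasing = TRUE)
  inBand <- scanned[scanned <= max(re) & scanned >= min(re)]
  list(first = max(re), last = min(re), empty = FALSE,
       contiguous = all(inBand %in% re))
}
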
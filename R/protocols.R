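# Programmed-stimulation protocol drivers: diastolic threshold search, His
# pacing (anterograde), S1 pacing (retrograde), S1S2 coupling-interval scan,
# and the two-stage rapid line-pacing protocol.

# longest calibrated APD in the model (ms), for quiescence gaps
.longestApd <- function(model) {
  apd <- 0
  d <- model@domain
  if (!is.null(d))
    apd <- max(apd, if (!is.null(d@apdTarget)) max(d@apdTarget)
                    else 1.3 * max(d@tauClose))
  if (length(model@netParams$tauClose))
    apd <- max(apd, 1.3 * max(model@netParams$tauClose))
  max(apd, 100)
}

.quiesceGap <- function(model) 1.25 * .longestApd(model)

#' Find the diastolic stimulation threshold
#'
#' Linear scan from zero in fixed increments of the stimulus
#' current-density scale until action potential propagation is initiated in
#' the myocardium from the stimulus site. Capture is defined as at least one
#' activation event beyond two passive space constants of the site within
#' 50 ms of stimulus end. The search is re-run for each new set of model
#' parameters by the protocol drivers.
#'
#' @param model A [CoupledModel-class] at rest.
#' @param site A [StimulusEvent-class] giving the electrode geometry and
#'   duration (its amplitude is ignored).
#' @param increment Scan increment (1/ms).
#' @param cap Abort amplitude: no capture at or below it is an error.
#' @return A [ThresholdResult-class].
#' @export
findDiastolicThreshold <- function(model, site, increment = 0.05, cap = 5) {
  stopifnot(site@medium == "tissue")
  d <- model@domain
  co <- tissueCoords(d)
  center <- c(mean(co$x[site@nodes]), mean(co$y[site@nodes]))
  siteRadius <- sqrt(max((co$x[site@nodes] - center[1])^2 +
                           (co$y[site@nodes] - center[2])^2))
  lambda <- sqrt(max(d@D) * max(d@tauOut))
  captR2 <- (siteRadius + 2 * lambda)^2
  far <- which((co$x - center[1])^2 + (co$y - center[2])^2 > captR2)
  model <- resetState(model)
  amps <- captured <- numeric(0)
  amp <- 0
  repeat {
    amp <- amp + increment
    if (amp > cap + 1e-12)
      stop(sprintf("no capture below the amplitude cap %.3g", cap))
    stim <- site; stim@amplitude <- amp; stim@onset <- 0
    tr <- runSimulation(model, list(stim), tEnd = site@duration + 50)
    ev <- tr@events
    hit <- any(ev$medium == "tissue" & ev$dir == 1L & ev$node %in% far &
                 ev$time > site@duration & ev$time <= site@duration + 50)
    amps <- c(amps, amp); captured <- c(captured, hit)
    if (hit) break
  }
  new("ThresholdResult", threshold = amp,
      searchTrace = data.frame(amplitude = amps, captured = as.logical(captured)))
}

# per-beat 1:1 capture check over a drive train
.checkCapture <- function(trace, onsets, cl, medium = "tissue") {
  ev <- trace@events
  for (b in seq_along(onsets)) {
    w <- ev$medium == medium & ev$dir == 1L &
      ev$time >= onsets[b] & ev$time < onsets[b] + cl
    if (!any(w))
      stop(sprintf("loss of 1:1 capture during the drive at beat %d", b))
  }
  invisible(TRUE)
}

#' His-bundle pacing (anterograde activation)
#'
#' Paces the His bundle for `beats` cycles and returns the activation maps
#' of the final beat for both media.
#'
#' @param model A [CoupledModel-class] with a network (fails otherwise).
#' @param cl Cycle length (ms), default 750.
#' @param beats Number of cycles, default 10.
#' @param amplitude Network stimulus amplitude (1/ms).
#' @return List with `trace`, `map` (myocardium, last beat), `networkMap`,
#'   and `window` (the last-beat window used).
#' @export
runHisPacing <- function(model, cl = 750, beats = 10, amplitude = 0.8) {
  if (is.null(model@network))
    stop("His pacing requires a model with a Purkinje network")
  model <- resetState(model)
  onsets <- (seq_len(beats) - 1) * cl
  stims <- lapply(onsets, function(t0) hisStimulus(model, onset = t0,
                                                   amplitude = amplitude))
  tr <- runSimulation(model, stims, tEnd = beats * cl)
  .checkCapture(tr, onsets, cl, "network")
  if (!is.null(model@domain)) .checkCapture(tr, onsets, cl, "tissue")
  w <- c((beats - 1) * cl, beats * cl)
  list(trace = tr,
       map = if (is.null(model@domain)) NULL else activationMap(tr, w, "tissue"),
       networkMap = activationMap(tr, w, "network"),
       window = w)
}

#' Apical S1 pacing (retrograde activation)
#'
#' Paces the myocardium from a small spherical electrode at the apex (the
#' catheter analog, diameter 1.5 mm) for `beats` cycles at twice the
#' diastolic threshold; the network activates only retrogradely through the
#' PMJs. Returns last-beat activation maps for both media.
#'
#' @param model A [CoupledModel-class].
#' @param cl Cycle length (ms), default 600.
#' @param beats Number of cycles, default 10.
#' @param site Optional [StimulusEvent-class] electrode; default is a
#'   1.5 mm sphere at the apex mid-line.
#' @param ampMultiple Amplitude as a multiple of the diastolic threshold.
#' @param threshold Optional precomputed [ThresholdResult-class].
#' @param increment Threshold-search increment.
#' @return List with `trace`, `map`, `networkMap`, `window`, `threshold`.
#' @export
runS1Pacing <- function(model, cl = 600, beats = 10, site = NULL,
                        ampMultiple = 2, threshold = NULL, increment = 0.05) {
  if (is.null(model@domain)) stop("S1 pacing requires a tissue domain")
  if (is.null(site)) {
    sz <- .domainSize(model@domain)
    site <- sphereStimulus(model, c(sz["w"] / 2, 0), diameter = 1.5)
  }
  if (is.null(threshold))
    threshold <- findDiastolicThreshold(model, site, increment = increment)
  model <- resetState(model)
  onsets <- (seq_len(beats) - 1) * cl
  stims <- lapply(onsets, function(t0) {
    s <- site; s@onset <- t0; s@amplitude <- ampMultiple * threshold@threshold
    s
  })
  tr <- runSimulation(model, stims, tEnd = beats * cl)
  .checkCapture(tr, onsets, cl, "tissue")
  w <- c((beats - 1) * cl, beats * cl)
  list(trace = tr, map = activationMap(tr, w, "tissue"),
       networkMap = if (is.null(model@network)) NULL
                    else activationMap(tr, w, "network"),
       window = w, threshold = threshold)
}

#' S1S2 programmed stimulation scan
#'
#' After an S1 drive at the apical site, applies a single premature S2 from
#' the same electrode at coupling intervals starting at `s2Start` and
#' decreasing by `decrement` until loss of stimulus capture (no activation
#' outside the electrode footprint within 50 ms of S2 end). Each coupling
#' interval resumes from the post-drive state saved once, so the scan costs
#' one single-beat continuation per CI. Outcomes are classified as
#' `no_capture`, `capture_no_reentry` or `reentry` (at least two full
#' rotations, delegated to [detectReentry()]).
#'
#' @param model A [CoupledModel-class].
#' @param cl S1 cycle length (ms), default 600.
#' @param beats S1 beats, default 10.
#' @param site Optional electrode; defaults as in [runS1Pacing()].
#' @param ampMultiple Stimulus strength in diastolic thresholds (S1 and S2).
#' @param s2Start First (largest) coupling interval (ms).
#' @param decrement CI decrement (ms).
#' @param observeMs Post-S2 observation per CI (ms).
#' @param threshold Optional precomputed [ThresholdResult-class].
#' @return List with `classifications` (`data.frame(ci, outcome, rotations,
#'   duration_s)`), `window` (from [vulnerableWindow()]), `threshold`, and
#'   `postDrive` (the saved model for re-running single CIs).
#' @export
runS1S2Scan <- function(model, cl = 600, beats = 10, site = NULL,
                        ampMultiple = 2, s2Start = 400, decrement = 10,
                        observeMs = 1500, threshold = NULL) {
  if (is.null(model@domain)) stop("the S1S2 scan requires a tissue domain")
  if (is.null(site)) {
    sz <- .domainSize(model@domain)
    site <- sphereStimulus(model, c(sz["w"] / 2, 0), diameter = 1.5)
  }
  if (is.null(threshold)) threshold <- findDiastolicThreshold(model, site)
  amp <- ampMultiple * threshold@threshold
  model <- resetState(model)
  # drive up to the onset of the final S1; the final S1 is replayed in each
  # continuation so that the S2 coupling interval is measured from it
  tLast <- (beats - 1) * cl
  onsets <- (seq_len(beats - 1) - 1) * cl
  stims <- lapply(onsets, function(t0) {
    s <- site; s@onset <- t0; s@amplitude <- amp; s
  })
  drive <- runSimulation(model, stims, tEnd = tLast)
  .checkCapture(drive, onsets, cl, "tissue")
  saved <- drive@finalModel
  gap <- .quiesceGap(model)

  cis <- seq(s2Start, decrement, by = -decrement)
  out <- data.frame(ci = numeric(0), outcome = character(0),
                    rotations = integer(0), duration_s = numeric(0))
  for (ci in cis) {
    s1 <- site; s1@onset <- tLast; s1@amplitude <- amp
    s2 <- site; s2@onset <- tLast + ci; s2@amplitude <- amp
    tr <- runSimulation(saved, list(s1, s2),
                        tEnd = tLast + ci + s2@duration + observeMs,
                        quiesceGap = gap)
    s2End <- tLast + ci + s2@duration
    ev <- tr@events
    capt <- any(ev$medium == "tissue" & ev$dir == 1L &
                  !(ev$node %in% site@nodes) &
                  ev$time > s2End & ev$time <= s2End + 50)
    if (!capt) {
      out <- rbind(out, data.frame(ci = ci, outcome = "no_capture",
                                   rotations = 0L, duration_s = 0))
      break
    }
    rep <- detectReentry(ev, finalStimTime = tLast + ci,
                         observeEnd = tr@t1, quiesceGap = gap)
    out <- rbind(out, data.frame(
      ci = ci,
      outcome = if (rep@induced) "reentry" else "capture_no_reentry",
      rotations = rep@rotations, duration_s = rep@durationS))
  }
  list(classifications = out, window = vulnerableWindow(out),
       threshold = threshold, postDrive = saved, tLastS1 = tLast, amp = amp,
       site = site)
}

#' Rerun one S1S2 coupling interval with a long observation window
#'
#' Used to measure reentry duration (arrhythmia maintenance) for a chosen
#' CI, e.g. the largest reentrant CI found by [runS1S2Scan()].
#'
#' @param scan Result of [runS1S2Scan()].
#' @param ci Coupling interval (ms).
#' @param observeMs Observation window (ms), default 20000 (20 s).
#' @return List with `trace` and `report` ([ReentryReport-class]).
#' @export
rerunS2 <- function(scan, ci, observeMs = 20000) {
  saved <- scan$postDrive
  site <- scan$site
  s1 <- site; s1@onset <- scan$tLastS1; s1@amplitude <- scan$amp
  s2 <- site; s2@onset <- scan$tLastS1 + ci; s2@amplitude <- scan$amp
  gap <- .quiesceGap(saved)
  tr <- runSimulation(saved, list(s1, s2),
                      tEnd = scan$tLastS1 + ci + s2@duration + observeMs,
                      quiesceGap = gap)
  rep <- detectReentry(tr@events, finalStimTime = scan$tLastS1 + ci,
                       observeEnd = tr@t1, quiesceGap = gap)
  list(trace = tr, report = rep)
}

#' Rapid line pacing (arrhythmia maintenance)
#'
#' Two-stage drive from an apicobasal line electrode (2 mm diameter,
#' parallel to the APD-gradient axis, mid-domain): `beats1` cycles at
#' `cl1` = 400 ms, then `beats2` cycles at `cl2` = 250 ms, all at
#' `ampMultiple` = 8 times the diastolic threshold, followed by an
#' observation window (default 20 s) that ends early on quiescence.
#'
#' @param model A [CoupledModel-class].
#' @param cl1,beats1 Stage-1 cycle length (ms) and beat count.
#' @param cl2,beats2 Stage-2 (rapid) cycle length and beat count.
#' @param ampMultiple Stimulus strength in diastolic thresholds.
#' @param line Optional `list(from, to)` endpoints (mm); default mid-domain
#'   apicobasal line inset 2 mm from the apex and base edges.
#' @param threshold Optional precomputed [ThresholdResult-class].
#' @param observeMs Observation window after the final beat (ms).
#' @return List with `trace`, `report` ([ReentryReport-class]),
#'   `threshold` and `schedule` (the stimulus bookkeeping data frame).
#' @export
runLinePacing <- function(model, cl1 = 400, beats1 = 10, cl2 = 250,
                          beats2 = 10, ampMultiple = 8, line = NULL,
                          threshold = NULL, observeMs = 20000) {
  if (is.null(model@domain)) stop("line pacing requires a tissue domain")
  sz <- .domainSize(model@domain)
  if (is.null(line))
    line <- list(from = c(sz["w"] / 2, 2), to = c(sz["w"] / 2, sz["h"] - 2))
  site <- lineStimulus(model, line$from, line$to, diameter = 2)
  if (is.null(threshold)) threshold <- findDiastolicThreshold(model, site)
  amp <- ampMultiple * threshold@threshold
  model <- resetState(model)
  onsets <- c((seq_len(beats1) - 1) * cl1,
              beats1 * cl1 + (seq_len(beats2) - 1) * cl2)
  stims <- lapply(onsets, function(t0) {
    s <- site; s@onset <- t0; s@amplitude <- amp; s
  })
  finalStim <- onsets[length(onsets)]
  gap <- .quiesceGap(model)
  tr <- runSimulation(model, stims, tEnd = finalStim + cl2 + observeMs,
                      quiesceGap = gap)
  rep <- detectReentry(tr@events, finalStimTime = finalStim,
                       observeEnd = min(tr@t1, finalStim + observeMs),
                       quiesceGap = gap)
  list(trace = tr, report = rep, threshold = threshold,
       schedule = data.frame(onset = onsets, duration = site@duration,
                             amplitude = amp,
                             stage = rep(c(1L, 2L), c(beats1, beats2)),
                             cl = rep(c(cl1, cl2), c(beats1, beats2))))
}
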
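# Phenomenological membrane kinetics: a two-variable reaction model
#   dv/dt = h v^2 (1 - v)/tau_in - v/tau_out + I_stim
#   dh/dt = (1 - h)/tau_open  if v < v_gate,  -h/tau_close otherwise
# with v mapped affinely to [vRest, vPeak] mV. tau_close is the APD dial;
# the Purkinje presets stand in for the slow-delayed-rectifier (G_Ks)
# reduction that lengthens Purkinje APD relative to the myocardium: the
# functional consequence (an APD gap, on average 56 ms at the junctions) is
# implemented as a calibration target rather than an ionic-current change.

#' Construct a membrane parameter set
#'
#' @param tauIn,tauOut,tauOpen,tauClose Time constants (ms).
#' @param vGate Dimensionless excitation threshold.
#' @param vRest,vPeak Potential mapping (mV).
#' @param apdExtensionFactor APD extension bookkeeping for Purkinje variants.
#' @return A [MembraneParams-class] object.
#' @export
membraneParams <- function(tauIn = 0.3, tauOut = 6, tauOpen = 35,
                           tauClose = 150, vGate = 0.13, vRest = -85,
                           vPeak = 25, apdExtensionFactor = 1) {
  new("MembraneParams", tauIn = tauIn, tauOut = tauOut, tauOpen = tauOpen,
      tauClose = tauClose, vGate = vGate, vRest = vRest, vPeak = vPeak,
      apdExtensionFactor = apdExtensionFactor)
}

#' Named membrane presets
#'
#' `"myocardium"` is the ventricular working-myocardium reference
#' (single-cell APD close to 300 ms at a 750 ms cycle length).
#' `"purkinje_default"` extends APD moderately (+20 ms), standing in for
#' Purkinje tissue at the default repolarization-current conductance;
#' `"purkinje_arrhythmogenic"` carries the reduced-conductance substrate,
#' calibrated so that Purkinje APD exceeds myocardial APD by 56 ms. The
#' Purkinje `tauClose` values were obtained with [calibrateAPD()] against the
#' myocardium preset at a 750 ms cycle length.
#'
#' @param name One of `"myocardium"`, `"purkinje_default"`,
#'   `"purkinje_arrhythmogenic"`.
#' @return A [MembraneParams-class] object.
#' @export
membranePreset <- function(name = c("myocardium", "purkinje_default",
                                    "purkinje_arrhythmogenic")) {
  name <- match.arg(name)
  switch(name,
    myocardium = membraneParams(),
    purkinje_default = calibrateAPD(
      singleCellAPD(membraneParams(), cl = 750) + 20, cl = 750,
      base = membraneParams(), tol = 0.5),
    purkinje_arrhythmogenic = calibrateAPD(
      singleCellAPD(membraneParams(), cl = 750) + 56, cl = 750,
      base = membraneParams(), tol = 0.5)
  )
}

#' Advance membrane states by one reaction step (no diffusion)
#'
#' Vectorized over nodes: forward-Euler update of `v` and an exact
#' exponential update of the gate `h` (which therefore stays in [0, 1] for
#' any `dt`). With `iStim = 0` and `v = 0` the state is a fixed point.
#'
#' @param state List with numeric vectors `v` and `h`.
#' @param params A [MembraneParams-class], or a list of per-node numeric
#'   vectors `tauIn`, `tauOut`, `tauOpen`, `tauClose` (recycled), with
#'   scalar `vGate`.
#' @param iStim Stimulus current density (1/ms), scalar or per node.
#' @param dt Time step (ms).
#' @return Updated state list.
#' @export
reactionStep <- function(state, params, iStim = 0, dt = 0.05) {
  if (!all(is.finite(state$v)) || !all(is.finite(state$h))) {
    bad <- which(!is.finite(state$v) | !is.finite(state$h))[1]
    stop(sprintf("non-finite membrane state at node %d", bad))
  }
  if (is(params, "MembraneParams"))
    params <- list(tauIn = params@tauIn, tauOut = params@tauOut,
                   tauOpen = params@tauOpen, tauClose = params@tauClose,
                   vGate = params@vGate)
  v <- state$v; h <- state$h
  dv <- h * v^2 * (1 - v) / params$tauIn - v / params$tauOut + iStim
  below <- v < params$vGate
  hNew <- ifelse(below,
                 h + (1 - h) * (-expm1(-dt / params$tauOpen)),
                 h * exp(-dt / params$tauClose))
  list(v = v + dt * dv, h = hNew)
}

#' Map the dimensionless transmembrane variable to millivolts (and back)
#'
#' @param v Dimensionless state.
#' @param params A [MembraneParams-class] (or anything with vRest/vPeak slots).
#' @return Potential in mV.
#' @export
vToMv <- function(v, params) params@vRest + v * (params@vPeak - params@vRest)

#' @rdname vToMv
#' @param mv Potential in mV.
#' @export
mvToV <- function(mv, params) (mv - params@vRest) / (params@vPeak - params@vRest)

# v-units value of the -10 mV activation/repolarization threshold
.vth <- function(vRest, vPeak) (-10 - vRest) / (vPeak - vRest)

#' Single-cell action potential duration under pacing
#'
#' Paces an isolated cell at cycle length `cl` (2 ms suprathreshold pulses)
#' and measures the APD of the last beat between the ascending and
#' descending crossings of the mapped -10 mV threshold.
#'
#' @param params A [MembraneParams-class].
#' @param cl Pacing cycle length (ms).
#' @param beats Number of paced beats (the last is measured).
#' @param dt Integration step (ms).
#' @param stimAmp Stimulus amplitude (1/ms).
#' @return APD in ms (`NA` if the last beat shows no full action potential).
#' @export
singleCellAPD <- function(params, cl = 750, beats = 4, dt = 0.02,
                          stimAmp = 0.3) {
  vth <- .vth(params@vRest, params@vPeak)
  cr <- .cellCrossings(params@tauIn, params@tauOut, params@tauOpen,
                       params@tauClose, params@vGate, vth, cl, beats,
                       stimAmp, 2, dt)
  tLast <- (beats - 1) * cl
  up <- cr$up[cr$up >= tLast]
  if (!length(up)) return(NA_real_)
  down <- cr$down[cr$down > up[1]]
  if (!length(down)) return(NA_real_)
  down[1] - up[1]
}

#' Calibrate tau_close against a target APD
#'
#' Bisection on `tauClose` so that the single-cell APD at pacing cycle
#' length `cl` matches `targetApd` within `tol`. Used to realize the
#' Purkinje-versus-myocardium APD gap and the apicobasal APD gradient.
#'
#' @param targetApd Target APD (ms).
#' @param cl Pacing cycle length (ms).
#' @param base A [MembraneParams-class] providing all other parameters.
#' @param tol Tolerance (ms).
#' @param bracket Search bracket for `tauClose` (ms).
#' @return A [MembraneParams-class] with calibrated `tauClose` and
#'   `apdExtensionFactor` set to achieved/base APD.
#' @export
calibrateAPD <- function(targetApd, cl = 750, base = membraneParams(),
                         tol = 2, bracket = c(5, 2000)) {
  f <- function(tc) {
    p <- base; p@tauClose <- tc
    singleCellAPD(p, cl = cl)
  }
  lo <- bracket[1]
  flo <- f(lo)
  if (is.na(flo) || flo > targetApd)
    stop(sprintf(
      "target APD %.1f ms below the achievable minimum (%.1f ms at tau_close = %g)",
      targetApd, flo, lo))
  # APD grows monotonically with tau_close only until capture breaks down
  # (alternans / 2:1 block at the pacing rate), so grow the upper bracket by
  # doubling and stop at the edge of the monotone regime
  hi <- lo; fhi <- flo
  repeat {
    cand <- min(bracket[2], hi * 2)
    fc <- f(cand)
    if (is.na(fc) || fc < fhi) break
    hi <- cand; fhi <- fc
    if (fhi >= targetApd || hi >= bracket[2] - 1e-9) break
  }
  if (fhi < targetApd)
    stop(sprintf(
      "target APD %.1f ms unreachable at cycle length %g ms (max %.1f ms before capture breaks down)",
      targetApd, cl, fhi))
  baseApd <- singleCellAPD(base, cl = cl)
  for (i in seq_len(60)) {
    mid <- 0.5 * (lo + hi)
    fm <- f(mid)
    if (!is.na(fm) && abs(fm - targetApd) <= tol * 0.5) {
      lo <- hi <- mid
      break
    }
    if (!is.na(fm) && fm < targetApd) lo <- mid else hi <- mid
  }
  out <- base
  out@tauClose <- 0.5 * (lo + hi)
  achieved <- singleCellAPD(out, cl = cl)
  if (abs(achieved - targetApd) > tol)
    stop(sprintf("calibration did not converge: achieved %.2f ms for target %.2f ms",
                 achieved, targetApd))
  out@apdExtensionFactor <- max(1, achieved / baseApd)
  out
}

#' Linear APD-to-tau_close interpolation map
#'
#' Calibrates `tauClose` at the two ends of an APD range (single-cell
#' bisection) and returns a linear interpolant, used to paint smooth APD
#' gradients over thousands of tissue nodes without per-node bisection. APD
#' is very close to linear in `tauClose` for this model.
#'
#' @param apdLo,apdHi APD range endpoints (ms).
#' @param base A [MembraneParams-class] template.
#' @param cl Pacing cycle length (ms) for calibration.
#' @return Function mapping APD (ms) to `tauClose` (ms).
#' @export
apdToTauCloseMap <- function(apdLo, apdHi, base = membraneParams(), cl = 750) {
  pLo <- calibrateAPD(apdLo, cl = cl, base = base, tol = 0.5)
  if (apdHi <= apdLo + 1e-9) {
    tc <- pLo@tauClose
    return(function(apd) rep(tc, length(apd)))
  }
  pHi <- calibrateAPD(apdHi, cl = cl, base = base, tol = 0.5)
  slope <- (pHi@tauClose - pLo@tauClose) / (apdHi - apdLo)
  function(apd) pLo@tauClose + slope * (apd - apdLo)
}
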
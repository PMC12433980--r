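# Generics for the verbs that dispatch on package classes, plus show methods.

#' Prune distal Purkinje fiber reconnections
#'
#' Converts a meshed Purkinje network into a tree: at each reunification
#' point with two (or more) parent cables, every parent cable but the first
#' (smallest cable id) is removed back to the point where it originated at a
#' bifurcation -- the walk passes through degree-2 internal nodes and stops
#' at the first node of degree >= 3 or at the His root. PMJ terminals and
#' proximal (fascicle) cables are never removed, so no PMJ is left
#' unconnected.
#'
#' @param net A [PurkinjeNetwork-class] in mesh mode (a tree passes through
#'   unchanged).
#' @return A [PurkinjeNetwork-class] in tree mode with the identical PMJ
#'   terminal set; the input is not modified.
#' @export
setGeneric("pruneReconnections", function(net) standardGeneric("pruneReconnections"))

#' Topology summary of a Purkinje network
#'
#' @param net A [PurkinjeNetwork-class].
#' @return A list with node/edge/cable counts, number of reunification nodes
#'   (in-degree >= 2), undirected cycle count (E - V + C), and
#'   `pathMultiplicity`: for every `pmj_terminal` node, the number of
#'   distinct directed His-to-terminal paths.
#' @export
setGeneric("networkStats", function(net) standardGeneric("networkStats"))

#' Compare two activation maps
#'
#' Computes the map-difference statistics for a variant map `b` against a
#' reference map `a` over the nodes activated in both: per-node difference
#' `d = b - a`; RMSD reported as mean +/- sd of `|d|`; relative difference
#' `RD = 100 * sum(|d|) / sum(|a|)`; Pearson correlation CC; and the percent
#' absolute change in total activation time, where total AT is the range
#' (max - min) of the map. Argument order matters (variant versus
#' reference): RD is not symmetric.
#'
#' @param a Reference [ActivationMap-class].
#' @param b Variant [ActivationMap-class]; same medium and node count.
#' @return A [MapComparison-class].
#' @export
setGeneric("compareMaps", function(a, b) standardGeneric("compareMaps"))

#' Per-node absolute activation-time difference
#'
#' @param a,b [ActivationMap-class] objects over the same node set.
#' @return Numeric vector `|b - a|` (ms); `NA` where either map is
#'   unactivated.
#' @export
setGeneric("absDifferenceMap", function(a, b) standardGeneric("absDifferenceMap"))

setMethod("show", "MembraneParams", function(object) {
  cat("MembraneParams: tau_in", object@tauIn, "tau_out", object@tauOut,
      "tau_open", object@tauOpen, "tau_close", round(object@tauClose, 2),
      "| v_gate", object@vGate, "| map [", object@vRest, ",", object@vPeak, "] mV\n")
})

setMethod("show", "TissueDomain", function(object) {
  cat(sprintf("TissueDomain: %d x %d nodes, %.3g mm spacing (%.3g x %.3g mm)\n",
              object@nx, object@ny, object@spacing,
              (object@nx - 1L) * object@spacing, (object@ny - 1L) * object@spacing))
  cat(sprintf("  D in [%.3g, %.3g] mm^2/ms; tau_close in [%.3g, %.3g] ms\n",
              min(object@D), max(object@D), min(object@tauClose), max(object@tauClose)))
})

setMethod("show", "PurkinjeNetwork", function(object) {
  indeg <- table(object@edges$to)
  cat(sprintf("PurkinjeNetwork (%s): %d nodes, %d edges, %d cables\n",
              object@topologyMode, nrow(object@nodes), nrow(object@edges),
              nrow(object@cables)))
  cat(sprintf("  %d pmj_terminal, %d reunification node(s), %d bridge cable(s)\n",
              sum(object@nodes$role == "pmj_terminal"), sum(indeg > 1L),
              sum(object@cables$kind == "bridge")))
})

setMethod("show", "PMJSet", function(object) {
  cat(sprintf("PMJSet: %d junction(s), resistance %.3g-%.3g Ohm, footprint size %d-%d\n",
              length(object@terminal), min(object@resistance), max(object@resistance),
              min(vapply(object@footprint, length, 1L)),
              max(vapply(object@footprint, length, 1L))))
})

setMethod("show", "CoupledModel", function(object) {
  nt <- if (is.null(object@domain)) 0L else object@domain@nx * object@domain@ny
  nn <- length(object@netIndex)
  np <- if (is.null(object@pmjs)) 0L else length(object@pmjs@terminal)
  cat(sprintf("CoupledModel: %d tissue node(s), %d network node(s), %d PMJ(s); t = %.6g ms, dt = %g ms\n",
              nt, nn, np, object@time, object@dt))
})

setMethod("show", "SimulationTrace", function(object) {
  cat(sprintf("SimulationTrace: [%.6g, %.6g] ms (%s), %d event(s)\n",
              object@t0, object@t1, object@stopped, nrow(object@events)))
})

setMethod("show", "ActivationMap", function(object) {
  act <- sum(!is.na(object@at))
  cat(sprintf("ActivationMap (%s): %d/%d node(s) activated", object@medium,
              act, length(object@at)))
  if (act) cat(sprintf(", total AT %.6g ms", totalAT(object)))
  cat("\n")
})

setMethod("show", "MapComparison", function(object) {
  cat(sprintf("MapComparison: %%|dTotalAT| %.3g, RD %.3g%%, RMSD %.3g +/- %.3g ms, CC %.4g (n = %d shared; %d/%d excluded)\n",
              object@pctAbsDeltaTotalAT, object@rd, object@rmsdMean,
              object@rmsdSd, object@cc, object@nShared, object@nOnlyA, object@nOnlyB))
})

setMethod("show", "ReentryReport", function(object) {
  cat(sprintf("ReentryReport: induced = %s, rotations = %d, duration = %.3g s, terminated = %s\n",
              object@induced, object@rotations, object@durationS, object@terminated))
})

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf("ThresholdResult: threshold %.4g (after %d trial(s))\n",
              object@threshold, nrow(object@searchTrace)))
})

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf("FixtureSpec '%s': %g x %g mm @ %g mm, APD %g-%g ms (+%g ms Purkinje), %g PMJ/cm^2, reconnection rate %g, seed %d\n",
              object@name, object@width, object@height, object@spacing,
              object@apdRange[1], object@apdRange[2], object@purkinjeApdGap,
              object@pmjDensity, object@reconnectionRate, object@seed))
})
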
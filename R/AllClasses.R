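# S4 class definitions. Validity methods enforce the structural invariants
# that the algorithms rely on; expensive graph-wide checks live in
# networkStats()/tests rather than in validity, so that validObject() stays
# cheap on ~10^3-node networks.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Membrane parameter set for the two-variable reaction model
#'
#' Phenomenological action-potential kinetics (a Mitchell-Schaeffer-type
#' two-variable model) used for both myocardium and Purkinje tissue. The
#' dimensionless transmembrane variable `v` is mapped affinely to millivolts
#' via `vRest` and `vPeak`, which makes the -10 mV activation threshold and
#' APD measurement well defined.
#'
#' @slot tauIn,tauOut,tauOpen,tauClose Time constants (ms) of the inward
#'   current, outward current, gate recovery and gate closure. `tauClose` is
#'   the main APD dial: APD grows monotonically with it.
#' @slot vGate Dimensionless excitation threshold of the gate dynamics.
#' @slot vRest,vPeak Resting and peak transmembrane potential (mV) used for
#'   the affine mapping of `v` to millivolts.
#' @slot apdExtensionFactor Dimensionless factor >= 1 recording how much a
#'   Purkinje variant's APD was extended relative to its myocardial base.
#' @export
setClass("MembraneParams",
  representation(
    tauIn = "numeric", tauOut = "numeric", tauOpen = "numeric",
    tauClose = "numeric", vGate = "numeric", vRest = "numeric",
    vPeak = "numeric", apdExtensionFactor = "numeric"
  ),
  prototype(
    tauIn = 0.3, tauOut = 6, tauOpen = 35, tauClose = 150,
    vGate = 0.13, vRest = -85, vPeak = 25, apdExtensionFactor = 1
  )
)

setValidity("MembraneParams", function(object) {
  msg <- character()
  tc <- c(object@tauIn, object@tauOut, object@tauOpen, object@tauClose)
  if (any(!is.finite(tc)) || any(tc <= 0))
    msg <- c(msg, "all time constants must be finite and > 0")
  if (!(object@vRest < -10 && -10 < object@vPeak))
    msg <- c(msg, "vRest < -10 mV < vPeak is required for the activation threshold")
  if (object@apdExtensionFactor < 1)
    msg <- c(msg, "apdExtensionFactor must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Discretized myocardial tissue domain
#'
#' A structured 2D sheet (a 1-row grid gives a 1D cable) with per-node
#' membrane-parameter fields and a per-node isotropic conductivity field.
#' Node `k` (1-based, row-major with x fastest) sits at
#' `((k-1) %% nx, (k-1) %/% nx) * spacing` mm. Boundaries are zero-flux.
#'
#' @slot nx,ny Grid dimensions.
#' @slot spacing Node spacing (mm).
#' @slot tauIn,tauOut,tauOpen,tauClose Per-node membrane time constants (ms).
#' @slot D Per-node diffusivity (mm^2/ms).
#' @slot vGate,vRest,vPeak Scalars shared across the domain.
#' @slot apdTarget Optional per-node APD (ms) the `tauClose` field was
#'   calibrated to; `NULL` when the field was set directly.
#' @export
setClass("TissueDomain",
  representation(
    nx = "integer", ny = "integer", spacing = "numeric",
    tauIn = "numeric", tauOut = "numeric", tauOpen = "numeric",
    tauClose = "numeric", D = "numeric",
    vGate = "numeric", vRest = "numeric", vPeak = "numeric",
    apdTarget = "numericOrNULL"
  )
)

setValidity("TissueDomain", function(object) {
  msg <- character()
  nt <- object@nx * object@ny
  if (object@nx < 1L || object@ny < 1L) msg <- c(msg, "nx, ny must be >= 1")
  if (object@spacing <= 0) msg <- c(msg, "spacing must be > 0")
  for (f in c("tauIn", "tauOut", "tauOpen", "tauClose", "D")) {
    v <- slot(object, f)
    if (length(v) != nt) msg <- c(msg, sprintf("field %s must have length nx*ny", f))
    else if (any(!is.finite(v)) || any(v <= 0)) msg <- c(msg, sprintf("field %s must be finite and > 0", f))
  }
  if (!is.null(object@apdTarget) && length(object@apdTarget) != nt)
    msg <- c(msg, "apdTarget must be NULL or length nx*ny")
  if (length(msg)) msg else TRUE
})

#' Purkinje network graph
#'
#' A directed graph of cables rooted at the His bundle. Nodes carry a role:
#' `his_root` (exactly one), `branch_point` (bifurcations), `reunification`
#' (a node with two or more parent cables -- the structural signature of a
#' distal Purkinje fiber reconnection), `pmj_terminal` (candidate
#' Purkinje-muscular junction sites, out-degree 0) and `internal`.
#'
#' @slot nodes `data.frame(id, x, y, z, role)`; coordinates in mm.
#' @slot edges `data.frame(from, to, cable, length)` -- directed segments,
#'   His side to distal side, grouped into cables; lengths in mm.
#' @slot cables `data.frame(id, proximal, cvScale, kind)`; `proximal` cables
#'   (His bundle and major fascicles) are never pruned; `kind` is `"branch"`
#'   or `"bridge"` (a reunification cross-bridge); `cvScale` multiplies the
#'   cable conduction velocity.
#' @slot topologyMode `"mesh"` (at least one reunification node) or
#'   `"tree"` (every non-root node has exactly one incoming edge).
#' @export
setClass("PurkinjeNetwork",
  representation(
    nodes = "data.frame", edges = "data.frame", cables = "data.frame",
    topologyMode = "character"
  )
)

setValidity("PurkinjeNetwork", function(object) {
  msg <- character()
  nd <- object@nodes; ed <- object@edges
  roles <- c("his_root", "branch_point", "reunification", "pmj_terminal", "internal")
  if (!all(nd$role %in% roles)) msg <- c(msg, "unknown node role")
  if (sum(nd$role == "his_root") != 1L) msg <- c(msg, "exactly one his_root required")
  if (anyDuplicated(nd$id)) msg <- c(msg, "duplicated node ids")
  if (nrow(ed)) {
    if (!all(c(ed$from, ed$to) %in% nd$id)) msg <- c(msg, "edge endpoint not in node table")
    if (!all(ed$cable %in% object@cables$id)) msg <- c(msg, "edge cable id not in cable table")
    indeg <- table(ed$to)
    term <- nd$id[nd$role == "pmj_terminal"]
    if (any(term %in% ed$from)) msg <- c(msg, "pmj_terminal nodes must have out-degree 0")
    if (object@topologyMode == "tree" && any(indeg > 1L))
      msg <- c(msg, "tree mode requires in-degree <= 1 everywhere")
    if (object@topologyMode == "mesh" && !any(indeg > 1L))
      msg <- c(msg, "mesh mode requires at least one reunification node")
  }
  if (!object@topologyMode %in% c("mesh", "tree")) msg <- c(msg, "topologyMode must be mesh or tree")
  if (length(msg)) msg else TRUE
})

#' Set of Purkinje-muscular junctions
#'
#' Each PMJ couples one `pmj_terminal` network node to a non-empty footprint
#' of tissue nodes through a lumped junctional resistance (default 100 kOhm,
#' the physiological reference value).
#'
#' @slot terminal Integer vector of network node ids.
#' @slot resistance Numeric vector of junctional resistances (Ohm).
#' @slot footprint List of integer vectors of tissue node indices (1-based).
#' @export
setClass("PMJSet",
  representation(terminal = "integer", resistance = "numeric", footprint = "list")
)

setValidity("PMJSet", function(object) {
  msg <- character()
  n <- length(object@terminal)
  if (length(object@resistance) != n || length(object@footprint) != n)
    msg <- c(msg, "terminal, resistance and footprint must have equal length")
  if (any(object@resistance <= 0)) msg <- c(msg, "junctional resistance must be > 0")
  if (n && any(vapply(object@footprint, length, 1L) == 0L))
    msg <- c(msg, "every PMJ footprint must be non-empty")
  if (length(msg)) msg else TRUE
})

setClassUnion("TissueDomainOrNULL", c("TissueDomain", "NULL"))
setClassUnion("PurkinjeNetworkOrNULL", c("PurkinjeNetwork", "NULL"))
setClassUnion("PMJSetOrNULL", c("PMJSet", "NULL"))

#' Coupled tissue/network simulation model
#'
#' The simulable unit: a tissue domain, an optional Purkinje network with
#' per-node membrane parameters and cable diffusivities, the PMJ couplings
#' between them, and the current membrane states of both media. Either
#' medium may be absent (no-network models; network-only ring fixtures).
#'
#' @slot domain Tissue domain or `NULL`.
#' @slot network Purkinje network or `NULL`.
#' @slot pmjs PMJ set or `NULL`.
#' @slot netIndex Integer vector mapping solver network-node index (position)
#'   to `PurkinjeNetwork` node id.
#' @slot netEdges List with `efrom`, `eto` (0-based solver indices) and `ew`
#'   (edge coupling, `D_edge / length^2`, 1/ms).
#' @slot netParams List of per-network-node membrane fields
#'   (`tauIn`, `tauOut`, `tauOpen`, `tauClose`).
#' @slot state List `vT`, `hT`, `vN`, `hN` of current membrane states.
#' @slot time Current model time (ms).
#' @slot dt Macro time step (ms).
#' @slot nsub Diffusion subcycles per macro step.
#' @slot couplGainNet,couplGainMyo Junctional coupling gains (1/ms at the
#'   100 kOhm reference resistance); scaled by `1e5 / resistance` per PMJ.
#' @slot vGate,vRest,vPeak Shared scalars for thresholding and mV mapping.
#' @export
setClass("CoupledModel",
  representation(
    domain = "TissueDomainOrNULL", network = "PurkinjeNetworkOrNULL",
    pmjs = "PMJSetOrNULL",
    netIndex = "integer", netEdges = "list", netParams = "list",
    state = "list", time = "numeric", dt = "numeric", nsub = "integer",
    couplGainNet = "numeric", couplGainMyo = "numeric",
    vGate = "numeric", vRest = "numeric", vPeak = "numeric"
  )
)

setValidity("CoupledModel", function(object) {
  msg <- character()
  if (is.null(object@domain) && is.null(object@network))
    msg <- c(msg, "at least one medium (domain or network) is required")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (!is.null(object@pmjs)) {
    if (is.null(object@domain) || is.null(object@network))
      msg <- c(msg, "PMJs require both a domain and a network")
    else {
      nt <- object@domain@nx * object@domain@ny
      if (!all(object@pmjs@terminal %in% object@netIndex))
        msg <- c(msg, "PMJ terminal not present in the network index")
      if (any(unlist(object@pmjs@footprint) > nt))
        msg <- c(msg, "PMJ footprint node outside the tissue domain")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Stimulus event
#'
#' Transmembrane current injection into a fixed node set of one medium.
#' Amplitude is in units of the model's stimulus current-density scale
#' (dv/dt, 1/ms); protocol drivers express it as a multiple of the measured
#' diastolic threshold.
#'
#' @slot medium `"tissue"` or `"network"`.
#' @slot nodes Target node indices (1-based, solver indexing).
#' @slot onset,duration Stimulus timing (ms); duration defaults to 2 ms.
#' @slot amplitude Injected dv/dt (1/ms).
#' @export
setClass("StimulusEvent",
  representation(medium = "character", nodes = "integer",
                 onset = "numeric", duration = "numeric", amplitude = "numeric"),
  prototype(duration = 2)
)

setValidity("StimulusEvent", function(object) {
  msg <- character()
  if (!object@medium %in% c("tissue", "network")) msg <- c(msg, "medium must be tissue or network")
  if (!length(object@nodes)) msg <- c(msg, "stimulus target must be non-empty")
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (length(msg)) msg else TRUE
})

#' Simulation trace
#'
#' Activation-event stream of a run plus the final model (so protocols can
#' be chained without re-running the drive). Events record interpolated
#' threshold crossings of the mapped transmembrane potential at -10 mV in
#' both directions for both media.
#'
#' @slot events `data.frame(medium, node, time, dir)`; `medium` is
#'   `"tissue"`/`"network"`, `node` 1-based solver index, `time` ms,
#'   `dir` +1 ascending / -1 descending.
#' @slot t0,t1 Start and actual stop time of the run (ms).
#' @slot stopped `"end"` or `"quiescent"`.
#' @slot finalModel The model with states advanced to `t1`.
#' @slot probes Optional probe traces (list with `time` and `v`).
#' @export
setClass("SimulationTrace",
  representation(events = "data.frame", t0 = "numeric", t1 = "numeric",
                 stopped = "character", finalModel = "CoupledModel",
                 probes = "ANY")
)

#' Activation map
#'
#' Per-node time of the first ascending -10 mV crossing within a beat
#' window, in ms relative to the window start. Unactivated nodes are `NA`.
#'
#' @slot medium `"tissue"` or `"network"`.
#' @slot at Numeric vector of activation times (NA = unactivated).
#' @slot ids Integer node ids aligned with `at` (tissue: grid index;
#'   network: network node id), so maps over different node subsets — e.g.
#'   a mesh network and its pruned tree — compare on their shared ids.
#' @slot t0 Beat reference time (ms, absolute).
#' @export
setClass("ActivationMap",
  representation(medium = "character", at = "numeric", ids = "integer",
                 t0 = "numeric")
)

setValidity("ActivationMap", function(object) {
  msg <- character()
  if (any(object@at < 0, na.rm = TRUE)) msg <- c(msg, "activation times must be >= 0")
  if (length(object@ids) != length(object@at))
    msg <- c(msg, "ids and at must have equal length")
  if (length(msg)) msg else TRUE
})

#' Activation-map comparison statistics
#'
#' The map-difference statistics used to compare a variant map `b` against a
#' reference map `a`: relative difference (RD, %), root mean square
#' difference reported as mean +/- sd of per-node absolute differences (ms),
#' Pearson correlation coefficient (CC), and the percent absolute change in
#' total activation time (range max - min).
#'
#' @slot rd,rmsdMean,rmsdSd,cc,pctAbsDeltaTotalAT The statistics.
#' @slot absDiff Per-node |b - a| (ms) over shared activated nodes.
#' @slot nShared Number of nodes activated in both maps.
#' @slot nOnlyA,nOnlyB Nodes activated in exactly one map (excluded).
#' @export
setClass("MapComparison",
  representation(rd = "numeric", rmsdMean = "numeric", rmsdSd = "numeric",
                 cc = "numeric", pctAbsDeltaTotalAT = "numeric",
                 absDiff = "numeric", nShared = "integer",
                 nOnlyA = "integer", nOnlyB = "integer")
)

setValidity("MapComparison", function(object) {
  msg <- character()
  if (is.finite(object@rd) && object@rd < 0) msg <- c(msg, "rd must be >= 0")
  if (is.finite(object@cc) && abs(object@cc) > 1 + 1e-12) msg <- c(msg, "cc must lie in [-1, 1]")
  if (is.finite(object@pctAbsDeltaTotalAT) && object@pctAbsDeltaTotalAT < 0)
    msg <- c(msg, "pctAbsDeltaTotalAT must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Reentry detection report
#'
#' @slot induced Reentry of at least two full rotations was observed (some
#'   node in either medium re-activated at least twice after the final
#'   stimulus).
#' @slot rotations Maximum per-node activation count after the final
#'   stimulus, minus one.
#' @slot durationS Time (s) from the final stimulus to the last activation
#'   event, capped by the observation window.
#' @slot terminated Activity ceased before the observation window ended.
#' @slot windowCiFirst,windowCiLast First (largest) and last (smallest)
#'   reentrant S2 coupling interval (ms); `NA` outside a scan context.
#' @export
setClass("ReentryReport",
  representation(induced = "logical", rotations = "integer",
                 durationS = "numeric", terminated = "logical",
                 windowCiFirst = "numeric", windowCiLast = "numeric"),
  prototype(windowCiFirst = NA_real_, windowCiLast = NA_real_)
)

setValidity("ReentryReport", function(object) {
  if (object@induced && object@rotations < 2L)
    "induced reentry requires >= 2 rotations" else TRUE
})

#' Diastolic threshold search result
#'
#' @slot threshold Lowest tested amplitude that captured (stimulus
#'   current-density units, 1/ms).
#' @slot searchTrace `data.frame(amplitude, captured)` of the linear scan.
#' @export
setClass("ThresholdResult",
  representation(threshold = "numeric", searchTrace = "data.frame")
)

setValidity("ThresholdResult", function(object) {
  st <- object@searchTrace
  if (nrow(st) && !st$captured[nrow(st)]) "last tested amplitude must capture" else TRUE
})

#' Synthetic fixture specification
#'
#' Declares the study conditions for a reference coupled model: a sheet with
#' an apicobasal APD gradient (apex at y = 0, base at y = height), a Purkinje
#' network grown over it, PMJs at fixed density, and the Purkinje-myocardium
#' APD gap.
#'
#' @slot name Fixture name.
#' @slot width,height Sheet size (mm).
#' @slot spacing Grid spacing (mm).
#' @slot apdRange Myocardial APD (ms) at apex (y = 0) and base (y = height).
#' @slot purkinjeApdGap Purkinje APD excess over local myocardial APD (ms).
#' @slot pmjDensity PMJs per cm^2 (2D interpretation of the volumetric
#'   density; see the methods vignette).
#' @slot pmjResistance Junctional resistance (Ohm).
#' @slot reconnectionRate Fraction controlling the number of cross-bridge
#'   cables added by the generator.
#' @slot seed RNG seed for network growth and PMJ placement.
#' @export
setClass("FixtureSpec",
  representation(name = "character", width = "numeric", height = "numeric",
                 spacing = "numeric", apdRange = "numeric",
                 purkinjeApdGap = "numeric", pmjDensity = "numeric",
                 pmjResistance = "numeric", reconnectionRate = "numeric",
                 seed = "integer")
)

setValidity("FixtureSpec", function(object) {
  msg <- character()
  if (length(object@apdRange) != 2L || diff(object@apdRange) < 0)
    msg <- c(msg, "apdRange must be (min, max) with max >= min")
  if (object@spacing <= 0 || object@width <= 0 || object@height <= 0)
    msg <- c(msg, "geometry must be positive")
  if (object@pmjDensity <= 0) msg <- c(msg, "pmjDensity must be > 0")
  if (object@pmjResistance <= 0) msg <- c(msg, "pmjResistance must be > 0")
  if (object@reconnectionRate < 0 || object@reconnectionRate > 1)
    msg <- c(msg, "reconnectionRate must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
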
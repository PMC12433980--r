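# Synthetic fixtures: reference coupled models (mesh / tree / no-network)
# sharing one PMJ set, and the 1D ring fixture used as a reentry oracle.

#' Construct a fixture specification
#'
#' Describes a desk-scale sheet + network fixture completely; together with
#' its seed it regenerates byte-identically. The default geometry is a
#' 40 x 40 mm sheet at 0.4 mm resolution (~10^4 nodes) with an apicobasal
#' APD gradient, a Purkinje-vs-myocardium APD gap of 56 ms, and a PMJ
#' density of 15 per cm^2 at the 100 kOhm reference resistance.
#'
#' @param name Fixture name.
#' @param width,height Sheet size (mm).
#' @param spacing Node spacing (mm); must resolve at least 4 nodes per
#'   passive space constant `sqrt(D * tauClose)` at the shortest APD.
#' @param apdRange `c(apdApex, apdBase)` (ms), apex < base.
#' @param purkinjeApdGap Purkinje APD excess over local myocardium (ms).
#' @param pmjDensity PMJs per cm^2.
#' @param pmjResistance Junctional resistance (Ohm).
#' @param reconnectionRate Cross-bridge rate for the mesh variant.
#' @param seed Integer RNG seed.
#' @param D Myocardial diffusivity (mm^2/ms), used for the resolution check.
#' @return A [FixtureSpec-class].
#' @export
fixtureSpec <- function(name = "reference", width = 40, height = 40,
                        spacing = 0.4, apdRange = c(120, 175),
                        purkinjeApdGap = 56, pmjDensity = 15,
                        pmjResistance = 1e5, reconnectionRate = 0.3,
                        seed = 20240601L, D = 0.1) {
  spec <- new("FixtureSpec", name = name, width = width, height = height,
              spacing = spacing, apdRange = as.numeric(apdRange),
              purkinjeApdGap = purkinjeApdGap, pmjDensity = pmjDensity,
              pmjResistance = pmjResistance,
              reconnectionRate = reconnectionRate, seed = as.integer(seed))
  # resolution invariant: >= 4 nodes per space constant at the fastest-
  # repolarizing (shortest-APD) end of the gradient
  m <- apdToTauCloseMap(apdRange[1], apdRange[2])
  lambda <- sqrt(D * m(min(apdRange)))
  if (lambda / spacing < 4)
    stop(sprintf(
      "spacing %.3g mm resolves only %.1f nodes per space constant (%.2f mm); at least 4 are required",
      spacing, lambda / spacing, lambda))
  spec
}

#' Build a reference coupled fixture
#'
#' Realizes one of the three study cases from a [FixtureSpec-class]: the
#' reconnected network (`"mesh"`), its pruned variant (`"tree"`, same major
#' fascicles and the identical PMJ set), or the homogeneous-connectivity
#' no-network analog (`"none"`, the bare sheet). The myocardial APD
#' parameter field varies linearly along the apicobasal (y) axis; each
#' Purkinje node's membrane is calibrated to the myocardial APD at its
#' location plus the spec's APD gap.
#'
#' @param spec A [FixtureSpec-class].
#' @param topology `"mesh"`, `"tree"` or `"none"`.
#' @param D Myocardial diffusivity (mm^2/ms).
#' @param purkinjeD Purkinje cable diffusivity (mm^2/ms).
#' @param dt Macro time step (ms).
#' @param couplGainNet,couplGainMyo PMJ coupling gains (see
#'   [coupledModel()]).
#' @param cl Calibration cycle length (ms).
#' @return A [CoupledModel-class] (with `network = NULL` for `"none"`).
#' @export
buildFixture <- function(spec, topology = c("mesh", "tree", "none"),
                         D = 0.1, purkinjeD = 1.2, dt = 0.05,
                         couplGainNet = 1.5, couplGainMyo = 0.8, cl = 750) {
  topology <- match.arg(topology)
  validObject(spec)
  domain <- tissueDomain(spec@width, spec@height, spacing = spec@spacing,
                         D = D, apdRange = spec@apdRange, cl = cl)
  if (topology == "none")
    return(coupledModel(domain = domain, dt = dt))
  mesh <- generateNetwork(domain, reconnectionRate = spec@reconnectionRate,
                          seed = spec@seed)
  pmjs <- placePMJs(mesh, domain, density = spec@pmjDensity,
                    resistance = spec@pmjResistance, seed = spec@seed + 1L)
  net <- if (topology == "tree") pruneReconnections(mesh) else mesh
  coupledModel(domain, net, pmjs,
               purkinjeMembrane = .purkinjeFieldFor(net, domain, spec, cl),
               purkinjeD = purkinjeD, dt = dt,
               couplGainNet = couplGainNet, couplGainMyo = couplGainMyo)
}

# per-network-node membrane: local myocardial APD target + the spec's gap,
# mapped back to tauClose with the calibration interpolant
.purkinjeFieldFor <- function(net, domain, spec, cl = 750) {
  base <- membraneParams()
  lo <- spec@apdRange[1] + spec@purkinjeApdGap
  hi <- spec@apdRange[2] + spec@purkinjeApdGap
  m <- apdToTauCloseMap(lo, hi, base = base, cl = cl)
  sz <- .domainSize(domain)
  yFrac <- pmin(1, pmax(0, net@nodes$y / sz["h"]))
  localApd <- spec@apdRange[1] + yFrac * diff(spec@apdRange)
  nn <- nrow(net@nodes)
  list(tauIn = rep(base@tauIn, nn), tauOut = rep(base@tauOut, nn),
       tauOpen = rep(base@tauOpen, nn),
       tauClose = as.numeric(m(localApd + spec@purkinjeApdGap)))
}

#' Build the three-case fixture set
#'
#' Generates the mesh fixture once and derives the tree (pruned, identical
#' PMJ set) and no-network cases from the same spec, mirroring the
#' experimental design of comparing the same heart with and without distal
#' Purkinje reconnections and without a conduction system.
#'
#' @inheritParams buildFixture
#' @param ... Passed to [buildFixture()].
#' @return Named list of [CoupledModel-class]: `mesh`, `tree`, `none`.
#' @export
buildFixtureSet <- function(spec, ...) {
  mesh <- buildFixture(spec, "mesh", ...)
  tree <- mesh
  tree@network <- pruneReconnections(mesh@network)
  # rebuild through the constructor so edge tables / stability subcycling
  # are recomputed for the pruned network
  tree <- coupledModel(mesh@domain, tree@network, mesh@pmjs,
                       purkinjeMembrane = .purkinjeFieldFor(
                         tree@network, mesh@domain, spec),
                       purkinjeD = 1.2, dt = mesh@dt,
                       couplGainNet = mesh@couplGainNet,
                       couplGainMyo = mesh@couplGainMyo)
  list(mesh = mesh, tree = tree, none = buildFixture(spec, "none", ...))
}

#' Build the 1D ring fixture (reentry oracle)
#'
#' A closed loop of Purkinje cable supporting circus-movement reentry with
#' an analytic transit time `loopLength / CV`. With `unidirectional = TRUE`
#' the ring is initialized with a self-consistent traveling-pulse snapshot
#' taken from a straight-cable simulation of the same membrane, spacing and
#' diffusivity: the pulse's own refractory tail is the functional block
#' segment, so the wave circulates in one direction only. (A static
#' refractory arc cannot produce unidirectional block here: the recovery
#' gate reopens within a few tens of ms while the neighbouring plateau
#' persists for a full APD, so a short arc is always re-excited.) With
#' `unidirectional = FALSE` the ring starts at rest and the `t = 0` node-1
#' stimulus of [runRingReentry()] launches two fronts that collide — the
#' symmetric control. If the loop is shorter than the reentry wavelength
#' (APD x CV, see [ringWavelength()]), circulation self-terminates; a
#' warning flags this at build time.
#'
#' @param loopLength Loop perimeter (mm).
#' @param unidirectional Initialize with a circulating pulse (`TRUE`) or at
#'   rest for the bidirectional collision control (`FALSE`).
#' @param spacing Node spacing along the loop (mm).
#' @param membrane A [MembraneParams-class] for the loop.
#' @param D Cable diffusivity (mm^2/ms).
#' @param dt Macro time step (ms).
#' @param warnWavelength Check the wavelength criterion (costs one short
#'   cable simulation) and warn when the loop cannot sustain reentry.
#' @return A [CoupledModel-class] (network only).
#' @export
buildRingFixture <- function(loopLength = 300, unidirectional = TRUE,
                             spacing = 0.25, membrane = membraneParams(),
                             D = 0.6, dt = 0.05, warnWavelength = TRUE) {
  n <- as.integer(round(loopLength / spacing))
  if (n < 8L) stop("loop too short to discretize (needs >= 8 nodes)")
  r <- loopLength / (2 * pi)
  th <- 2 * pi * (seq_len(n) - 1L) / n
  nodes <- data.frame(id = seq_len(n), x = r * cos(th), y = r * sin(th),
                      z = 0,
                      role = c("his_root", rep("internal", n - 1L)))
  edges <- data.frame(from = seq_len(n), to = c(seq_len(n)[-1], 1L),
                      cable = 1L, length = loopLength / n)
  cables <- data.frame(id = 1L, proximal = NA_integer_, cvScale = 1,
                       kind = "ring")
  ring <- new("PurkinjeNetwork", nodes = nodes, edges = edges,
              cables = cables, topologyMode = "tree")
  model <- coupledModel(network = ring, purkinjeMembrane = membrane,
                        purkinjeD = D, dt = dt)
  if (unidirectional) {
    # straight cable with the identical discretization: its node-for-node
    # state at the snapshot time is a valid ring state carrying one
    # forward-moving pulse (front at ~3/4 of the loop, tail behind it)
    cableNodes <- nodes; cableNodes$role <- c("his_root",
                                              rep("internal", n - 1L))
    cable <- new("PurkinjeNetwork", nodes = cableNodes,
                 edges = edges[-n, , drop = FALSE], cables = cables,
                 topologyMode = "tree")
    cm <- coupledModel(network = cable, purkinjeMembrane = membrane,
                       purkinjeD = D, dt = dt)
    stim <- new("StimulusEvent", medium = "network", nodes = 1:4,
                onset = 0, duration = 2, amplitude = 0.8)
    tSnap <- 0.75 * loopLength / ringCV(model)
    snap <- runSimulation(cm, list(stim), tEnd = tSnap)
    model@state$vN <- snap@finalModel@state$vN
    model@state$hN <- snap@finalModel@state$hN
  }
  if (warnWavelength && loopLength < ringWavelength(model))
    warning(sprintf(
      "loop (%g mm) is shorter than the reentry wavelength (%.1f mm); circulation will self-terminate",
      loopLength, ringWavelength(model)))
  model
}

#' Reentry wavelength of a ring fixture
#'
#' APD x CV for the ring's membrane and cable discretization; `ringCV`
#' gives the conduction velocity alone (mm/ms). The CV is measured on a
#' straight cable with the identical spacing and diffusivity, whose
#' discrete update equals the ring's.
#'
#' @param model A ring [CoupledModel-class] from [buildRingFixture()].
#' @return Wavelength (mm) / conduction velocity (mm/ms).
#' @export
ringWavelength <- function(model) {
  p <- .ringMembrane(model)
  singleCellAPD(p, cl = 750) * ringCV(model)
}

#' @rdname ringWavelength
#' @export
ringCV <- function(model) {
  p <- .ringMembrane(model)
  h <- model@network@edges$length[1]
  Deff <- model@netEdges$ew[1] * h^2
  measureCableCV(p, D = Deff, lengthMm = 30, spacing = h, dt = model@dt)
}

.ringMembrane <- function(model) {
  membraneParams(tauIn = model@netParams$tauIn[1],
                 tauOut = model@netParams$tauOut[1],
                 tauOpen = model@netParams$tauOpen[1],
                 tauClose = model@netParams$tauClose[1],
                 vGate = model@vGate)
}

#' Run the ring-reentry experiment
#'
#' Observes circulation on a ring fixture. A ring carrying a preloaded
#' pulse (unidirectional build) is left alone; a resting ring (the
#' symmetric control) is stimulated at node 1 at `t = 0`, launching two
#' colliding fronts. With the circulating pulse the analytic expectation is
#' `rotations = floor(tEnd / (loopLength / CV))` when the loop exceeds the
#' wavelength.
#'
#' @param model A ring [CoupledModel-class].
#' @param tEnd Observation end (ms).
#' @param amplitude Stimulus amplitude (1/ms) for the resting control.
#' @return List with `trace`, `report` ([ReentryReport-class]) and
#'   `transitMs` (analytic loop transit time).
#' @export
runRingReentry <- function(model, tEnd = 2000, amplitude = 0.8) {
  stims <- if (max(model@state$vN) < 0.05) {
    list(new("StimulusEvent", medium = "network", nodes = 1:4,
             onset = 0, duration = 2, amplitude = amplitude))
  } else list()
  gap <- .quiesceGap(model)
  tr <- runSimulation(model, stims, tEnd = tEnd, quiesceGap = gap)
  loopLength <- sum(model@network@edges$length)
  list(trace = tr,
       report = detectReentry(tr@events, finalStimTime = 0,
                              observeEnd = tr@t1, quiesceGap = gap),
       transitMs = loopLength / ringCV(model))
}
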
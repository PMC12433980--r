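# Coupled monodomain / cable solver: model assembly and the R-facing
# simulation driver over the compiled core. Operator splitting per macro
# step: membrane reaction + stimulus + PMJ exchange, then an explicit
# diffusion substep, sub-cycled automatically to respect the stability
# bound. The default macro step is 50 us.

#' Construct a tissue domain
#'
#' Builds a structured sheet (1 row gives a 1D cable) with homogeneous
#' membrane parameters, optionally painting an apicobasal APD gradient along
#' the y axis by calibrating `tauClose` per node.
#'
#' @param width,height Sheet size (mm); `height = 0` gives a 1D cable.
#' @param spacing Node spacing (mm).
#' @param D Diffusivity (mm^2/ms), scalar or per node.
#' @param membrane A [MembraneParams-class] template.
#' @param apdRange Optional `c(apdApex, apdBase)` (ms): APD varies linearly
#'   along y from apex (y = 0) to base; requires a calibration at the given
#'   `cl`.
#' @param cl Pacing cycle length (ms) used for the APD calibration.
#' @return A [TissueDomain-class].
#' @export
tissueDomain <- function(width, height = 0, spacing = 0.4, D = 0.1,
                         membrane = membraneParams(), apdRange = NULL,
                         cl = 750) {
  nx <- as.integer(round(width / spacing)) + 1L
  ny <- as.integer(round(height / spacing)) + 1L
  nt <- nx * ny
  tauClose <- rep(membrane@tauClose, nt)
  apdTarget <- NULL
  if (!is.null(apdRange)) {
    m <- apdToTauCloseMap(apdRange[1], apdRange[2], base = membrane, cl = cl)
    yFrac <- rep(seq_len(ny) - 1L, each = nx) / max(1L, ny - 1L)
    apdTarget <- apdRange[1] + yFrac * (apdRange[2] - apdRange[1])
    tauClose <- m(apdTarget)
  }
  new("TissueDomain", nx = nx, ny = ny, spacing = spacing,
      tauIn = rep(membrane@tauIn, nt), tauOut = rep(membrane@tauOut, nt),
      tauOpen = rep(membrane@tauOpen, nt), tauClose = tauClose,
      D = rep(D, length.out = nt), vGate = membrane@vGate,
      vRest = membrane@vRest, vPeak = membrane@vPeak, apdTarget = apdTarget)
}

#' Node coordinates of a tissue domain
#'
#' @param domain A [TissueDomain-class].
#' @return `data.frame(node, x, y)` in solver (row-major, x fastest) order.
#' @export
tissueCoords <- function(domain) {
  data.frame(
    node = seq_len(domain@nx * domain@ny),
    x = rep(seq_len(domain@nx) - 1L, times = domain@ny) * domain@spacing,
    y = rep(seq_len(domain@ny) - 1L, each = domain@nx) * domain@spacing)
}

#' Assemble a coupled simulation model
#'
#' Wires a tissue domain, a Purkinje network and a PMJ set into a simulable
#' unit, precomputing the network cable discretization (the generator's
#' segment nodes are the 1D grid) and the diffusion-stability subcycling.
#' Either medium may be omitted.
#'
#' @param domain A [TissueDomain-class] or `NULL`.
#' @param network A [PurkinjeNetwork-class] or `NULL`.
#' @param pmjs A [PMJSet-class] or `NULL`.
#' @param purkinjeMembrane A [MembraneParams-class] for the network, or a
#'   list of per-node vectors `tauIn`, `tauOut`, `tauOpen`, `tauClose`
#'   (solver node order = network node-table order).
#' @param purkinjeD Cable diffusivity (mm^2/ms); multiplied by the square of
#'   each cable's `cvScale` (CV scales as the square root of D).
#' @param dt Macro time step (ms), default 0.05 (50 us).
#' @param couplGainNet,couplGainMyo Junctional coupling gains (1/ms) at the
#'   100 kOhm reference resistance, scaled per PMJ by `1e5 / resistance`.
#' @return A [CoupledModel-class] at rest, time 0.
#' @export
coupledModel <- function(domain = NULL, network = NULL, pmjs = NULL,
                         purkinjeMembrane = membraneParams(),
                         purkinjeD = 1.2, dt = 0.05,
                         couplGainNet = 1.5, couplGainMyo = 0.8) {
  nt <- if (is.null(domain)) 0L else domain@nx * domain@ny
  netIndex <- integer()
  netEdges <- list(efrom = integer(), eto = integer(), ew = numeric())
  netParams <- list(tauIn = numeric(), tauOut = numeric(),
                    tauOpen = numeric(), tauClose = numeric())
  if (!is.null(network)) {
    netIndex <- network@nodes$id
    nn <- length(netIndex)
    ef <- match(network@edges$from, netIndex) - 1L
    et <- match(network@edges$to, netIndex) - 1L
    cvs <- network@cables$cvScale[match(network@edges$cable, network@cables$id)]
    ew <- purkinjeD * cvs^2 / pmax(network@edges$length, 1e-6)^2
    netEdges <- list(efrom = ef, eto = et, ew = ew)
    if (is(purkinjeMembrane, "MembraneParams"))
      netParams <- list(tauIn = rep(purkinjeMembrane@tauIn, nn),
                        tauOut = rep(purkinjeMembrane@tauOut, nn),
                        tauOpen = rep(purkinjeMembrane@tauOpen, nn),
                        tauClose = rep(purkinjeMembrane@tauClose, nn))
    else
      netParams <- lapply(
        purkinjeMembrane[c("tauIn", "tauOut", "tauOpen", "tauClose")],
        rep, length.out = nn)
  }
  vg <- if (!is.null(domain)) domain@vGate else
    if (is(purkinjeMembrane, "MembraneParams")) purkinjeMembrane@vGate else 0.13
  vr <- if (!is.null(domain)) domain@vRest else -85
  vp <- if (!is.null(domain)) domain@vPeak else 25

  # diffusion stability: dt_sub * (max node coupling rate) <= 0.8
  maxRate <- 0
  if (!is.null(domain) && nt > 1L)
    maxRate <- max(maxRate, 4 * max(domain@D) / domain@spacing^2)
  if (length(netEdges$ew)) {
    rates <- numeric(length(netIndex))
    for (k in seq_along(netEdges$ew)) {
      rates[netEdges$efrom[k] + 1L] <- rates[netEdges$efrom[k] + 1L] + netEdges$ew[k]
      rates[netEdges$eto[k] + 1L] <- rates[netEdges$eto[k] + 1L] + netEdges$ew[k]
    }
    maxRate <- max(maxRate, max(rates))
  }
  nsub <- max(1L, as.integer(ceiling(dt * maxRate / 0.8)))

  m <- new("CoupledModel", domain = domain, network = network, pmjs = pmjs,
           netIndex = as.integer(netIndex), netEdges = netEdges,
           netParams = netParams,
           state = list(vT = numeric(nt), hT = rep(1, nt),
                        vN = numeric(length(netIndex)),
                        hN = rep(1, length(netIndex))),
           time = 0, dt = dt, nsub = nsub,
           couplGainNet = couplGainNet, couplGainMyo = couplGainMyo,
           vGate = vg, vRest = vr, vPeak = vp)
  validObject(m)
  m
}

#' Reset a model to the resting state at time zero
#'
#' @param model A [CoupledModel-class].
#' @return The model at rest.
#' @export
resetState <- function(model) {
  model@state <- list(vT = numeric(length(model@state$vT)),
                      hT = rep(1, length(model@state$hT)),
                      vN = numeric(length(model@state$vN)),
                      hN = rep(1, length(model@state$hN)))
  model@time <- 0
  model
}

#' Stimulus constructors
#'
#' `sphereStimulus` targets tissue nodes within a spherical (here circular)
#' region; `lineStimulus` targets tissue nodes within `diameter/2` of a
#' segment; `hisStimulus` targets the His root and the proximal cable nodes
#' within 2 mm of it.
#'
#' @param model A [CoupledModel-class].
#' @param center,from,to Coordinates (mm).
#' @param diameter Electrode diameter (mm).
#' @param onset,duration Timing (ms).
#' @param amplitude Injected dv/dt (1/ms).
#' @return A [StimulusEvent-class].
#' @export
sphereStimulus <- function(model, center, diameter = 1.5, onset = 0,
                           duration = 2, amplitude = 0.5) {
  co <- tissueCoords(model@domain)
  d2 <- (co$x - center[1])^2 + (co$y - center[2])^2
  nodes <- which(d2 <= (diameter / 2)^2)
  if (!length(nodes)) nodes <- which.min(d2)
  new("StimulusEvent", medium = "tissue", nodes = as.integer(nodes),
      onset = onset, duration = duration, amplitude = amplitude)
}

#' @rdname sphereStimulus
#' @export
lineStimulus <- function(model, from, to, diameter = 2, onset = 0,
                         duration = 2, amplitude = 0.5) {
  co <- tissueCoords(model@domain)
  ab <- c(to[1] - from[1], to[2] - from[2])
  len2 <- sum(ab^2)
  tpar <- pmin(1, pmax(0, ((co$x - from[1]) * ab[1] + (co$y - from[2]) * ab[2]) / len2))
  d2 <- (co$x - (from[1] + tpar * ab[1]))^2 + (co$y - (from[2] + tpar * ab[2]))^2
  nodes <- which(d2 <= (diameter / 2)^2)
  if (!length(nodes)) stop("line electrode endpoints lie outside the domain")
  new("StimulusEvent", medium = "tissue", nodes = as.integer(nodes),
      onset = onset, duration = duration, amplitude = amplitude)
}

#' @rdname sphereStimulus
#' @export
hisStimulus <- function(model, onset = 0, duration = 2, amplitude = 0.8) {
  if (is.null(model@network)) stop("model has no Purkinje network to pace")
  nd <- model@network@nodes
  root <- which(nd$role == "his_root")
  d2 <- (nd$x - nd$x[root])^2 + (nd$y - nd$y[root])^2
  nodes <- which(d2 <= 4)  # within 2 mm of the His root
  new("StimulusEvent", medium = "network", nodes = as.integer(nodes),
      onset = onset, duration = duration, amplitude = amplitude)
}

.packStimuli <- function(stimuli) {
  if (!length(stimuli))
    return(list(spec = matrix(0, 0, 4), ptr = 0L, idx = integer()))
  spec <- t(vapply(stimuli, function(s)
    c(s@onset, s@duration, s@amplitude, if (s@medium == "tissue") 0 else 1),
    numeric(4)))
  idx <- unlist(lapply(stimuli, function(s) s@nodes - 1L))
  ptr <- c(0L, cumsum(vapply(stimuli, function(s) length(s@nodes), 1L)))
  list(spec = spec, ptr = as.integer(ptr), idx = as.integer(idx))
}

.packPmjs <- function(model) {
  p <- model@pmjs
  if (is.null(p))
    return(list(term = integer(), fptr = 0L, fidx = integer(),
                g_net = numeric(), g_myo = numeric()))
  term <- match(p@terminal, model@netIndex) - 1L
  fidx <- unlist(p@footprint) - 1L
  fptr <- c(0L, cumsum(vapply(p@footprint, length, 1L)))
  scale <- 1e5 / p@resistance
  list(term = as.integer(term), fptr = as.integer(fptr),
       fidx = as.integer(fidx),
       g_net = model@couplGainNet * scale,
       g_myo = model@couplGainMyo * scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a simulation
#'
#' Advances the model to `tEnd` under a stimulus protocol, recording
#' interpolated -10 mV threshold crossings for every node of both media.
#' Fully deterministic for fixed inputs and `dt`.
#'
#' @param model A [CoupledModel-class].
#' @param stimuli List of [StimulusEvent-class] objects (absolute onsets).
#' @param tEnd Absolute end time (ms); must exceed the model time.
#' @param quiesceGap If > 0, stop early once no activation event has
#'   occurred for this many ms after the last stimulus ended.
#' @param reaction Integrate membrane kinetics (set `FALSE` for
#'   diffusion-only runs, e.g. solver verification).
#' @param probes Optional list with `tissue` and/or `network` node indices
#'   whose transmembrane variable is sampled every `probeEvery` steps.
#' @param probeEvery Sampling stride (steps) for probes.
#' @return A [SimulationTrace-class]; `finalModel` carries the advanced
#'   state so protocols can be chained.
#' @export
runSimulation <- function(model, stimuli = list(), tEnd,
                          quiesceGap = 0, reaction = TRUE, probes = NULL,
                          probeEvery = 10L) {
  stopifnot(tEnd > model@time)
  d <- model@domain
  tissue <- list(
    nx = if (is.null(d)) 0L else d@nx, ny = if (is.null(d)) 0L else d@ny,
    h = if (is.null(d)) 1 else d@spacing,
    v = model@state$vT, h_gate = model@state$hT,
    D = if (is.null(d)) numeric() else d@D,
    tau_in = if (is.null(d)) numeric() else d@tauIn,
    tau_out = if (is.null(d)) numeric() else d@tauOut,
    tau_open = if (is.null(d)) numeric() else d@tauOpen,
    tau_close = if (is.null(d)) numeric() else d@tauClose)
  net <- list(n = length(model@netIndex), v = model@state$vN,
              h_gate = model@state$hN,
              efrom = model@netEdges$efrom, eto = model@netEdges$eto,
              ew = model@netEdges$ew,
              tau_in = model@netParams$tauIn, tau_out = model@netParams$tauOut,
              tau_open = model@netParams$tauOpen,
              tau_close = model@netParams$tauClose)
  ctrl <- list(t0 = model@time, t_end = tEnd, dt = model@dt,
               nsub = model@nsub, vth = .vth(model@vRest, model@vPeak),
               vgate = model@vGate, reaction = reaction,
               quiesce_gap = quiesceGap, diverge_bound = 50,
               probe_t = as.integer((probes$tissue %||% integer()) - 1L),
               probe_n = as.integer((probes$network %||% integer()) - 1L),
               probe_every = as.integer(probeEvery))
  res <- .simCore(tissue, net, .packPmjs(model), .packStimuli(stimuli), ctrl)
  out <- model
  out@state <- list(vT = res$vT, hT = res$hT, vN = res$vN, hN = res$hN)
  out@time <- res$t_stop
  ev <- res$events
  ev$medium <- ifelse(ev$medium == 0L, "tissue", "network")
  ev$node <- ev$node + 1L
  new("SimulationTrace", events = ev, t0 = model@time, t1 = res$t_stop,
      stopped = res$stopped, finalModel = out,
      probes = if (is.null(res$probes)) NULL else res$probes)
}

#' Advance a model by a single macro time step
#'
#' @param model A [CoupledModel-class].
#' @param stimuli Active stimulus events.
#' @return The model advanced by `dt`.
#' @export
stepModel <- function(model, stimuli = list()) {
  runSimulation(model, stimuli, tEnd = model@time + model@dt)@finalModel
}

#' PMJ transmission delay
#'
#' Measures the junctional conduction delay of one PMJ from a trace:
#' anterograde delay is the footprint-mean tissue activation time minus the
#' terminal activation time; retrograde is the reverse. A failure to
#' transmit (no activation on the receiving side within the window) is a
#' distinguished no-conduction outcome reported as `NA`, not an error.
#'
#' @param model A [CoupledModel-class] with PMJs.
#' @param trace A [SimulationTrace-class] containing one junction crossing.
#' @param pmj Index of the PMJ in the model's PMJ set.
#' @param direction `"anterograde"` (Purkinje to muscle) or `"retrograde"`.
#' @param window Time window (ms) to search; defaults to the whole trace.
#' @return Delay in ms, or `NA` for no conduction.
#' @export
pmjTransmissionDelay <- function(model, trace, pmj,
                                 direction = c("anterograde", "retrograde"),
                                 window = c(trace@t0, trace@t1)) {
  direction <- match.arg(direction)
  termSolver <- match(model@pmjs@terminal[pmj], model@netIndex)
  foot <- model@pmjs@footprint[[pmj]]
  ev <- trace@events
  ev <- ev[ev$dir == 1L & ev$time >= window[1] & ev$time < window[2], ]
  tTerm <- ev$time[ev$medium == "network" & ev$node == termSolver]
  footAt <- vapply(foot, function(n) {
    t <- ev$time[ev$medium == "tissue" & ev$node == n]
    if (length(t)) min(t) else NA_real_
  }, 1)
  if (!length(tTerm) || all(is.na(footAt))) return(NA_real_)
  d <- mean(footAt, na.rm = TRUE) - min(tTerm)
  if (direction == "retrograde") d <- -d
  d
}

#' Measure conduction velocity on a 1D cable
#'
#' Stimulates the left end of a uniform 1D strand and measures CV between
#' 40% and 70% of its length from the activation times -- the convergence
#' oracle for the time-step policy and the transit-time input for ring
#' fixtures.
#'
#' @param membrane A [MembraneParams-class].
#' @param D Diffusivity (mm^2/ms).
#' @param lengthMm Strand length (mm).
#' @param spacing Node spacing (mm).
#' @param dt Macro step (ms).
#' @param cvMin Lower bound (mm/ms) used to size the simulated window.
#' @return CV in mm/ms (`NA` if the wave does not traverse).
#' @export
measureCableCV <- function(membrane, D = 0.1, lengthMm = 30, spacing = 0.1,
                           dt = 0.05, cvMin = 0.05) {
  dom <- tissueDomain(lengthMm, 0, spacing = spacing, D = D, membrane = membrane)
  m <- coupledModel(domain = dom, network = NULL, dt = dt)
  stim <- new("StimulusEvent", medium = "tissue",
              nodes = seq_len(max(2L, round(1 / spacing))), onset = 0,
              duration = 2, amplitude = 0.6)
  tr <- runSimulation(m, list(stim), tEnd = lengthMm / cvMin + 50)
  ev <- tr@events[tr@events$medium == "tissue" & tr@events$dir == 1L, ]
  n1 <- round(0.4 * (dom@nx - 1L)) + 1L
  n2 <- round(0.7 * (dom@nx - 1L)) + 1L
  t1 <- ev$time[ev$node == n1]; t2 <- ev$time[ev$node == n2]
  if (!length(t1) || !length(t2)) return(NA_real_)
  (n2 - n1) * spacing / (min(t2) - min(t1))
}
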
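---
title: "Desk-scale methods: topology, membrane calibration and reentry oracles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-scale methods: topology, membrane calibration and reentry oracles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`purkinet` studies one question at desk scale: how do distal Purkinje fiber
*reconnections* — cross-bridge cables that reunify branches of the conduction
system into a mesh — change anterograde activation, retrograde activation,
and the initiation and maintenance of reentrant arrhythmias? The package
compares three variants of one synthetic heart: the reconnected (*mesh*)
network, its pruned (*tree*) variant sharing the same major fascicles and the
identical set of Purkinje-muscular junctions (PMJs), and a bare sheet without
a conduction system. This vignette documents the design decisions that make
the experiment meaningful on a laptop-sized model, where the physiological
headline numbers of organ-scale simulations are out of reach and only the
qualitative directions can be reproduced.

```{r setup}
library(purkinet)
```

## The coupled model

The myocardium is a 2D monodomain sheet: a reaction–diffusion equation for a
dimensionless transmembrane variable $v \in [0, 1]$, integrated by operator
splitting (explicit subcycled diffusion, exact-exponential gate update). The
Purkinje network is a 1D cable graph over the same equations with a faster
diffusivity. The two media talk only through PMJs, modeled as lumped
resistors (default $10^5\,\Omega$): the junction current is proportional to
the voltage difference between the terminal node and the unweighted mean of
its myocardial footprint, mapped through an affine voltage scale
($v = 0 \mapsto -85$ mV, $v = 1 \mapsto 25$ mV) so that the $-10$ mV
activation threshold is well defined in both media.

The membrane is the two-variable Mitchell–Schaeffer model. Its four time
constants are the levers the rest of this vignette is about:

```{r}
membraneParams()
```

## Why `tauOpen = 35` ms

`tauOpen` sets how fast the recovery gate reopens after repolarization, i.e.
the *post-repolarization refractoriness* — the gap between the action
potential duration (APD) and the shortest interval at which a second wave
can propagate. This single number decides whether the experiment works at
desk scale:

* Too slow (e.g. 80 ms): the refractory period extends ~110 ms past the APD.
  A premature wave then creeps along behind the recovery front and never
  blocks unidirectionally, so no S2 ever induces reentry — in any topology.
* Too fast (e.g. 20 ms): the refractory gap (~30 ms) falls below the 56 ms
  Purkinje-vs-myocardium APD gap. Every PMJ then becomes an echo source (the
  myocardium re-excites the Purkinje side as soon as it repolarizes), the
  mesh fixture self-sustains at *every* coupling interval, and even the bare
  sheet reenters — the no-network control stops being a control.
* `tauOpen = 35` ms threads the needle: junctional echo is suppressed
  (refractory gap ≈ the APD gap), the homogeneous sheet cannot be induced,
  and dispersion-based unidirectional block — the actual mechanism under
  study — is available to the network variants.

## APD heterogeneity and the Purkinje APD gap

The sheet carries a linear apicobasal APD gradient (default 120 ms at the
apex to 175 ms at the base at a 750 ms cycle length); every Purkinje node is
calibrated to its *local* myocardial APD plus a fixed 56 ms gap. Calibration
inverts the monotone APD–`tauClose` relation by bracketed bisection; the
bracket is grown only within the monotone regime, because at long `tauClose`
the single-cell map becomes non-monotone (alternans, then 2:1 block) and a
naive bisection would land there silently:

```{r}
p <- calibrateAPD(150, cl = 750)
singleCellAPD(p, cl = 750)
```

Restitution is deliberately flat between the two pacing cycle lengths used
by the protocols (600 and 750 ms; diastolic intervals far exceed `tauOpen`),
so anterograde/retrograde map differences measure topology, not rate.

## Network generation, bridges and pruning

The generator grows a fascicle scaffold and a binary branching tree (8
generations, 256 terminals), then adds *reconnection* cables between nearby
branches at the configured rate. Two structural rules matter:

* **Depth-matched bridges.** Candidate bridge endpoints must have similar
  conduction depth from the His root (`bridgeDepthTol`, default 5 mm of
  path length). Depth-matched bridges barely perturb the anterograde
  wavefront — both ends activate nearly simultaneously — while still acting
  as retrograde shortcuts. This reproduces the study's signature asymmetry:
  anterograde activation is nearly invariant to pruning, retrograde
  activation is not.
* **Prune = remove the later parent.** At each reunification node the cable
  with the larger identifier is detached and walked back to its origin,
  stopping at nodes still serving other cables; PMJ terminals are never
  removed. The result satisfies tree invariants (in-degree ≤ 1, full root
  reachability, identical PMJ set) and is idempotent — properties enforced
  against an independent `igraph` traversal oracle in the test suite.

## The ring fixture: an analytic reentry oracle

Reentry detection ("some node re-activates at least twice after the final
stimulus") is validated against a 1D loop whose behaviour is known in closed
form: a pulse circulating on a ring of length $L$ rotates every $L /
\mathrm{CV}$ milliseconds.

A subtlety worth recording: a *static* refractory arc cannot create the
required unidirectional block in this membrane. The gate recovers to the
propagation threshold within ~8 ms of an `h = 0` initialization, while the
neighbouring stimulated plateau persists for a full APD, so a short arc is
always re-excited antidromically and the two fronts collide. The fixture
therefore injects a *self-consistent traveling pulse*: a straight cable with
the identical discretization is stimulated at one end, its state is
snapshotted when the front reaches three quarters of the loop length, and
that state is wrapped onto the ring. The pulse's own refractory tail — with
the wavelength-scale spatial extent a real waveback has — is the functional
block segment.

```{r, eval = FALSE}
p <- calibrateAPD(100, cl = 750)
m <- buildRingFixture(loopLength = 280, membrane = p, D = 0.6)
r <- runRingReentry(m, tEnd = 2000)
c(analytic = floor(2000 / r$transitMs), observed = r$report@rotations)
```

Rings shorter than the wavelength $\mathrm{APD} \times \mathrm{CV}$ warn at
build time and observably self-terminate; the symmetric control
(`unidirectional = FALSE`) launches two fronts that collide and die.

## Protocols

All protocols start from the diastolic threshold, found by a linear
amplitude scan (capture = an activation beyond two space constants of the
electrode within 50 ms of stimulus end) and re-run for every new model:

* **His pacing** (750 ms × 10): anterograde maps, last beat only.
* **Apical S1 pacing** (600 ms × 10, 2× threshold, 1.5 mm electrode):
  retrograde maps.
* **S1S2 scan** (S2 from 400 ms coupling interval in 10 ms decrements until
  loss of capture): the post-drive state is saved once, so each coupling
  interval is a single-beat continuation; outcomes are classified
  `no_capture` / `capture_no_reentry` / `reentry` and summarized as the
  vulnerable window.
* **Line pacing** (400 ms × 10 then 250 ms × 10 at 8× threshold along the
  mid-domain apicobasal line): the maintenance protocol; reentry duration is
  reported with a 20 s observation cap.

On the shipped reference fixture these reproduce the study's qualitative
findings: mesh-vs-tree anterograde myocardial maps correlate at ≥ 0.99 while
retrograde total activation time is distinctly longer in the tree; the
no-network sheet has an empty vulnerable window while mesh and tree have
overlapping contiguous windows; and reentry after line pacing survives
longest on the mesh. The acceptance suite
(`tests/testthat/test-acceptance.R`) asserts exactly these directions.

## Determinism

Every fixture regenerates byte-identically from its spec and seed; network
generation uses an isolated RNG stream so callers' randomness is untouched;
run manifests record the config hash, seed, `dt` and package version, and
re-running a manifest reproduces output files hash-for-hash.
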
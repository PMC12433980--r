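# Fixture construction: spec validation, the three-case set, the
# Purkinje-over-myocardium APD invariant, determinism, gradient calibration,
# and ring-fixture construction errors.

test_that("fixtureSpec validates its fields", {
  expect_error(fixtureSpec(apdRange = c(200, 150)), "apdRange")
  expect_error(fixtureSpec(pmjDensity = 0), "pmjDensity")
  expect_error(fixtureSpec(reconnectionRate = 1.5), "reconnectionRate")
  # coarse resolution vs space constant
  expect_error(fixtureSpec(spacing = 2.5), "space constant")
})

test_that("mesh and tree variants share the identical PMJ set", {
  spec <- fixtureSpec(width = 24, height = 24)
  fs <- buildFixtureSet(spec)
  expect_identical(fs$mesh@pmjs, fs$tree@pmjs)
  expect_equal(fs$mesh@network@topologyMode, "mesh")
  expect_equal(fs$tree@network@topologyMode, "tree")
  expect_null(fs$none@network)
  # tree is the pruned mesh
  expect_identical(fs$tree@network, pruneReconnections(fs$mesh@network))
  # all three share the same tissue domain
  expect_identical(fs$mesh@domain, fs$none@domain)
})

test_that("Purkinje APD parameter exceeds local myocardial APD everywhere", {
  spec <- fixtureSpec(width = 24, height = 24)
  m <- buildFixture(spec, "mesh")
  # tauClose is monotone in APD, so the +56 ms gap implies strictly larger
  # tauClose than any myocardial node at the same y
  d <- m@domain
  yNet <- m@network@nodes$y
  co <- tissueCoords(d)
  for (k in seq_len(nrow(m@network@nodes))) {
    near <- which.min((co$x - m@network@nodes$x[k])^2 + (co$y - yNet[k])^2)
    expect_gt(m@netParams$tauClose[k], d@tauClose[near])
  }
})

test_that("fixtures regenerate byte-identically from (spec, seed)", {
  spec <- fixtureSpec(width = 24, height = 24)
  a <- buildFixture(spec, "mesh")
  b <- buildFixture(spec, "mesh")
  expect_identical(a, b)
  spec2 <- fixtureSpec(width = 24, height = 24, seed = spec@seed + 1L)
  expect_false(identical(buildFixture(spec2, "mesh")@network, a@network))
})

test_that("gradient (250, 330) calibrates domain-end APDs within 2 ms", {
  d <- tissueDomain(10, 10, spacing = 0.5, apdRange = c(250, 330), cl = 750)
  pApex <- membraneParams(tauClose = d@tauClose[1])
  pBase <- membraneParams(tauClose = d@tauClose[d@nx * d@ny])
  expect_lt(abs(singleCellAPD(pApex, cl = 750) - 250), 2)
  expect_lt(abs(singleCellAPD(pBase, cl = 750) - 330), 2)
})

test_that("ring fixture construction and its guard rails", {
  m <- buildRingFixture(loopLength = 300, unidirectional = TRUE,
                        warnWavelength = FALSE)
  expect_null(m@domain)
  expect_equal(nrow(m@network@edges), nrow(m@network@nodes))  # closed loop
  # the injected pulse: some nodes excited, a refractory tail behind them
  expect_gt(max(m@state$vN), 0.5)
  expect_lt(min(m@state$hN), 0.5)
  expect_error(buildRingFixture(loopLength = 1), "too short")
  expect_warning(buildRingFixture(loopLength = 12, unidirectional = FALSE,
                                  spacing = 0.5),
                 "wavelength")
})

test_that("symmetric ring (no block): two fronts collide, no reentry", {
  m <- buildRingFixture(loopLength = 40, unidirectional = FALSE,
                        spacing = 0.5, warnWavelength = FALSE)
  expect_equal(max(m@state$vN), 0)  # resting control
  r <- runRingReentry(m, tEnd = 600)
  expect_false(r$report@induced)
  expect_true(r$report@terminated)
})
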
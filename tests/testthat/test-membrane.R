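# Membrane kinetics: fixed point, gate bounds, potential mapping, APD
# calibration against the single-cell oracle.

test_that("rest is a fixed point of the reaction step", {
  s <- list(v = c(0, 0), h = c(1, 1))
  out <- reactionStep(s, membraneParams(), iStim = 0, dt = 0.05)
  expect_equal(out$v, c(0, 0))
  expect_equal(out$h, c(1, 1))
})

test_that("gate stays in [0, 1] even for large steps", {
  p <- membraneParams()
  s <- list(v = c(0.01, 0.99), h = c(0.5, 0.5))
  for (dt in c(0.05, 5, 500)) {
    out <- reactionStep(s, p, dt = dt)
    expect_true(all(out$h >= 0 & out$h <= 1))
  }
})

test_that("non-finite state is rejected with the node named", {
  s <- list(v = c(0, NaN, 0), h = c(1, 1, 1))
  expect_error(reactionStep(s, membraneParams()), "node 2")
})

test_that("mV mapping is affine, invertible, and -10 mV sits at 75/110", {
  p <- membraneParams()
  expect_equal(vToMv(0, p), -85)
  expect_equal(vToMv(1, p), 25)
  expect_equal(mvToV(-10, p), 75 / 110)
  v <- seq(0, 1, by = 0.1)
  expect_equal(mvToV(vToMv(v, p), p), v)
})

test_that("single-cell APD grows monotonically with tauClose", {
  apds <- vapply(c(60, 100, 150), function(tc)
    singleCellAPD(membraneParams(tauClose = tc)), 0)
  expect_true(all(diff(apds) > 0))
})

test_that("calibrateAPD hits targets and reports failures", {
  p <- calibrateAPD(150, cl = 750, tol = 1)
  expect_lt(abs(singleCellAPD(p, cl = 750) - 150), 1)
  expect_gte(p@apdExtensionFactor, 1)
  expect_error(calibrateAPD(3, cl = 750), "below the achievable minimum")
  expect_error(calibrateAPD(500, cl = 400), "unreachable")
})

test_that("the linear APD-to-tauClose map interpolates within 2 ms", {
  m <- apdToTauCloseMap(120, 175)
  for (target in c(120, 147.5, 175)) {
    p <- membraneParams(tauClose = m(target))
    expect_lt(abs(singleCellAPD(p, cl = 750) - target), 2)
  }
})

test_that("Purkinje presets prolong APD in the required order", {
  a0 <- singleCellAPD(membranePreset("myocardium"))
  a1 <- singleCellAPD(membranePreset("purkinje_default"))
  a2 <- singleCellAPD(membranePreset("purkinje_arrhythmogenic"))
  expect_true(a0 < a1 && a1 < a2)
  expect_lt(abs((a1 - a0) - 20), 2)
  expect_lt(abs((a2 - a0) - 56), 2)
})

test_that("restitution is flat between cycle lengths 600 and 750 ms", {
  p <- membraneParams()
  a750 <- singleCellAPD(p, cl = 750)
  a600 <- singleCellAPD(p, cl = 600)
  expect_lt(abs(a750 - a600) / a750, 0.02)
})

test_that("validity rejects nonsensical parameters", {
  expect_error(membraneParams(tauIn = -1))
  expect_error(membraneParams(vRest = 0))
})
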
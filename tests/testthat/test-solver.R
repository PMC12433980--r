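# Solver correctness: diffusion against the heat-kernel closed form, flux
# conservation, event-crossing interpolation against an analytic ramp, model
# assembly and stimulus geometry.

test_that("pure diffusion matches the 1D heat kernel", {
  # no-reaction run on a long cable: an initial near-delta spreads as the
  # Green's function of the heat equation; compare profiles at t = 5 ms
  h <- 0.1; D <- 0.1
  d <- tissueDomain(40, 0, spacing = h, D = D)
  m <- coupledModel(domain = d, dt = 0.01)
  n <- d@nx
  mid <- (n + 1L) %/% 2L
  m@state$vT[mid] <- 1 / h  # unit mass
  tr <- runSimulation(m, tEnd = 5, reaction = FALSE)
  v <- tr@finalModel@state$vT
  x <- (seq_len(n) - mid) * h
  ref <- exp(-x^2 / (4 * D * 5)) / sqrt(4 * pi * D * 5)
  expect_lt(max(abs(v - ref)) / max(ref), 0.01)
})

test_that("diffusion conserves total state on a sheet", {
  d <- tissueDomain(10, 10, spacing = 0.5, D = 0.2)
  m <- coupledModel(domain = d, dt = 0.05)
  set.seed(4)
  m@state$vT <- runif(d@nx * d@ny)
  s0 <- sum(m@state$vT)
  tr <- runSimulation(m, tEnd = 20, reaction = FALSE)
  expect_equal(sum(tr@finalModel@state$vT), s0, tolerance = 1e-10)
})

test_that("threshold crossings are linearly interpolated (ramp oracle)", {
  # reaction off, constant stimulus of amplitude a from t=0: v(t) = a t,
  # so the -10 mV crossing (v = 75/110) happens at exactly (75/110)/a
  d <- tissueDomain(1, 0, spacing = 0.5, D = 1e-9)
  m <- coupledModel(domain = d, dt = 0.05)
  a <- 0.123
  stim <- new("StimulusEvent", medium = "tissue", nodes = 1:3,
              onset = 0, duration = 20, amplitude = a)
  tr <- runSimulation(m, list(stim), tEnd = 20, reaction = FALSE)
  up <- tr@events[tr@events$dir == 1L & tr@events$node == 2L, ]
  expect_equal(nrow(up), 1L)
  expect_lt(abs(up$time - (75 / 110) / a), 0.01)
})

test_that("cable CV converges under dt halving (< 2%)", {
  p <- membraneParams()
  cv1 <- measureCableCV(p, dt = 0.05)
  cv2 <- measureCableCV(p, dt = 0.025)
  expect_lt(abs(cv1 - cv2) / cv2, 0.02)
})

test_that("Purkinje cable CV exceeds myocardial CV in shipped presets", {
  cvP <- measureCableCV(membranePreset("purkinje_arrhythmogenic"), D = 1.2)
  cvM <- measureCableCV(membranePreset("myocardium"), D = 0.1)
  expect_gt(cvP, cvM)
})

test_that("model assembly validates media and stability subcycling", {
  expect_error(coupledModel(), "at least one medium")
  d <- tissueDomain(10, 10, spacing = 0.2, D = 0.5)
  m <- coupledModel(domain = d, dt = 0.05)
  # dt_sub * 4 D / h^2 <= 0.8 must hold after subcycling
  expect_lte(m@dt / m@nsub * 4 * max(d@D) / d@spacing^2, 0.8 + 1e-12)
})

test_that("stimulus constructors select the advertised geometry", {
  d <- tissueDomain(20, 20, spacing = 0.5)
  m <- coupledModel(domain = d)
  co <- tissueCoords(d)
  s <- sphereStimulus(m, c(10, 10), diameter = 3)
  expect_true(all((co$x[s@nodes] - 10)^2 + (co$y[s@nodes] - 10)^2 <= 1.5^2))
  l <- lineStimulus(m, c(10, 2), c(10, 18), diameter = 2)
  expect_true(all(abs(co$x[l@nodes] - 10) <= 1))
  expect_error(lineStimulus(m, c(100, 100), c(120, 120)), "outside")
})

test_that("quiescence stops a run early; final state resumes exactly", {
  d <- tissueDomain(10, 0, spacing = 0.5)
  m <- coupledModel(domain = d)
  s <- sphereStimulus(m, c(0, 0), diameter = 1.5, amplitude = 0.5)
  tr <- runSimulation(m, list(s), tEnd = 5000, quiesceGap = 300)
  expect_equal(tr@stopped, "quiescent")
  expect_lt(tr@t1, 5000)
  # split run equals a straight run (deterministic core)
  tr1 <- runSimulation(m, list(s), tEnd = 100)
  tr2 <- runSimulation(tr1@finalModel, tEnd = 200)
  trAll <- runSimulation(m, list(s), tEnd = 200)
  expect_equal(tr2@finalModel@state$vT, trAll@finalModel@state$vT,
               tolerance = 1e-12)
})

test_that("anterograde PMJ delay is positive at every junction", {
  spec <- fixtureSpec()
  m <- buildFixture(spec, "tree")
  his <- hisStimulus(m)
  tr <- runSimulation(m, list(his), tEnd = 250)
  delays <- vapply(seq_along(m@pmjs@terminal), function(k)
    pmjTransmissionDelay(m, tr, k, direction = "anterograde",
                         window = c(0, 250)), 0)
  expect_true(all(is.na(delays) | delays > 0))
  expect_gt(mean(delays, na.rm = TRUE), 0)
  expect_lt(mean(is.na(delays)), 0.05)  # nearly every junction conducts
})
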
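# Protocol drivers on a small bare sheet: diastolic threshold semantics,
# capture bookkeeping, S1 pacing outputs, and the S1S2 scan mechanics.
# Network-coupled physics lives in the acceptance suite.

smallSheet <- function() {
  d <- tissueDomain(12, 12, spacing = 0.5)
  coupledModel(domain = d, dt = 0.05)
}

test_that("diastolic threshold: smallest capturing multiple of the increment", {
  m <- smallSheet()
  site <- sphereStimulus(m, c(6, 0), diameter = 1.5)
  thr <- findDiastolicThreshold(m, site, increment = 0.05)
  st <- thr@searchTrace
  # scan is linear from the increment; only the last amplitude captures
  expect_equal(st$amplitude, seq_along(st$amplitude) * 0.05)
  expect_true(st$captured[nrow(st)])
  expect_false(any(st$captured[-nrow(st)]))
  expect_equal(thr@threshold, st$amplitude[nrow(st)])
  # a coarser scan cannot find a lower threshold
  thrCoarse <- findDiastolicThreshold(m, site, increment = 0.2)
  expect_gte(thrCoarse@threshold, thr@threshold - 1e-12)
  expect_lt(thrCoarse@threshold - thr@threshold, 0.2)
})

test_that("threshold search errors at the amplitude cap", {
  m <- smallSheet()
  site <- sphereStimulus(m, c(6, 0), diameter = 1.5)
  expect_error(findDiastolicThreshold(m, site, increment = 0.011, cap = 0.02),
               "amplitude cap")
})

test_that("protocols demand the medium they pace", {
  m <- smallSheet()
  expect_error(runHisPacing(m), "network")
  netOnly <- buildRingFixture(loopLength = 40, unidirectional = FALSE,
                              spacing = 0.5, warnWavelength = FALSE)
  expect_error(runS1Pacing(netOnly), "tissue domain")
  expect_error(runLinePacing(netOnly), "tissue domain")
})

test_that("sub-threshold drive fails loudly at the first beat", {
  m <- smallSheet()
  fake <- new("ThresholdResult", threshold = 0.005,
              searchTrace = data.frame(amplitude = 0.005, captured = TRUE))
  expect_error(runS1Pacing(m, cl = 400, beats = 2, threshold = fake,
                           ampMultiple = 1),
               "loss of 1:1 capture during the drive at beat 1")
})

test_that("S1 pacing returns a full last-beat map and its window", {
  m <- smallSheet()
  r <- runS1Pacing(m, cl = 400, beats = 3)
  expect_equal(r$window, c(800, 1200))
  expect_s4_class(r$map, "ActivationMap")
  expect_equal(length(r$map@at), 25L * 25L)
  expect_false(anyNA(r$map@at))       # the whole sheet activates
  expect_null(r$networkMap)           # bare sheet
  # activation times are relative to the window and start near the S1 onset
  expect_lt(min(r$map@at), 5)
  # re-running with the returned threshold reproduces the same map
  r2 <- runS1Pacing(m, cl = 400, beats = 3, threshold = r$threshold)
  expect_equal(r2$map@at, r$map@at, tolerance = 1e-12)
})

test_that("S1S2 scan walks down to loss of capture and classifies each CI", {
  m <- smallSheet()
  thr <- findDiastolicThreshold(m, sphereStimulus(m, c(6, 0), diameter = 1.5))
  sc <- runS1S2Scan(m, cl = 400, beats = 3, s2Start = 360, decrement = 20,
                    observeMs = 600, threshold = thr)
  cls <- sc$classifications
  expect_true(all(cls$outcome %in%
                    c("reentry", "capture_no_reentry", "no_capture")))
  expect_equal(cls$ci, seq(360, by = -20, length.out = nrow(cls)))
  # the scan stops at the refractory boundary
  expect_equal(cls$outcome[nrow(cls)], "no_capture")
  expect_false(any(cls$outcome[-nrow(cls)] == "no_capture"))
  # a homogeneous small sheet cannot reenter
  expect_true(sc$window$empty)
  # a captured CI rerun at longer observation still shows no reentry
  okCi <- cls$ci[cls$outcome == "capture_no_reentry"][1]
  rr <- rerunS2(sc, okCi, observeMs = 1000)
  expect_false(rr$report@induced)
  expect_true(rr$report@terminated)
})
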
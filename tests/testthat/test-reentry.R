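# Reentry detection on synthetic event streams and vulnerable-window
# bookkeeping (the simulation-driven ring oracle lives in the acceptance
# suite).

mkEvents <- function(times, node = 1L, medium = "tissue", dir = 1L) {
  data.frame(medium = medium, node = node, time = times, dir = dir)
}

test_that("three ascending crossings after the final stimulus = reentry", {
  # S2-evoked beat + two re-activations -> two full rotations
  ev <- mkEvents(c(1005, 1155, 1305))
  rep <- detectReentry(ev, finalStimTime = 1000, observeEnd = 2000,
                       quiesceGap = 250)
  expect_true(rep@induced)
  expect_equal(rep@rotations, 2L)
})

test_that("two crossings is one rotation, not reentry", {
  rep <- detectReentry(mkEvents(c(1005, 1155)), 1000, 2000, 250)
  expect_false(rep@induced)
  expect_equal(rep@rotations, 1L)
})

test_that("events at or before the final stimulus are ignored", {
  ev <- mkEvents(c(500, 700, 1000, 1005))
  rep <- detectReentry(ev, 1000, 2000, 250)
  expect_equal(rep@rotations, 0L)
  expect_false(rep@induced)
})

test_that("rotations count per node and medium, not pooled", {
  ev <- rbind(mkEvents(c(1005, 1155), node = 1L),
              mkEvents(c(1010, 1160), node = 2L),
              mkEvents(1020, node = 1L, medium = "network"))
  rep <- detectReentry(ev, 1000, 2000, 250)
  expect_equal(rep@rotations, 1L)
  expect_false(rep@induced)
})

test_that("termination requires a quiescent gap before the window end", {
  ev <- mkEvents(c(1005, 1155, 1305))
  term <- detectReentry(ev, 1000, observeEnd = 1700, quiesceGap = 250)
  expect_true(term@terminated)
  expect_equal(term@durationS, 0.305)
  ongoing <- detectReentry(ev, 1000, observeEnd = 1400, quiesceGap = 250)
  expect_false(ongoing@terminated)
  expect_equal(ongoing@durationS, 0.4)
})

test_that("no post-stimulus activity is quiescent with zero duration", {
  rep <- detectReentry(mkEvents(500), 1000, 2000, 250)
  expect_false(rep@induced)
  expect_true(rep@terminated)
  expect_equal(rep@durationS, 0)
})

test_that("vulnerable window: worked classification example", {
  cls <- data.frame(ci = c(320, 310, 270, 260),
                    outcome = c("reentry", "reentry", "reentry", "no_capture"))
  w <- vulnerableWindow(cls)
  expect_equal(w$first, 320)
  expect_equal(w$last, 270)
  expect_false(w$empty)
  expect_true(w$contiguous)
})

test_that("vulnerable window: empty and non-contiguous bands", {
  w0 <- vulnerableWindow(data.frame(ci = c(300, 280),
                                    outcome = rep("capture_no_reentry", 2)))
  expect_true(w0$empty)
  expect_true(is.na(w0$first))
  # a capture_no_reentry CI inside the band is reported, not hidden
  w1 <- vulnerableWindow(data.frame(
    ci = c(320, 300, 280),
    outcome = c("reentry", "capture_no_reentry", "reentry")))
  expect_equal(w1$first, 320)
  expect_equal(w1$last, 280)
  expect_false(w1$contiguous)
})
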
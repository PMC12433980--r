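# Map-comparison statistics against a naive independent re-implementation,
# plus the worked three-node example and degenerate-map handling.

naiveCompare <- function(atA, atB) {
  sh <- which(!is.na(atA) & !is.na(atB))
  d <- atB[sh] - atA[sh]
  tA <- diff(range(atA[!is.na(atA)])); tB <- diff(range(atB[!is.na(atB)]))
  list(rd = 100 * sum(abs(d)) / sum(abs(atA[sh])),
       rmsdMean = mean(abs(d)),
       rmsdSd = if (length(d) > 1) sd(abs(d)) else 0,
       cc = suppressWarnings(cor(atA[sh], atB[sh])),
       pct = 100 * abs(tB - tA) / tA)
}

mkMap <- function(at) new("ActivationMap", medium = "tissue", at = at,
                          ids = seq_along(at), t0 = 0)

test_that("worked example: at = (0,10,20) vs (0,12,16)", {
  cc <- compareMaps(mkMap(c(0, 10, 20)), mkMap(c(0, 12, 16)))
  # |d| = (0, 2, 4); sum 6 over sum |a| = 30 -> RD 20%
  expect_equal(cc@rd, 20)
  expect_equal(cc@rmsdMean, 2)
  expect_equal(cc@rmsdSd, 2)
  # total AT 20 vs 16 -> 20% change
  expect_equal(cc@pctAbsDeltaTotalAT, 20)
  expect_equal(cc@cc, cor(c(0, 10, 20), c(0, 12, 16)))
})

test_that("identity comparison is exactly zero difference", {
  at <- c(0, 3.25, 7.5, 12.125)
  cc <- compareMaps(mkMap(at), mkMap(at))
  expect_identical(cc@rd, 0)
  expect_identical(cc@rmsdMean, 0)
  expect_identical(cc@rmsdSd, 0)
  expect_equal(cc@cc, 1)
  expect_identical(cc@pctAbsDeltaTotalAT, 0)
})

test_that("uniform shift: cc 1, rd = shift-derived value", {
  at <- c(0, 5, 10, 20)
  cc <- compareMaps(mkMap(at), mkMap(at + 3))
  expect_equal(cc@cc, 1)
  expect_equal(cc@rmsdMean, 3)
  expect_equal(cc@rmsdSd, 0)
  expect_equal(cc@pctAbsDeltaTotalAT, 0)  # range is shift-invariant
})

test_that("matches the naive oracle on random map pairs", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    atA <- runif(n, 0, 100)
    atB <- atA + rnorm(n, sd = 5)
    atB[atB < 0] <- 0
    # punch some NA holes (keep >= 3 shared)
    if (n > 6) {
      atA[sample(n, 1)] <- NA
      atB[sample(n, 1)] <- NA
    }
    o <- naiveCompare(atA, atB)
    cc <- compareMaps(mkMap(atA), mkMap(atB))
    expect_equal(cc@rd, o$rd, tolerance = 1e-12)
    expect_equal(cc@rmsdMean, o$rmsdMean, tolerance = 1e-12)
    expect_equal(cc@rmsdSd, o$rmsdSd, tolerance = 1e-12)
    expect_equal(cc@cc, o$cc, tolerance = 1e-12)
    expect_equal(cc@pctAbsDeltaTotalAT, o$pct, tolerance = 1e-12)
  }
})

test_that("maps align by node id, not by position", {
  a <- new("ActivationMap", medium = "network", at = c(1, 2, 3, 4),
           ids = c(10L, 20L, 30L, 40L), t0 = 0)
  b <- new("ActivationMap", medium = "network", at = c(4, 2, 1),
           ids = c(40L, 20L, 10L), t0 = 0)
  cc <- compareMaps(a, b)
  expect_equal(cc@nShared, 3L)
  expect_equal(cc@rmsdMean, 0)
  expect_equal(cc@rd, 0)
})

test_that("degenerate and error cases", {
  expect_error(compareMaps(mkMap(c(0, 1)),
                           new("ActivationMap", medium = "network",
                               at = c(0, 1), ids = 1:2, t0 = 0)),
               "medium")
  expect_error(compareMaps(mkMap(c(NA, NA, 1)), mkMap(c(1, 2, NA))),
               "share no activated nodes")
  # constant maps: identical shift -> cc 1; different pattern -> NA
  expect_equal(compareMaps(mkMap(c(5, 5, 5)), mkMap(c(7, 7, 7)))@cc, 1)
  expect_true(is.na(compareMaps(mkMap(c(5, 5, 5)), mkMap(c(1, 2, 3)))@cc))
  # empty map has NA total AT
  expect_true(is.na(totalAT(new("ActivationMap", medium = "tissue",
                                at = c(NA_real_, NA_real_), ids = 1:2,
                                t0 = 0))))
  expect_equal(totalAT(mkMap(c(2, 12))), 10)
})

test_that("activationMap picks first ascending crossing in the window", {
  ev <- data.frame(medium = c("tissue", "tissue", "tissue", "tissue", "network"),
                   node = c(1L, 1L, 2L, 1L, 1L),
                   time = c(5.02, 40, 12, 305, 6),
                   dir = c(1L, -1L, 1L, 1L, 1L))
  tr <- new("SimulationTrace", events = ev, t0 = 0, t1 = 400, stopped = "end",
            probes = list())
  m <- activationMap(tr, c(0, 300), "tissue", nNodes = 3L)
  expect_equal(m@at, c(5.02, 12, NA))
  # window is half-open: the 305 ms event is excluded; a later window sees it
  m2 <- activationMap(tr, c(300, 400), "tissue", nNodes = 3L)
  expect_equal(m2@at, c(5, NA, NA))
  # zero activated nodes is an empty map, not an error
  m3 <- activationMap(tr, c(350, 400), "tissue", nNodes = 3L)
  expect_true(all(is.na(m3@at)))
})

test_that("absDifferenceMap aligns on shared ids", {
  a <- mkMap(c(0, 10, 20))
  b <- mkMap(c(1, 12, 26))
  expect_equal(unname(absDifferenceMap(a, b)), c(1, 2, 6))
})
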
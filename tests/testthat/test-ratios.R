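test_that("sinus/peripheral ratios divide concurrent samples", {
  p <- IpssProcedure("r1",
    acth = mkMat(left = c(40, rep(NA, 6)),
                 peripheral = c(10, 10, rep(NA, 4), 10)),
    prolactin = mkMat())
  expect_equal(sinusPeripheralRatio(p, "ACTH", "left", -5), 4.0)
  p2 <- mkRatioProc(acthLeft = 1)
  expect_equal(sinusPeripheralRatio(p2, "ACTH", "left", 0), 1.0)
  # peripheral cell absent => missing, not an error
  expect_true(is.na(sinusPeripheralRatio(p, "ACTH", "left", 10)))
  # peripheral value 0 paired with a sinus sample is degenerate
  bad <- IpssProcedure("r2",
    acth = mkMat(left = 5, peripheral = c(0, rep(10, 6))),
    prolactin = mkMat())
  expect_error(sinusRatios(bad, "ACTH"), "degenerate")
})

test_that("peak ratio maximizes over the window with deterministic ties", {
  p <- mkRatioProc(
    acthLeft = c(NA, 1.0, 4.0, NA, NA, NA, NA),
    acthRight = c(NA, 2.5, NA, 3.5, NA, NA, NA))
  pk <- peakActhRatio(p, "all")
  expect_equal(pk$value, 4.0)
  expect_identical(pk$side, "left")
  expect_equal(pk$time, 1.5)

  pk0 <- peakActhRatio(p, "basal", basalTime = "t0")
  expect_equal(pk0$value, 2.5)
  expect_identical(pk0$side, "right")
  expect_equal(pk0$time, 0)

  # exact ties resolve to the earlier time, then the left side
  tie <- mkRatioProc(acthLeft = c(NA, 3, 3, NA, NA, NA, NA),
                     acthRight = c(NA, 3, NA, NA, NA, NA, NA))
  pkT <- peakActhRatio(tie, "all")
  expect_identical(pkT$side, "left")
  expect_equal(pkT$time, 0)

  empty <- mkRatioProc(acthLeft = c(1, 1, rep(NA, 5)))
  expect_error(peakActhRatio(empty, "post_stimulation"), "window empty")
})

test_that("the four adjustment methods follow their formulas", {
  # Method 1: peak post ratio 4.0 on left / basal prolactin ratio 2.0 -> 2.0
  p <- mkRatioProc(acthLeft = c(1, 1, 4, 2, 2, 2, 2),
                   prlLeft = c(2, 2, 1.6, 2, 2, 2, 2))
  m1 <- basalAdjustedPeak(p)
  expect_equal(m1$value, 2.0)
  expect_identical(m1$side, "left")
  expect_equal(c(m1$acthTime, m1$prolactinTime), c(1.5, 0))

  # identity when the prolactin gradient is 1
  pid <- mkRatioProc(acthLeft = c(1, 1, 10, 2, 2, 2, 2), prlLeft = 1)
  expect_equal(basalAdjustedPeak(pid)$value, 10.0)

  # Method 2: peak all 4.0 at (left, +1.5) / concurrent prolactin 1.6 -> 2.5
  m2 <- concurrentAdjustedPeak(p)
  expect_equal(m2$value, 2.5)
  expect_equal(m2$acthTime, m2$prolactinTime)

  # Method 3: single side, ratios {0: 1, +1.5: 4}, basal prolactin 2 -> 2
  p3 <- mkRatioProc(acthLeft = c(NA, 1, 4, NA, NA, NA, NA),
                    prlLeft = c(NA, 2, 2, NA, NA, NA, NA))
  expect_equal(basalAdjustedAll(p3)$value, 2.0)
  # all ACTH ratios equal to the side's basal prolactin ratio -> 1.0
  pEq <- mkRatioProc(acthLeft = 2, prlLeft = 2)
  expect_equal(basalAdjustedAll(pEq)$value, 1.0)

  # Method 4: {0: 2/1, +5: 6/3} -> max(2, 2) = 2
  p4 <- mkRatioProc(acthLeft = c(NA, 2, NA, 6, NA, NA, NA),
                    prlLeft = c(NA, 1, NA, 3, NA, NA, NA))
  expect_equal(concurrentAdjustedAll(p4)$value, 2.0)
  # halving a prolactin cell doubles that cell's adjusted ratio
  p4b <- mkRatioProc(acthLeft = c(NA, 2, NA, 6, NA, NA, NA),
                     prlLeft = c(NA, 1, NA, 1.5, NA, NA, NA))
  expect_equal(concurrentAdjustedAll(p4b)$value, 4.0)
})

test_that("missing ipsilateral prolactin fails loudly, never switches sides", {
  p <- mkRatioProc(acthLeft = c(1, 1, 4, 2, 2, 2, 2),
                   prlRight = 2)  # prolactin only on the other side
  expect_error(basalAdjustedPeak(p), "ipsilateral basal prolactin unavailable")
  expect_error(concurrentAdjustedPeak(p), "concurrent prolactin unavailable")
  expect_error(basalAdjustedAll(p), "ipsilateral basal prolactin unavailable")
  # Method 4 skips prolactin-free cells with a warning
  p4 <- mkRatioProc(acthLeft = c(NA, 2, 4, NA, NA, NA, NA),
                    prlLeft = c(NA, 1, NA, NA, NA, NA, NA))
  expect_warning(res <- concurrentAdjustedAll(p4), "skipped")
  expect_equal(res$value, 2.0)
  pNone <- mkRatioProc(acthLeft = c(NA, 2, rep(NA, 5)))
  expect_error(suppressWarnings(concurrentAdjustedAll(pNone)),
               "no cell has both")
})

test_that("prolactin rise on the dominant side is a percent change", {
  mk <- function(prlPost) {
    acth <- mkMat(left = c(1, 1, 50, 1, 1, 1, 1), peripheral = 10)
    prl <- mkMat(left = c(200, 200, prlPost, 180, 170, 160, 150),
                 peripheral = 100)
    IpssProcedure("pr", acth = acth, prolactin = prl)
  }
  expect_equal(prolactinRiseDominant(mk(227)), 13.5)
  expect_equal(prolactinRiseDominant(mk(200)), 0)
  acth <- mkMat(left = c(1, 1, 50, 1, 1, 1, 1), peripheral = 10)
  prl <- mkMat(left = c(100, 100, 764.3, 100, 100, 100, 100), peripheral = 100)
  expect_equal(prolactinRiseDominant(IpssProcedure("pr2", acth = acth,
                                                   prolactin = prl)), 664.3)
})

test_that("peak dominance, window nesting and method ordering hold on random procedures", {
  sim <- simulateCohort(ipssConfig(nProcedures = 60, dilutionJitterCv = 0.2),
                        seed = 314)
  for (p in procedures(sim$cohort)) {
    ratios <- sinusRatios(p, "ACTH")
    pkAll <- peakActhRatio(p, "all")$value
    expect_gte(pkAll, max(ratios, na.rm = TRUE) - 1e-12)
    expect_gte(pkAll, peakActhRatio(p, "post_stimulation")$value)
    expect_gte(pkAll, peakActhRatio(p, "basal", basalTime = "both")$value)
    # the peak-method term is a member of the all-method max
    expect_gte(basalAdjustedAll(p)$value, basalAdjustedPeak(p)$value - 1e-12)
    expect_gte(concurrentAdjustedAll(p)$value,
               concurrentAdjustedPeak(p)$value - 1e-12)
  }
})

test_that("ratios and scores are invariant to per-analyte rescaling", {
  p <- mkCompleteProc()
  for (an in ipssAnalytes()) {
    ps <- scaleAnalyte(p, an, 3.7)
    expect_equal(sinusRatios(ps, an), sinusRatios(p, an))
    expect_equal(adjustedScores(ps)$value, adjustedScores(p)$value)
  }
})

test_that("a shared dilution factor cancels out of the adjusted scores", {
  p <- mkCompleteProc()
  base <- adjustedScores(p)
  # side-uniform dilution: Methods 1-4 all unchanged
  pd <- diluteSide(p, "left", 0.25)
  expect_equal(adjustedScores(pd)$value, base$value)
  # single-time dilution: the concurrent-adjusted CELL score at that time is
  # unchanged (the peak may legitimately move to another cell)
  peakTime <- peakActhRatio(p, "all")$time
  pt <- diluteSide(p, "left", 0.5, times = peakTime)
  cellScore <- function(pr)
    sinusRatios(pr, "ACTH")["left", as.character(peakTime)] /
      sinusRatios(pr, "prolactin")["left", as.character(peakTime)]
  expect_equal(cellScore(pt), cellScore(p))
})

test_that("out-of-range inputs taint score provenance", {
  p <- mkRatioProc(acthLeft = c(1, 1, 4, 2, 2, 2, 2),
                   prlLeft = 2, acthPeripheral = 200)
  # left sinus at +1.5 is 4 * 200 = 800 pmol/L, above the assay ceiling
  expect_true(basalAdjustedPeak(p)$qcFlagged)
  pOk <- mkRatioProc(acthLeft = c(1, 1, 4, 2, 2, 2, 2), prlLeft = 2)
  expect_false(basalAdjustedPeak(pOk)$qcFlagged)
})
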
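test_that("cohort simulation is reproducible and insertion-stable", {
  cfg <- ipssConfig(nProcedures = 5)
  a <- simulateCohort(cfg, seed = 1)
  b <- simulateCohort(cfg, seed = 1)
  expect_identical(a$truth, b$truth)
  for (i in 1:5)
    expect_identical(assayValues(a$cohort[[i]], "ACTH"),
                     assayValues(b$cohort[[i]], "ACTH"))

  # per-procedure substreams: growing the cohort leaves early procedures alone
  big <- simulateCohort(ipssConfig(nProcedures = 8), seed = 1)
  expect_identical(big$truth[1:5, ], a$truth)

  c2 <- simulateCohort(cfg, seed = 2)
  expect_false(identical(a$truth, c2$truth))
})

test_that("labels follow easFraction and truth is carried on the procedure", {
  allCd <- simulateCohort(ipssConfig(nProcedures = 25, easFraction = 0),
                          seed = 5)
  expect_true(all(allCd$truth$trueLabel == "CD"))
  expect_identical(unname(referenceLabels(allCd$cohort)),
                   allCd$truth$trueLabel)
  allEas <- simulateCohort(ipssConfig(nProcedures = 10, easFraction = 1),
                           seed = 5)
  expect_true(all(allEas$truth$trueLabel == "EAS"))
  expect_true(all(is.na(allEas$truth$dominantSide)))
})

noiseFree <- function(...) {
  args <- utils::modifyList(
    list(cdDominantGradient = c(10, 0), cdContralateralGradient = c(2, 0),
         crhActhFoldCd = c(4, 4), peripheralCrhFoldCd = c(1, 1),
         crhProlactinRise = c(0, 0), prolactinGradient = c(3, 0),
         dilutionLow = 1, dilutionJitterCv = 0, assayCv = 0),
    list(...))
  do.call(ipssConfig, args)
}

test_that("noise-free kinetics reproduce the hand-propagated ratios", {
  s <- simulateProcedure(noiseFree(), trueLabel = "CD", seed = 7)
  p <- s$procedure
  dom <- s$truth$dominantSide
  ratios <- sinusRatios(p, "ACTH")
  # basal gradient 10 on the dominant side, amplified x4 at the +1.5 peak
  expect_equal(unname(ratios[dom, "0"]), 10)
  expect_equal(unname(ratios[dom, "1.5"]), 40)
  # kinetic shape decays along the tail
  expect_equal(unname(ratios[dom, "20"]), 10 * (1 + 3 * 0.4))
  # contralateral side keeps its mild constant gradient
  other <- setdiff(c("left", "right"), dom)
  expect_equal(unname(ratios[other, ]), rep(2, 7))
  # prolactin gradient 3 on both sides, no rise
  expect_equal(unname(sinusRatios(p, "prolactin")[dom, ]), rep(3, 7))
  expect_equal(basalAdjustedPeak(p)$value, 40 / 3)
  expect_equal(concurrentAdjustedPeak(p)$value, 40 / 3)
})

test_that("the peripheral CRH response divides into post-stimulation ratios", {
  cfg <- noiseFree(peripheralCrhFoldCd = c(1.5, 1.5))
  s <- simulateProcedure(cfg, trueLabel = "CD", seed = 7)
  ratios <- sinusRatios(s$procedure, "ACTH")
  dom <- s$truth$dominantSide
  # one-grid-point lag: the +1.5 ratio is untouched, +5 is divided by the
  # peripheral rise at its lagged shape peak
  expect_equal(unname(ratios[dom, "1.5"]), 40)
  expect_equal(unname(ratios[dom, "5"]), 10 * (1 + 3 * 0.9) / 1.5)
})

test_that("catheter dilution suppresses unadjusted ratios but cancels in adjustment", {
  s <- simulateProcedure(noiseFree(), trueLabel = "CD", seed = 11)
  p <- diluteSide(s$procedure, s$truth$dominantSide, 0.25)
  expect_equal(peakActhRatio(p, "all")$value, 10)  # was 40
  expect_equal(basalAdjustedPeak(p)$value, 40 / 3) # unchanged
  expect_equal(concurrentAdjustedPeak(p)$value, 40 / 3)
})

test_that("a worked dilution example: gradient 20, prolactin gradient 2.5", {
  cfg <- ipssConfig(cdDominantGradient = c(20, 0),
                    cdContralateralGradient = c(2, 0),
                    crhActhFoldCd = c(1, 1), peripheralCrhFoldCd = c(1, 1),
                    crhProlactinRise = c(0, 0), prolactinGradient = c(2.5, 0),
                    dilutionLow = 1, dilutionJitterCv = 0, assayCv = 0)
  s <- simulateProcedure(cfg, trueLabel = "CD", seed = 3)
  p <- diluteSide(s$procedure, s$truth$dominantSide, 0.25)
  expect_equal(peakActhRatio(p, "all")$value, 5.0)
  expect_equal(basalAdjustedPeak(p)$value, 8.0)
})

test_that("noise-free EAS cohorts have near-unity gradients and low scores", {
  cfg <- ipssConfig(nProcedures = 40, easFraction = 1,
                    peripheralCrhFoldCd = c(1, 1),
                    dilutionLow = 1, dilutionJitterCv = 0, assayCv = 0)
  sim <- simulateCohort(cfg, seed = 21)
  ratios <- unlist(lapply(procedures(sim$cohort),
                          function(p) sinusRatios(p, "ACTH")))
  expect_gt(mean(ratios >= 0.8 & ratios <= 1.3), 0.95)
  expect_lt(abs(stats::median(ratios) - 1), 0.1)
  sc <- cohortScores(sim$cohort)
  expect_gt(mean(sc$basal_peak < 1), 0.95)
  expect_gt(mean(sc$concurrent_peak < 1), 0.95)
  expect_lt(stats::median(sc$basal_peak), 0.6)
})

test_that("values beyond the assay ranges are always flagged, never silently emitted", {
  cfg <- ipssConfig(nProcedures = 30, peripheralActhMedian = 150)
  sim <- simulateCohort(cfg, seed = 13)
  rng <- assayRanges()
  sawOutOfRange <- FALSE
  for (p in procedures(sim$cohort)) for (an in ipssAnalytes()) {
    v <- assayValues(p, an); f <- assayFlags(p, an)
    out <- !is.na(v) & (v < rng[[an]][1] | v > rng[[an]][2])
    sawOutOfRange <- sawOutOfRange || any(out)
    expect_true(all(f[out] != "ok"))
    expect_true(all(f[!is.na(v) & !out] == "ok"))
  }
  expect_true(sawOutOfRange)  # the scenario actually exercises truncation
})

test_that("dominant-side prolactin rise lands in the configured envelope", {
  cfg <- ipssConfig(nProcedures = 25, easFraction = 0, dilutionLow = 1,
                    dilutionJitterCv = 0, assayCv = 0,
                    peripheralCrhFoldCd = c(1, 1))
  sim <- simulateCohort(cfg, seed = 17)
  rises <- vapply(procedures(sim$cohort), prolactinRiseDominant, numeric(1))
  expect_true(all(rises >= 13.5 - 1e-9 & rises <= 300 + 1e-9))
  # inside the clinically observed 13.5-664.3% envelope
  expect_true(all(rises <= 664.3))
})

test_that("scenario presets encode their intended regimes", {
  presets <- scenarioPresets()
  expect_setequal(names(presets),
                  c("clean", "dilution", "noisy_timepoints", "partial"))
  expect_equal(presets$clean$dilutionLow, 1)
  expect_equal(presets$clean$dilutionJitterCv, 0)
  expect_equal(presets$dilution$dilutionLow, 0.2)
  expect_equal(presets$noisy_timepoints$dilutionJitterCv, 0.30)
  expect_equal(presets$partial$missingSideProb, 0.15)

  # clean: no dilution, so basal ratios equal the true gradients up to noise
  cfg <- presets$clean; cfg$nProcedures <- 15; cfg$assayCv <- 0
  sim <- simulateCohort(cfg, seed = 9)
  for (i in seq_len(15)) {
    r <- sinusRatios(sim$cohort[[i]], "ACTH")
    expect_equal(unname(r["left", "0"]), sim$truth$gradientLeft[i])
    expect_equal(unname(r["right", "0"]), sim$truth$gradientRight[i])
  }

  # partial cohorts stay analyzable end-to-end
  cfgP <- presets$partial; cfgP$nProcedures <- 40
  simP <- simulateCohort(cfgP, seed = 23)
  oneSided <- vapply(procedures(simP$cohort),
                     function(p) length(sidesAvailable(p)) == 1L, logical(1))
  expect_true(any(oneSided))
  sc <- cohortScores(simP$cohort)
  expect_equal(nrow(sc), 40L)
  expect_true(all(is.finite(sc$basal_peak)))
})

test_that("generator configuration is validated", {
  expect_error(ipssConfig(nProcedures = 0), "positive")
  expect_error(ipssConfig(easFraction = 1.2), "easFraction")
  expect_error(ipssConfig(dilutionLow = 0), "dilutionLow")
  expect_error(ipssConfig(cdDominantGradient = c(-1, 0.5)), "median")
})
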
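stdFrame <- function(mw, intercept = 150, slope = -38)
  data.frame(mw_kda = mw, migration_mm = intercept + slope * log10(mw))

test_that("mobility calibration interpolates log-linearly", {
  cal <- calibrateMobility(data.frame(mw_kda = c(3000, 300),
                                      migration_mm = c(10, 20)))
  # midway in migration lies at the geometric-mean MW
  expect_equal(migrationToMw(cal, 15), sqrt(3000 * 300), tolerance = 1e-9)
  # a standard's migration maps back to its MW exactly (2-point case)
  expect_equal(migrationToMw(cal, 10), 3000, tolerance = 1e-9)
  expect_equal(migrationToMw(cal, 20), 300, tolerance = 1e-9)
  # three collinear-in-log standards fit with zero residual
  s3 <- stdFrame(c(4000, 1000, 250))
  cal3 <- calibrateMobility(s3)
  expect_equal(mwToMigration(cal3, s3$mw_kda), s3$migration_mm,
               tolerance = 1e-9)
  # round trip MW -> migration -> MW is identity to machine precision
  mws <- c(223, 948.7, 2300, 3700)
  expect_equal(migrationToMw(cal3, mwToMigration(cal3, mws)), mws,
               tolerance = 1e-12)
})

test_that("calibration errors on insufficient or degenerate standards", {
  expect_error(calibrateMobility(stdFrame(1000)), "at least 2")
  expect_error(calibrateMobility(
    data.frame(mw_kda = c(1000, 1000), migration_mm = c(10, 12))),
    "distinct")
})

test_that("band integration conserves area and removes linear backgrounds", {
  cal <- calibrateMobility(stdFrame(c(4000, 1000, 250)))
  b <- data.frame(label = "T2", mw_kda = 2300, quantity_au = 0.8)
  p0 <- gelSimParams(bands = b, background = c(0, 0), noiseSd = 0,
                     quantityCv = 0, seed = 1)
  lane0 <- simulateGelLane(p0)$lane
  win <- data.frame(label = "T2",
                    from_mm = mwToMigration(cal, 2300) - 3,
                    to_mm = mwToMigration(cal, 2300) + 3)
  q0 <- quantifyLane(lane0, cal, bandWindows = win)
  expect_lt(abs(q0$integrated_od - 0.8) / 0.8, 0.01)
  # adding a linear ramp changes the area by < 2% (baseline removal)
  p1 <- gelSimParams(bands = b, background = c(0.1, 0.004), noiseSd = 0,
                     quantityCv = 0, seed = 1)
  q1 <- quantifyLane(simulateGelLane(p1)$lane, cal, bandWindows = win)
  expect_lt(abs(q1$integrated_od - q0$integrated_od) / q0$integrated_od, 0.02)
})

test_that("auto-windowed lanes recover labels, masses and the trunc band", {
  cal <- calibrateMobility(stdFrame(c(4000, 2000, 1000, 500, 250)))
  sim <- simulateGelLane(gelSimParams(seed = 21))
  bands <- quantifyLane(sim$lane, cal)
  expect_setequal(setdiff(bands$label, "other"),
                  c("N2BA", "N2B", "T2", "MyHC"))
  pred <- defaultGelComposition("TTNTV_POS")
  predTrunc <- pred$mw_kda[pred$label == "truncated"]
  bands <- identifyTruncatedBand(bands, predTrunc)
  expect_true("truncated" %in% bands$label)
  est <- bands$estimated_mw_kda[bands$label == "truncated"]
  # calibration round trip: estimated MW within 5% of the configured MW
  expect_lt(abs(est - predTrunc) / predTrunc, 0.05)
})

test_that("titin ratios follow their defining arithmetic and scale invariance", {
  mk <- function(od) data.frame(
    label = c("N2BA", "N2B", "T2", "truncated", "MyHC"),
    integrated_od = od, estimated_mw_kda = c(3700, 3000, 2300, 1900, 223))
  r <- computeTitinRatios(mk(rep(1, 5)))
  expect_equal(r$n2ba_over_n2b, 1, tolerance = 1e-12)
  expect_equal(r$t2_over_t1, 0.5, tolerance = 1e-12)
  expect_equal(r$trunc_over_t1, 0.5, tolerance = 1e-12)
  expect_equal(r$t1_over_myhc, 2, tolerance = 1e-12)
  expect_equal(r$integrated_titin_over_myhc, 4, tolerance = 1e-12)
  # global OD scaling leaves every ratio unchanged
  r2 <- computeTitinRatios(mk(2.7 * c(0.4, 0.6, 0.25, 0.19, 2.5)))
  r1 <- computeTitinRatios(mk(c(0.4, 0.6, 0.25, 0.19, 2.5)))
  for (f in names(r1)) expect_equal(r2[[f]], r1[[f]], tolerance = 1e-12)
  # absent optional bands count as zero; missing mandatory bands error
  r3 <- computeTitinRatios(mk(rep(1, 5))[c(1, 2, 5), ])
  expect_identical(r3$t2_over_t1, 0)
  expect_error(computeTitinRatios(mk(rep(1, 5))[c(1, 3, 5), ]), "N2B")
  expect_error(computeTitinRatios({
    d <- mk(rep(1, 5)); d$integrated_od[5] <- 0; d
  }), "MyHC")
})

test_that("truncated-band mass matching applies the relative tolerance", {
  expect_true(matchTruncatedBand(2000, 2100))    # 4.8% off
  expect_true(matchTruncatedBand(1500, 1500))
  expect_false(matchTruncatedBand(1000, 2000))
  expect_error(matchTruncatedBand(-1, 2000), "positive")
})

test_that("simulated lanes recover the configured trunc/T1 on average", {
  cal <- calibrateMobility(stdFrame(c(4000, 2000, 1000, 500, 250)))
  pred <- defaultGelComposition("TTNTV_POS")
  predTrunc <- pred$mw_kda[pred$label == "truncated"]
  ratios <- vapply(1:12, function(i) {
    sim <- simulateGelLane(gelSimParams(seed = 400 + i))
    b <- identifyTruncatedBand(quantifyLane(sim$lane, cal), predTrunc)
    computeTitinRatios(b)$trunc_over_t1
  }, 0)
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.19), 2 * se + 0.005)
})

test_that("saturated plateaus raise a warning", {
  cal <- calibrateMobility(stdFrame(c(4000, 1000, 250)))
  p <- gelSimParams(bands = data.frame(label = "x", mw_kda = 1000,
                                       quantity_au = 3),
                    background = c(0, 0), noiseSd = 0, quantityCv = 0,
                    seed = 2)
  lane <- simulateGelLane(p)$lane
  od <- lane@od
  od[od > 1] <- 1  # clip as a saturated scanner would
  sat <- new("GelLaneProfile", migrationMm = lane@migrationMm, od = od,
             laneId = "sat")
  win <- data.frame(label = "x", from_mm = mwToMigration(cal, 1000) - 3,
                    to_mm = mwToMigration(cal, 1000) + 3)
  expect_warning(quantifyLane(sat, cal, bandWindows = win), "saturated")
})
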
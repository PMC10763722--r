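test_that("a noiseless single Gaussian is recovered essentially exactly", {
  pk <- data.frame(center = 500, height = 100, fwhm = 40)
  prof <- makeGaussianProfile(pk, 0, 1000)
  fit <- detectAndFitPeaks(prof, "mir")
  expect_identical(nrow(fit), 1L)
  expect_lt(abs(fit$center_nm - 500), 1)
  expect_lt(abs(fit$fwhm_nm - 40), 1)
  expect_lt(abs(fit$height - 100), 1)
  expect_lt(abs(fit$baseline), 0.5)
})

test_that("a 140 nm doublet at 40 nm FWHM is resolved with the right separation", {
  pk <- data.frame(center = c(430, 570), height = c(100, 100), fwhm = 40)
  prof <- makeGaussianProfile(pk, 0, 1000)
  fit <- detectAndFitPeaks(prof, "mir")
  expect_identical(nrow(fit), 2L)
  expect_lt(abs(diff(fit$center_nm) - 140), 2)
})

test_that("a 30 nm pair below the resolving criterion stays one peak, flagged wide", {
  pk <- data.frame(center = c(485, 515), height = c(100, 100), fwhm = 40)
  # Rayleigh-style oracle: the summed curve has a single maximum
  x <- seq(400, 600, by = 1)
  s <- 40 / (2 * sqrt(2 * log(2)))
  y <- rowSums(sapply(pk$center, function(c0) 100 * exp(-(x - c0)^2 / (2 * s^2))))
  expect_identical(sum(diff(sign(diff(y))) < 0), 1L)
  prof <- makeGaussianProfile(pk, 0, 1000)
  fit <- detectAndFitPeaks(prof, "mir",
                           fitSettings(expectedFwhmNm = 40,
                                       maxFwhmFactor = 1.2))
  expect_identical(nrow(fit), 1L)
  expect_identical(fit$flag, "wide")
})

test_that("shoulder splitting is off by default but available via the F criterion", {
  pk <- data.frame(center = c(485, 515), height = c(100, 100), fwhm = 40)
  prof <- makeGaussianProfile(pk, 0, 1000)
  fit1 <- detectAndFitPeaks(prof, "mir", fitSettings(splitShoulders = FALSE))
  expect_identical(nrow(fit1), 1L)
  fit2 <- detectAndFitPeaks(prof, "mir", fitSettings(splitShoulders = TRUE))
  expect_identical(nrow(fit2), 2L)
  expect_lt(abs(diff(fit2$center_nm) - 30), 2)
})

test_that("sarcomere assignment follows the [MIR, A170, A170, MIR] grammar", {
  sl <- 1800
  mk <- function(nSarc) {
    mir <- c(); a170 <- c()
    for (k in seq_len(nSarc)) {
      o <- (k - 1) * sl; m <- o + sl / 2
      mir <- c(mir, m - 700, m + 700)
      a170 <- c(a170, m - 70, m + 70)
    }
    list(mir = peakTable(mir, "mir"), a170 = peakTable(a170, "a170"))
  }
  pks <- mk(3)
  meas <- assignSarcomeres(pks$mir, pks$a170)
  expect_identical(nrow(meas), 3L)
  expect_equal(meas$dtk_nm, rep(70, 3), tolerance = 1e-9)
  expect_equal(meas$aband_titin_len_nm, rep(1400, 3), tolerance = 1e-9)
  expect_equal(meas$sl_nm, rep(sl, 3), tolerance = 1e-9)

  # spurious extra MIR between a valid pair, outside the doublet: the
  # contaminated candidate is rejected and the count is unchanged
  spur <- rbind(pks$mir, peakTable(2 * sl - 650, "mir"))
  spur <- spur[order(spur$center_nm), ]
  meas2 <- assignSarcomeres(spur, pks$a170)
  expect_identical(nrow(meas2), 3L)

  # exhaustive-enumeration oracle: every reported match must bound exactly
  # two A170 peaks with no other MIR inside
  for (i in seq_len(nrow(meas2))) {
    l <- meas2$mir_left_nm[i]
    r <- meas2$mir_right_nm[i]
    inside_a <- sum(pks$a170$center_nm > l + 1e-6 & pks$a170$center_nm < r - 1e-6)
    inside_m <- sum(spur$center_nm > l + 1e-6 & spur$center_nm < r - 1e-6)
    expect_identical(inside_a, 2L)
    expect_identical(inside_m, 0L)
  }

  # no A170 peaks: no measurements
  empty <- assignSarcomeres(pks$mir, pks$a170[0, ])
  expect_identical(nrow(empty), 0L)
  expect_true(length(attr(empty, "diagnostics")) > 0)
})

test_that("fewer than two complete matches yields an empty result with diagnostics", {
  mir <- peakTable(c(200, 1600), "mir")
  a170 <- peakTable(c(830, 970), "a170")
  out <- assignSarcomeres(mir, a170)
  expect_identical(nrow(out), 0L)
  expect_match(attr(out, "diagnostics")[1], "need >= 2")
})

test_that("the QC rule reproduces hand-computed fluctuations", {
  m <- data.frame(mir_height_l = 100, mir_height_r = 130,
                  a170_height_l = 50, a170_height_r = 50)
  res <- qcFilter(m)
  expect_false(res$pass)          # 30/115 = 0.261 > 0.20
  expect_identical(res$reasons, "MIR")

  m2 <- data.frame(mir_height_l = 80, mir_height_r = 80,
                   a170_height_l = 80, a170_height_r = 80)
  expect_true(qcFilter(m2)$pass)

  m3 <- data.frame(mir_height_l = 100, mir_height_r = 101,
                   a170_height_l = 100, a170_height_r = 130)
  res3 <- qcFilter(m3)
  expect_false(res3$pass)
  expect_identical(res3$reasons, "A170")

  m4 <- m2; m4$a170_height_r <- NA
  expect_identical(qcFilter(m4)$reasons, "incomplete")

  # exactly at the threshold passes (fail requires exceeding 20%)
  m5 <- data.frame(mir_height_l = 100, mir_height_r = 100 * 1.2 / 0.9 * 0.9,
                   a170_height_l = 90, a170_height_r = 110)
  expect_true(qcFilter(m5)$pass)  # 20/100 = 0.20 exactly
})

test_that("the A170/MIR intensity ratio is the mean-height quotient", {
  m <- data.frame(mir_height_l = 120, mir_height_r = 80,
                  a170_height_l = 120, a170_height_r = 80)
  expect_equal(normalizeA170Intensity(m), 1.0, tolerance = 1e-12)
  m2 <- data.frame(mir_height_l = 0, mir_height_r = 0,
                   a170_height_l = 10, a170_height_r = 10)
  expect_error(normalizeA170Intensity(m2), "undefined ratio")
})

test_that("noiseless end-to-end recovery is exact within 1 nm", {
  prof <- makeLayoutProfile(genotypeParams("TTNTV_NEG"), 1.8, nSarc = 3)
  meas <- profileSarcomeres(prof)
  expect_identical(nrow(meas), 3L)
  expect_true(all(meas$qc_pass))
  expect_lt(max(abs(meas$a170_separation_nm - 140)), 1)
  expect_lt(max(abs(meas$dtk_nm - 70)), 1)
  expect_lt(max(abs(meas$aband_titin_len_nm - 1400)), 1)
  expect_lt(max(abs(meas$sl_nm - 1800)), 1)
  expect_equal(meas$a170_over_mir_intensity, rep(1, 3), tolerance = 0.02)
  # dtk is half the A170 separation exactly, by construction
  expect_identical(meas$dtk_nm, meas$a170_separation_nm / 2)
})

test_that("assignments are invariant to translating the whole profile", {
  prof <- makeLayoutProfile(genotypeParams("TTNTV_NEG"), 2.0, nSarc = 3)
  shifted <- new("IntensityProfile",
                 positionsNm = positionsNm(prof) + 3456.7,
                 channels = prof@channels, metadata = prof@metadata)
  m1 <- profileSarcomeres(prof)
  m2 <- profileSarcomeres(shifted)
  for (col in c("sl_nm", "aband_titin_len_nm", "dtk_nm", "a170_separation_nm"))
    expect_equal(m2[[col]], m1[[col]], tolerance = 1e-6)
  expect_equal(m2$m_position_nm, m1$m_position_nm + 3456.7, tolerance = 1e-6)
})

test_that("recovered metrics are unbiased across seeds at generator defaults", {
  p <- stedSimParams(genotype = "TTNTV_NEG", seed = 77)
  m <- profileDataset(simulateStretchSeries(p, 1.8, 25))
  mq <- m[m$qc_pass, ]
  expect_gt(nrow(mq), 30)
  for (spec in list(c("a170_separation_nm", 140), c("dtk_nm", 70),
                    c("aband_titin_len_nm", 1400))) {
    v <- mq[[spec[1]]]
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - as.numeric(spec[2])), 2 * se + 1e-9)
  }
})

test_that("truncated-molecule disregistry widens the MIR band and relaxes with stretch", {
  run <- function(gt, sl, seed, n = 12) {
    p <- stedSimParams(genotype = gt, seed = seed)
    m <- profileDataset(simulateStretchSeries(p, sl, n))
    mean(m$mir_fwhm_nm)  # width question: use all assigned sarcomeres
  }
  wNeg <- run("TTNTV_NEG", 1.8, 501)
  wPosSlack <- run("TTNTV_POS", 1.8, 502)
  wPosLong <- run("TTNTV_POS", 2.6, 503)
  expect_gt(wPosSlack, wNeg)
  expect_lt(wPosLong, wPosSlack)
})

test_that("line profiles extracted from 2D images honour the averaging contract", {
  img <- matrix(7.5, nrow = 60, ncol = 21)
  for (w in c(1, 5, 11)) {
    prof <- extractLineProfile(img, 10, c(5, 11), c(55, 11), widthPx = w)
    expect_equal(unname(channelIntensity(prof, "intensity")),
                 rep(7.5, length(positionsNm(prof))), tolerance = 1e-9)
  }
  expect_error(extractLineProfile(img, 10, c(5, 2), c(55, 2), widthPx = 21),
               "exits the image")

  # generator round trip: a rendered image recovers the 1D ground truth
  sim <- simulateProfile(stedSimParams(genotype = "TTNTV_NEG", seed = 9))
  im <- renderProfileImage(sim, widthPx = 11)
  n <- length(im$positionsNm)
  prof <- extractLineProfile(im$images$mir, im$pixelNm, c(1, 6), c(n, 6),
                             widthPx = 11)
  truth <- sim$truth$noiseless$mir
  resid <- channelIntensity(prof, "intensity") - truth
  expect_lt(mean(abs(resid[truth > 50])) / mean(truth[truth > 50]), 0.1)

  # width averaging reduces noise relative to a single-pixel line
  msd <- function(w) {
    devs <- vapply(1:6, function(i) {
      s <- simulateProfile(stedSimParams(genotype = "TTNTV_NEG",
                                         seed = 600 + i))
      imi <- renderProfileImage(s, widthPx = 11)
      pr <- extractLineProfile(imi$images$mir, imi$pixelNm, c(1, 6),
                               c(length(imi$positionsNm), 6), widthPx = w)
      mean((channelIntensity(pr, "intensity") - s$truth$noiseless$mir)^2)
    }, 0)
    mean(devs)
  }
  expect_lt(msd(11), msd(1))
})
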
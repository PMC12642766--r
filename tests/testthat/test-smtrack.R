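test_that("dark offset is the grand mean over pixels and frames", {
  expect_equal(darkOffset(array(0, c(4, 4, 3))), 0)
  expect_equal(darkOffset(matrix(100, 8, 8)), 100)
  set.seed(21)
  dark <- array(rnorm(64 * 64 * 100, mean = 100, sd = 2), c(64, 64, 100))
  se <- 2 / sqrt(length(dark))
  expect_lt(abs(darkOffset(dark) - 100), 4 * se)
  expect_error(darkOffset(numeric(0)), "empty")
})

test_that("photon conversion applies gain, QE and offset correctly", {
  cal1 <- CameraCalibration(gain = 1, qe = 1, offset = 0)
  even <- photonCounts(iSpot = 100, iBgPerPix = 100 / 9, nMask = 9,
                       cal = cal1)
  expect_equal(even$nGamma, 0)
  expect_true(even$flagged)
  expect_equal(photonCounts(200, 100 / 9, 9, cal1)$nGamma, 100)

  cal2 <- CameraCalibration(gain = 0.5, qe = 0.8, offset = 100)
  expect_equal(photonCounts(2000, 104, 9, cal2)$bGamma, 2.5)

  expect_error(photonCounts(200, 50, 9, cal1, iBg = 100), "nMask")
  expect_error(CameraCalibration(gain = 1, qe = 0), "qe")
})

test_that("tilt mixing interpolates between lateral and axial widths", {
  expect_equal(tiltMixedSigma(0.1, 0.4, 0), 0.1)
  expect_equal(tiltMixedSigma(0.1, 0.4, 90), 0.4)
  expect_equal(tiltMixedSigma(0.2, 0.2, 37.3), 0.2)
  expect_equal(tiltMixedSigma(0.127, 0.294, 45),
               sqrt((0.127^2 + 0.294^2) / 2), tolerance = 1e-12)
})

test_that("localization precision follows the closed-form bound", {
  model <- PrecisionModel(pixelSize = 0.0867, sigmaX = 0.127,
                          sigmaY = 0.127, sigmaZ = 0.127, tiltDeg = 0)
  # independent scalar evaluation of the formula
  a <- 0.0867; s <- 0.127; n <- 110; b <- 5
  want <- sqrt((s^2 + a^2 / 12) / n + 8 * pi * s^4 * b / (a^2 * n^2))
  got <- localizationPrecision(n, b, model)
  expect_equal(got$sigmaLocX, want, tolerance = 1e-12)
  expect_equal(got$sigmaLocY, want, tolerance = 1e-12)

  # background-free small-pixel limit: sigma_psf / sqrt(N)
  tiny <- PrecisionModel(pixelSize = 1e-6, sigmaX = 0.127, sigmaY = 0.127,
                         sigmaZ = 0.127, tiltDeg = 0)
  expect_equal(localizationPrecision(110, 0, tiny)$sigmaLocX,
               0.127 / sqrt(110), tolerance = 1e-6)
  # quadrupling the photons halves the error in that limit
  expect_equal(localizationPrecision(440, 0, tiny)$sigmaLocX,
               localizationPrecision(110, 0, tiny)$sigmaLocX / 2,
               tolerance = 1e-6)

  expect_error(localizationPrecision(0, 1, model), "nGamma")
})

test_that("tilt degrades y' precision whenever the axial blur is broader", {
  model <- PrecisionModel(pixelSize = 0.0867, sigmaX = 0.127, sigmaY = 0.16,
                          sigmaZ = 0.294, tiltDeg = 45)
  pr <- localizationPrecision(c(50, 110, 400), c(2, 5, 9), model)
  expect_true(all(pr$sigmaLocY > pr$sigmaLocX))
})

test_that("mean precision averages spots and drops flagged ones", {
  cal <- CameraCalibration(gain = 1, qe = 1, offset = 0)
  model <- PrecisionModel(pixelSize = 0.0867, sigmaX = 0.127,
                          sigmaY = 0.127, sigmaZ = 0.3, tiltDeg = 45)
  tab <- data.frame(iSpot = rep(300, 3), iBgPerPix = rep(10, 3),
                    nMask = rep(9, 3))
  single <- localizationPrecision(300 - 90, 10, model)
  mp <- meanPrecision(tab, cal, model)
  expect_equal(mp$sigmaX, single$sigmaLocX, tolerance = 1e-12)
  expect_equal(mp$nUsed, 3)

  # brute-force loop over a random table
  set.seed(8)
  tab2 <- data.frame(iSpot = runif(40, 50, 500),
                     iBgPerPix = runif(40, 0, 12), nMask = 9)
  mp2 <- meanPrecision(tab2, cal, model)
  keep <- (tab2$iSpot - 9 * tab2$iBgPerPix) > 0
  loop <- colMeans(do.call(rbind, lapply(which(keep), function(i) {
    n <- tab2$iSpot[i] - 9 * tab2$iBgPerPix[i]
    unlist(localizationPrecision(n, tab2$iBgPerPix[i], model))
  })))
  expect_equal(mp2$sigmaX, unname(loop["sigmaLocX"]), tolerance = 1e-12)
  expect_equal(mp2$sigmaY, unname(loop["sigmaLocY"]), tolerance = 1e-12)
  expect_equal(mp2$nExcluded, sum(!keep))

  allBad <- data.frame(iSpot = 10, iBgPerPix = 10, nMask = 9)
  expect_error(meanPrecision(allBad, cal, model), "no spot")
})

test_that("Brownian track simulation has the stated step statistics", {
  ts <- simulateBrownianTracks(0, 0.05, 5, 10, 0, 0, seed = 4)
  expect_equal(nrow(tracks(ts)), 50)
  sq <- by(tracks(ts), tracks(ts)$track,
           function(b) max(abs(diff(b$x)), abs(diff(b$y))))
  expect_equal(max(unlist(sq)), 0)   # D = 0, no noise: constant tracks

  # identical seeds give bit-identical tables
  a <- simulateBrownianTracks(1, 0.05, 20, 20, 0.03, 0.06, seed = 7)
  b <- simulateBrownianTracks(1, 0.05, 20, 20, 0.03, 0.06, seed = 7)
  expect_identical(tracks(a), tracks(b))

  # empirical per-axis step variance ~ 2 D dt + 2 sigma^2
  ts2 <- simulateBrownianTracks(1, 0.05, 400, 30, 0.05, 0.08, seed = 12)
  dx <- unlist(by(tracks(ts2), tracks(ts2)$track, function(b) diff(b$x)))
  dy <- unlist(by(tracks(ts2), tracks(ts2)$track, function(b) diff(b$y)))
  expect_equal(var(dx), 2 * 1 * 0.05 + 2 * 0.05^2, tolerance = 0.03)
  expect_equal(var(dy), 2 * 1 * 0.05 + 2 * 0.08^2, tolerance = 0.03)
})

test_that("noise-corrected MSD removes the static localization floor", {
  # stationary emitters with localization noise: raw MSD ~ 2(sx^2+sy^2),
  # corrected ~ 0 within its standard error
  sx <- 0.0329; sy <- 0.0584
  ts <- simulateBrownianTracks(0, 0.05, 300, 40, sx, sy, seed = 31)
  res <- msdDiffusion(ts, sx, sy)
  floorVar <- 2 * (sx^2 + sy^2)
  expect_equal(res@msdRaw, floorVar, tolerance = 0.05)
  expect_lt(abs(res@msdCorrected), 3 * res@se)
  expect_equal(res@d, res@msdCorrected / (4 * 0.05), tolerance = 1e-12)

  still <- TrackSet(data.frame(track = 1, frame = 1:5, x = 2, y = 3),
                    dt = 0.05)
  res0 <- msdDiffusion(still)
  expect_equal(res0@msdRaw, 0)
  expect_equal(res0@d, 0)

  expect_error(msdDiffusion(TrackSet(data.frame(track = 1, frame = 1,
                                                x = 0, y = 0), 0.05)),
               "steps")
})

test_that("MSD vs lag is linear for free diffusion and matches the pooled
           estimate at lag one", {
  ts <- simulateBrownianTracks(0.8, 0.05, 300, 40, 0.03, 0.05, seed = 17)
  lagres <- msdVsLag(ts, 0.03, 0.05, maxLag = 4)
  pooled <- msdDiffusion(ts, 0.03, 0.05)
  # same pairs, same numbers at lag 1 - exactly
  expect_identical(lagres@msdRaw[1], pooled@msdRaw)
  expect_identical(lagres@se[1], pooled@se)
  expect_equal(lagres@nPairs[1], pooled@nPairs)

  # linearity: straight line through the corrected points, intercept ~ 0
  fit <- lm(msd ~ tau, data.frame(tau = lagres@lags,
                                  msd = lagres@msdCorrected))
  expect_lt(abs(coef(fit)[[1]]), 0.1 * lagres@msdRaw[1])
  expect_equal(coef(fit)[[2]] / 4, 0.8, tolerance = 0.05)

  # maxLag = 1 degenerates to the pooled estimator
  one <- msdVsLag(ts, 0.03, 0.05, maxLag = 1)
  expect_equal(one@d, pooled@d, tolerance = 1e-12)

  short <- TrackSet(data.frame(track = 1, frame = 1:2, x = c(0, 1),
                               y = c(0, 0)), 0.05)
  expect_error(msdVsLag(short, maxLag = 4), "usable lags")
})

test_that("confined motion bends the MSD curve below linear growth", {
  # harmonically confined walk: long-lag MSD saturates
  set.seed(44)
  dt <- 0.05; n <- 200; len <- 60; k <- 0.6
  tr <- do.call(rbind, lapply(seq_len(n), function(id) {
    x <- numeric(len); y <- numeric(len)
    for (i in 2:len) {
      x[i] <- (1 - k) * x[i - 1] + rnorm(1, sd = sqrt(2 * 1 * dt))
      y[i] <- (1 - k) * y[i - 1] + rnorm(1, sd = sqrt(2 * 1 * dt))
    }
    data.frame(track = id, frame = seq_len(len), x = x, y = y)
  }))
  res <- msdVsLag(TrackSet(tr, dt), maxLag = 4)
  increments <- diff(res@msdCorrected)
  expect_true(all(diff(increments) < 0))   # concave: sublinear growth
  expect_lt(res@msdCorrected[4], 4 * res@msdCorrected[1])
})

test_that("the corrected estimator recovers D with less bias", {
  # repeated simulation at D = 1: mean corrected estimate within 2 SE of
  # truth, and closer to it than the uncorrected one
  nSeeds <- 40
  est <- vapply(seq_len(nSeeds), function(s) {
    ts <- simulateBrownianTracks(1, 0.05, 500, 50, 0.033, 0.058, seed = s)
    c(msdDiffusion(ts, 0.033, 0.058)@d, msdDiffusion(ts)@d)
  }, numeric(2))
  corrected <- mean(est[1, ]); uncorrected <- mean(est[2, ])
  se <- sd(est[1, ]) / sqrt(nSeeds)
  expect_lt(abs(corrected - 1), 2 * se)
  expect_lt(abs(corrected - 1), abs(uncorrected - 1))
})

test_that("track tables round-trip and the TrackMate dialect is accepted", {
  ts <- simulateBrownianTracks(0.5, 0.05, 4, 6, 0.02, 0.02, seed = 9)
  path <- tempfile(fileext = ".csv")
  writeTrackTable(ts, path)
  back <- readTrackTable(path, dt = 0.05)
  expect_equal(tracks(back), tracks(ts), tolerance = 1e-12)

  # TrackMate-style export with its extra non-numeric header rows
  tm <- data.frame(LABEL = c("Label", "", "ID1", "ID2", "ID3"),
                   TRACK_ID = c("Track ID", "", "1", "1", "1"),
                   FRAME = c("Frame", "", "0", "1", "2"),
                   POSITION_X = c("X", "(micron)", "1.5", "1.7", "1.6"),
                   POSITION_Y = c("Y", "(micron)", "2.0", "2.1", "2.4"))
  path2 <- tempfile(fileext = ".csv")
  write.csv(tm, path2, row.names = FALSE)
  got <- readTrackTable(path2, dt = 0.05)
  expect_equal(nrow(tracks(got)), 3)
  expect_equal(tracks(got)$x, c(1.5, 1.7, 1.6))
  unlink(c(path, path2))
})
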
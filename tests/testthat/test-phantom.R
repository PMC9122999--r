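test_that("scatterer fields are deterministic with exact counts", {
  region <- c(0, 2e-3, 0, 2e-3)
  # count fixed at round(density * area): 4 mm^2 at 50 / mm^2 -> 200
  sf <- makeScattererField(c(0, 2e-3, 0, 2e-3), 50, seed = 1)
  expect_equal(nrow(sf@positions), 200L)
  # zero density: empty field
  expect_equal(nrow(makeScattererField(region, 0, seed = 7)@positions), 0L)
  # same seed twice: bit-identical
  a <- makeScattererField(region, 80, seed = 4)
  b <- makeScattererField(region, 80, seed = 4)
  expect_identical(a@positions, b@positions)
  expect_identical(a@amplitudes, b@amplitudes)
  # positions lie inside the region
  expect_true(all(a@positions[, 1] >= 0 & a@positions[, 1] <= 2e-3))
  expect_error(makeScattererField(region, -5), "nonnegative")
})

test_that("the annulus deformation is the identity at phase 0 and 1", {
  def <- annulusDeformation()
  set.seed(2)
  th <- runif(50, 0, 2 * pi)
  r <- runif(50, def@endoRadiusED, def@epiRadiusED)
  pts <- cbind(def@center[1] + r * cos(th), def@center[2] + r * sin(th))
  expect_equal(annulusDisplacement(def, 0, pts), 0 * pts)
  expect_lt(max(abs(annulusDisplacement(def, 1, pts))), 1e-12)
  expect_error(annulusDisplacement(def, 0.5, rbind(def@center)),
               "center")
})

test_that("mid-cycle endocardial displacement matches the closed form", {
  def <- annulusDeformation()
  p <- c(def@center[1] + def@endoRadiusED, def@center[2])
  u <- annulusDisplacement(def, 0.5, rbind(p))
  # at w = 1 the endocardial radius is Re0 (1 - s): purely inward
  expected <- -def@endoRadiusED * def@peakLongitudinalShortening
  expect_equal(unname(u[1, 1]), expected, tolerance = 1e-12)
  expect_equal(unname(u[1, 2]), 0, tolerance = 1e-15)
  # endocardial strains hit the configured peaks exactly
  st <- analyticStrain(def, 0.5, rbind(p))
  expect_equal(unname(st$radial), def@peakRadialThickening,
               tolerance = 1e-12)
  expect_equal(unname(st$longitudinal), -def@peakLongitudinalShortening,
               tolerance = 1e-12)
})

test_that("analytic strain equals the finite difference of displacement", {
  def <- annulusDeformation(dysfunctionAngle = pi / 4,
                            dysfunctionWidth = pi / 2)
  h <- 1e-7
  set.seed(6)
  th <- runif(20, 0, 2 * pi)
  r <- runif(20, def@endoRadiusED + 1e-5, def@epiRadiusED - 1e-5)
  pts <- cbind(def@center[1] + r * cos(th), def@center[2] + r * sin(th))
  st <- analyticStrain(def, 0.5, pts)
  dir <- cbind(cos(th), sin(th))
  uP <- annulusDisplacement(def, 0.5, pts + h * dir)
  uM <- annulusDisplacement(def, 0.5, pts - h * dir)
  fd <- rowSums((uP - uM) * dir) / (2 * h)
  expect_lt(max(abs(fd - st$radial)), 1e-5)
})

test_that("rendering is linear with the point response in the right place", {
  tp <- transducerParams()
  sf <- new("ScattererField",
            positions = rbind(c(1.00e-3, 1.02e-3)), amplitudes = 1,
            region = c(0, 2e-3, 0, 2e-3), seed = 1L)
  fr <- renderRFFrame(sf, tp)
  pk <- which(abs(fr) == max(abs(fr)), arr.ind = TRUE)[1, ]
  # frame maximum at the nearest grid sample to the scatterer
  expect_equal(unname(pk[1]),
               which.min(abs((0:(nrow(fr) - 1)) * tp@axialSpacing - 1e-3)))
  expect_equal(unname(pk[2]),
               which.min(abs((0:(ncol(fr) - 1)) * tp@lateralSpacing -
                               1.02e-3)))
  # doubling amplitudes doubles the frame exactly
  sf2 <- sf; sf2@amplitudes <- 2
  expect_equal(renderRFFrame(sf2, tp), 2 * fr, tolerance = 1e-15)
  # rendering twice with zero displacement is identical
  expect_identical(renderRFFrame(sf, tp), fr)
})

test_that("the mean axial spectrum peaks at the center frequency", {
  tp <- transducerParams()
  sf <- makeScattererField(c(0, 3e-3, 0, 3e-3), 150, seed = 2)
  fr <- renderRFFrame(sf, tp)
  spec <- rowMeans(Mod(stats::mvfft(fr))^2)
  n <- nrow(fr)
  fs <- tp@soundSpeed / tp@axialSpacing        # one-way depth-time mapping
  freqs <- (0:(n - 1)) / n * fs
  pkf <- freqs[which.max(spec[2:(n %/% 2)]) + 1]
  expect_lt(abs(pkf - tp@centerFrequency), fs / n + 1e-6)
})

test_that("simulated sequences are deterministic with a cyclic ground truth", {
  def <- annulusDeformation(center = c(1.6e-3, 1.6e-3),
                            endoRadiusED = 0.7e-3, epiRadiusED = 1.1e-3)
  a <- simulateSequence(def, nFrames = 4, densityPerMm2 = 60, seed = 5)
  b <- simulateSequence(def, nFrames = 4, densityPerMm2 = 60, seed = 5)
  expect_identical(a$series@frames, b$series@frames)
  # zero deformation: consecutive noiseless frames are identical
  def0 <- annulusDeformation(center = c(1.6e-3, 1.6e-3),
                             endoRadiusED = 0.7e-3, epiRadiusED = 1.1e-3,
                             peakRadialThickening = 0,
                             peakLongitudinalShortening = 0)
  s0 <- simulateSequence(def0, nFrames = 2, densityPerMm2 = 60,
                         noiseSNRdB = Inf, scattererReplacement = 0,
                         seed = 5)
  expect_identical(s0$series@frames[, , 1], s0$series@frames[, , 2])
  # cyclic closure of the analytic motion at a full cycle
  pts <- rbind(c(1.6e-3 + 0.9e-3, 1.6e-3))
  u <- annulusDisplacement(def, 1, pts)
  expect_lt(max(abs(u)), 1e-12)
  # the ECG carries an unambiguous R wave at each cycle start
  pk <- abrcsi:::findRPeaks(a$series@ecg$t, a$series@ecg$v)
  expect_gte(length(pk), 1)
  expect_lt(abs(pk[1]), 2e-3)
})

test_that("a pure translation moves the full-frame correlation argmax", {
  pair <- shiftPair(4, 0, sizeM = 2.5e-3)
  # full-frame cross-correlation oracle over axial lags
  lags <- -8:8
  cc <- vapply(lags, function(k) {
    if (k >= 0) {
      a <- pair$a[1:(nrow(pair$a) - k), ]
      b <- pair$b[(1 + k):nrow(pair$b), ]
    } else {
      a <- pair$a[(1 - k):nrow(pair$a), ]
      b <- pair$b[1:(nrow(pair$b) + k), ]
    }
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 4)
})

test_that("IQ demodulation round-trips the RF data", {
  def <- annulusDeformation(center = c(1.6e-3, 1.6e-3),
                            endoRadiusED = 0.7e-3, epiRadiusED = 1.1e-3)
  sim <- simulateSequence(def, nFrames = 2, densityPerMm2 = 60,
                          noiseSNRdB = Inf, scattererReplacement = 0,
                          seed = 8)
  iq <- iqDemodulate(sim$series)
  back <- iqRemodulate(iq, sim$series@transducer)
  rel <- max(abs(back - sim$series@frames)) / max(abs(sim$series@frames))
  expect_lt(rel, 1e-6)
})
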
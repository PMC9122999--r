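test_that("the NCC surface finds exact and negated copies", {
  set.seed(11)
  region <- matrix(rnorm(15 * 13), 15, 13)
  blk <- region[6:9, 5:8]      # 4 x 4 block, top-left (6, 5)
  s <- nccSurface(blk, region)
  pk <- peakValue(s)
  expect_equal(pk, 1)
  idx <- which(s@values == pk, arr.ind = TRUE)
  lag <- unname(c(idx[1, 1] + s@lagOffsets[1] - 1,
                  idx[1, 2] + s@lagOffsets[2] - 1))
  # placement (6, 5) 1-based = 0-based offset (5, 4); centered placement
  # is floor((15-4)/2) = 5, floor((13-4)/2) = 4 -> lag (0, 0)
  expect_equal(lag, c(0, 0))
  sNeg <- nccSurface(-blk, region)
  expect_equal(min(sNeg@values, na.rm = TRUE), -1)
  # zero-variance reference is flagged, not NaN-propagated
  sFlat <- nccSurface(matrix(1, 4, 4), region)
  expect_true(sFlat@flagged)
  expect_error(nccSurface(region, blk), "strictly larger")
})

test_that("optimized NCC equals the direct two-loop formula", {
  set.seed(12)
  for (k in 1:20) {
    ref <- matrix(rnorm(64), 8, 8)
    region <- matrix(rnorm(256), 16, 16)
    s <- nccSurface(ref, region)
    expect_lt(max(abs(s@values - nccOracle(ref, region))), 1e-10)
  }
  # the grid path agrees with the same oracle through the field interface
  a <- matrix(rnorm(40 * 40), 40, 40)
  b <- matrix(rnorm(40 * 40), 40, 40)
  res <- abrcsi:::cpp_ncc_field(a, b, 20L, 20L, matrix(0L, 1, 2),
                                4L, 4L, 4L, 4L)
  ref <- a[17:25, 17:25]
  oracle <- nccOracle(ref, b[13:29, 13:29])
  expect_lt(max(abs(res$surfaces[, , 1] - oracle)), 1e-10)
})

test_that("every NCC value lies within the correlation bound", {
  pair <- shiftPair(2, 1, sizeM = 2e-3)
  res <- abrcsi:::cpp_ncc_field(pair$a, pair$b,
                                as.integer(seq(20, 130, by = 10)),
                                as.integer(rep(20, 12)),
                                matrix(0L, 12, 2), 5L, 5L, 4L, 4L)
  expect_lt(max(abs(res$surfaces), na.rm = TRUE), 1 + 1e-9)
})

test_that("sinc subsample refinement locates band-limited bumps", {
  mk <- function(v) new("CorrelationSurface", values = v,
                        lagOffsets = c(-8L, -8L), flagged = FALSE)
  # symmetric surface peaked exactly at an integer lag: zero correction
  sym <- outer(-8:8, -8:8, function(a, l) exp(-(a^2 + l^2) / 6))
  r <- subsamplePeakSinc(mk(sym))
  expect_equal(r$lagAxial, 0)
  expect_equal(r$lagLateral, 0)
  # band-limited bump centered at lag (2.30, -1.20)
  bump <- outer(-8:8, -8:8, function(a, l)
    exp(-((a - 2.30)^2 + (l + 1.20)^2) / (2 * 1.8^2)))
  r <- subsamplePeakSinc(mk(bump))
  expect_lt(abs(r$lagAxial - 2.30), 0.02)
  expect_lt(abs(r$lagLateral + 1.20), 0.02)
  # stability: halved vs doubled interpolation window agree within 0.05
  rHalf <- subsamplePeakSinc(mk(bump), window = 4)
  rDouble <- subsamplePeakSinc(mk(bump), window = 16)
  expect_lt(abs(rHalf$lagAxial - rDouble$lagAxial), 0.05)
  expect_lt(abs(rHalf$lagLateral - rDouble$lagLateral), 0.05)
  # border peak returned unrefined with a flag
  edge <- matrix(0, 17, 17); edge[1, 9] <- 1
  r <- subsamplePeakSinc(mk(edge))
  expect_true(r$border)
  expect_equal(r$lagAxial, -8)
})

test_that("field median filtering matches a sort-based oracle", {
  gx <- (0:4) * 1e-4; gy <- (0:4) * 1e-4     # 0.1 mm node spacing
  mkf <- function(u) new("DisplacementField", gridAxial = gx,
                         gridLateral = gy, uAxial = u, uLateral = u,
                         corrPeak = u * 0 + 1,
                         flags = matrix(0L, 5, 5), level = 1L)
  # constant field unchanged
  cst <- matrix(2e-5, 5, 5)
  out <- medianFilterField(mkf(cst), c(0.3, 0.3), c(0.3, 0.3))
  expect_equal(out@uAxial, cst)
  # single-node outlier replaced by the constant
  one <- cst; one[3, 3] <- 9e-4
  out <- medianFilterField(mkf(one), c(0.3, 0.3), c(0.3, 0.3))
  expect_equal(out@uAxial[3, 3], 2e-5)
  # random field vs brute-force windowed median (3 x 3 window)
  set.seed(14)
  rnd <- matrix(rnorm(25), 5, 5)
  out <- medianFilterField(mkf(rnd), c(0.3, 0.3), c(0.3, 0.3))
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    ii <- max(1, i - 1):min(5, i + 1)
    jj <- max(1, j - 1):min(5, j + 1)
    oracle[i, j] <- median(rnd[ii, jj])
  }
  expect_equal(out@uAxial, oracle)
  # degenerate (sub-node) kernel is the identity
  out <- medianFilterField(mkf(rnd), c(0.05, 0.05), c(0.05, 0.05))
  expect_equal(out@uAxial, rnd)
})

test_that("identical frames give an identically zero field", {
  pair <- shiftPair(0, 0, sizeM = 2.6e-3)
  fld <- multilevelDisplacement(pair$a, pair$a, pair$tp)
  expect_true(all(fld@uAxial == 0, na.rm = TRUE))
  expect_true(all(fld@uLateral == 0, na.rm = TRUE))
  expect_equal(fld@level, 3L)
})

test_that("integer shifts are recovered exactly at interior nodes", {
  pair <- shiftPair(3, 0, sizeM = 4.4e-3)
  fld <- multilevelDisplacement(pair$a, pair$b, pair$tp)
  ua <- fld@uAxial / pair$tp@axialSpacing
  ia <- 5:(nrow(ua) - 6); il <- 3:(ncol(ua) - 3)
  expect_true(all(abs(ua[ia, il] - 3) < 1e-12))
  expect_true(all(abs(fld@uLateral[ia, il]) < 1e-12))
})

test_that("a single-level configuration reproduces the pyramid on pure shifts", {
  pair <- shiftPair(2, 0, sizeM = 3.2e-3)
  single <- trackingConfig(nLevels = 1, axialDecimation = 1,
                           lateralDecimation = 1,
                           axialKernelWavelengths = 1,
                           lateralKernelLines = 10)
  f1 <- multilevelDisplacement(pair$a, pair$b, pair$tp, single)
  f3 <- multilevelDisplacement(pair$a, pair$b, pair$tp, trackingConfig())
  # same finest-level geometry, same exact recovery at interior nodes
  ia <- 6:(length(f1@gridAxial) - 6); il <- 3:(length(f1@gridLateral) - 3)
  d1 <- f1@uAxial[ia, il] / pair$tp@axialSpacing
  d3 <- f3@uAxial[ia, il] / pair$tp@axialSpacing
  expect_true(all(abs(d1 - 2) < 1e-12))
  expect_identical(d1, d3)
})

test_that("kernel sizes honour the wavelength and A-line specification", {
  tp <- transducerParams()
  cfg <- trackingConfig()
  lam <- wavelength(tp)
  g3 <- abrcsi:::levelGeometry(tp, cfg, 3)
  # finest level: 1 wavelength = 4 samples at lambda/4 -> 5-sample kernel
  expect_equal(abrcsi:::roundUpOdd(cfg@axialKernelWavelengths[3] * lam /
                                     g3$asp, ensureMin3 = TRUE), 5L)
  # 10 A-lines at a 1:2 sampling factor -> 21 matched columns
  expect_equal(abrcsi:::roundUpOdd(cfg@lateralKernelLines[3] * 2 / g3$fl,
                                   ensureMin3 = TRUE), 21L)
  # a kernel larger than the frame is rejected
  tiny <- matrix(rnorm(30 * 8), 30, 8)
  expect_error(multilevelDisplacement(tiny, tiny, tp, cfg), "larger than")
})

test_that("tracking configuration validates its structural constraints", {
  expect_error(trackingConfig(axialDecimation = c(1, 2, 3)),
               "non-increasing")
  expect_error(trackingConfig(kernelOverlapPct = c(50, 100)), "overlaps")
  expect_error(trackingConfig(bogus = 1), "unknown tracking parameter")
  cfg <- trackingConfig()
  expect_equal(cfg@axialKernelWavelengths, c(8, 5, 1))
  expect_equal(cfg@maxAbrIterations, 10L)
})
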
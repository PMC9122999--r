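test_that("pixel classification recovers exact palette colours", {
  pal <- mtPalette()
  set.seed(21)
  lab <- matrix(sample(0:3, 400, replace = TRUE), 20, 20)
  rgb <- array(0, c(20, 20, 3))
  for (ch in 1:3) rgb[, , ch] <- matrix(pal[lab + 1L, ch], 20, 20)
  cls <- classifyPixels(rgb)
  expect_identical(cls@labels, lab)
  # pure white is background everywhere
  white <- array(1, c(5, 5, 3))
  expect_true(all(classifyPixels(white)@labels == 0L))
  # duplicate palette colours are rejected
  bad <- pal; bad[2, ] <- bad[3, ]
  expect_error(classifyPixels(rgb, palette = bad), "duplicate")
})

test_that("noisy classification beats the Monte-Carlo misclassification oracle", {
  # oracle: accuracy of the same nearest-centroid rule on pure Gaussian
  # colour clouds, computed independently of the image pathway
  pal <- mtPalette()
  sigma <- 0.05
  set.seed(31)
  nPer <- 400
  truthCls <- rep(0:3, each = nPer)
  pts <- pal[truthCls + 1L, ] + matrix(rnorm(4 * nPer * 3, sd = sigma),
                                       ncol = 3)
  pts[pts < 0] <- 0; pts[pts > 1] <- 1
  labPts <- convertColor(pts, from = "sRGB", to = "Lab")
  labRef <- convertColor(pal, from = "sRGB", to = "Lab")
  d <- sapply(1:4, function(k) rowSums(sweep(labPts, 2, labRef[k, ])^2))
  oracleAcc <- mean(max.col(-d) - 1L == truthCls)
  expect_gt(oracleAcc, 0.95)
  # synthetic slide at the same noise level reaches oracle-level accuracy
  sl <- synthWSI(size = 160, fibrosisFraction = rep(0.3, 6),
                 noiseSigma = sigma, seed = 8)
  cls <- classifyPixels(sl$rgb)
  acc <- mean(cls@labels == sl$truth@labels)
  expect_gt(acc, oracleAcc - 0.03)
})

test_that("angular six-segment division is symmetric and equivariant", {
  sl <- synthWSI(size = 200, seed = 2)
  seg <- segmentWSI(sl$truth)
  tissue <- sl$truth@labels != 0L & sl$truth@labels != 3L
  counts <- table(seg[tissue])
  expect_equal(length(counts), 6L)
  expect_lt(max(counts) / min(counts), 1.05)
  # rotating the landmarks by 60 degrees shifts labels by one segment
  ctr <- sl$landmarks$centroid
  rot <- function(p, th) {
    d <- p - ctr
    ctr + c(cos(th) * d[1] - sin(th) * d[2],
            sin(th) * d[1] + cos(th) * d[2])
  }
  lmRot <- list(base = rot(sl$landmarks$base, pi / 3),
                apex = rot(sl$landmarks$apex, pi / 3),
                centroid = ctr)
  segRot <- segmentWSI(sl$truth, lmRot)
  inWall <- sl$truth@labels %in% c(1L, 2L)
  shifted <- (seg[inWall] - 2) %% 6 + 1
  expect_gt(mean(segRot[inWall] == shifted), 0.98)
})

test_that("fibrosis painted at the apex lands in the apical segments", {
  sl <- synthWSI(size = 200, fibrosisFraction = c(0, 0, 1, 1, 0, 0),
                 seed = 3)
  seg <- segmentWSI(sl$truth)
  fib <- sl$truth@labels == 2L
  expect_gt(sum(fib & (seg == 3 | seg == 4)) / sum(fib), 0.95)
})

test_that("histology PFM follows the background-corrected formula", {
  # hand-built single-segment checks via a synthetic label image
  mkcls <- function(lab) new("ClassifiedWSI", labels = lab,
                             pixelSize = 1e-6, landmarks = list())
  lab <- matrix(2L, 10, 12)                 # all fibrotic, no background
  seg <- matrix(rep(1:6, each = 20), 10, 12)
  out <- pfmHistology(mkcls(lab), seg)
  expect_equal(out$pfm_percent, rep(100, 6))
  # 50% background, remaining half fibrotic half non-fibrotic -> 50
  lab <- matrix(0L, 10, 12)
  lab[1:5, ] <- rep(c(2L, 1L), length.out = 60)
  out <- pfmHistology(mkcls(lab), seg)
  expect_equal(out$pfm_percent, rep(50, 6))
  # all-background slide: every segment excluded
  out <- suppressWarnings(pfmHistology(mkcls(matrix(0L, 10, 12)), seg))
  expect_true(all(!out$included))
  lab1 <- matrix(1L, 10, 12); lab1[, 3:4] <- 0L   # one empty segment
  expect_warning(pfmHistology(mkcls(lab1), seg), "background")
})

test_that("noiseless slides round-trip PFM within rasterization error", {
  fr <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  sl <- synthWSI(size = 240, fibrosisFraction = fr, noiseSigma = 0, seed = 5)
  cls <- classifyPixels(sl$rgb)
  seg <- segmentWSI(cls, sl$landmarks)
  out <- pfmHistology(cls, seg)
  expect_true(all(abs(out$pfm_percent - sl$truthPFM$pfm_percent) < 0.5))
  # and the recovered values track the requested fractions
  expect_gt(cor(out$pfm_percent, fr * 100), 0.99)
})

test_that("background pixels never change a segment's PFM", {
  sl <- synthWSI(size = 160, fibrosisFraction = rep(0.25, 6), seed = 6)
  seg <- segmentWSI(sl$truth)
  base <- pfmHistology(sl$truth, seg)
  # grow the canvas with pure background on every side
  lab2 <- matrix(0L, 200, 200)
  lab2[21:180, 21:180] <- sl$truth@labels
  lm2 <- lapply(sl$landmarks, function(p) p + 20)
  cls2 <- new("ClassifiedWSI", labels = lab2, pixelSize = 1e-6,
              landmarks = lm2)
  out2 <- pfmHistology(cls2, segmentWSI(cls2, lm2))
  expect_equal(out2$pfm_percent, base$pfm_percent, tolerance = 1e-12)
})

test_that("slide generation is deterministic and rejects bad fractions", {
  a <- synthWSI(size = 80, fibrosisFraction = rep(0.2, 6),
                noiseSigma = 0.03, seed = 9)
  b <- synthWSI(size = 80, fibrosisFraction = rep(0.2, 6),
                noiseSigma = 0.03, seed = 9)
  expect_identical(a$rgb, b$rgb)
  expect_identical(a$truth@labels, b$truth@labels)
  expect_error(synthWSI(fibrosisFraction = c(rep(0.2, 5), 1.2)),
               "infeasible")
})

test_that("label images survive the PNG round trip", {
  sl <- synthWSI(size = 60, fibrosisFraction = rep(0.4, 6), seed = 12)
  path <- tempfile(fileext = ".png")
  writeLabelImage(sl$truth, path)
  back <- readLabelImage(path)
  expect_identical(back@labels, sl$truth@labels)
})
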
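test_that("ECG gating returns one R-to-R frame window", {
  ph <- reducedPhantom()
  win <- extractCycle(ph$series)
  # 0.185 s cycle at 235 fps spans ~43 frame increments
  expect_equal(win[1], 1L)
  expect_true(abs((win[2] - win[1]) - 43) <= 1)
  # hand-built ECG with R waves at 0 and 0.19 s
  tp <- transducerParams()
  times <- (0:46) / 235
  ecg <- abrcsi:::syntheticECG(0.2, 0.19)
  ser <- new("RFFrameSeries", frames = array(0, c(4, 4, 47)),
             transducer = tp, frameTimes = times, ecg = ecg,
             respiration = list())
  win <- extractCycle(ser)
  expect_true(abs((win[2] - win[1]) - 44) <= 1)
  # flat ECG is rejected
  serFlat <- ser
  serFlat@ecg <- list(t = ecg$t, v = rep(0, length(ecg$t)))
  expect_error(extractCycle(serFlat), "R waves")
})

test_that("respiratory gating skips windows with large excursion", {
  tp <- transducerParams()
  times <- (0:100) / 235
  ecg <- abrcsi:::syntheticECG(max(times) + 0.01, 0.14)
  # respiration spike during the first cycle only
  rt <- seq(0, max(times), by = 1e-3)
  rv <- ifelse(rt < 0.12, 1, 0)
  ser <- new("RFFrameSeries", frames = array(0, c(4, 4, 101)),
             transducer = tp, frameTimes = times, ecg = ecg,
             respiration = list(t = rt, v = rv))
  winAll <- extractCycle(ser)                       # no threshold: first
  winQuiet <- extractCycle(ser, respirationThreshold = 0.5)
  expect_lt(winAll[1], winQuiet[1])
  expect_gte(ser@frameTimes[winQuiet[1]], 0.14 - 1e-6)
})

test_that("mesh generation blends contours into 24,000 oriented nodes", {
  def <- annulusDeformation()
  cont <- annulusContours(def, n = 64)
  mesh <- generateMesh(cont$endo, cont$epi)
  expect_equal(nNodes(mesh), 24000L)
  d <- dim(mesh@referencePositions)
  expect_equal(d[1:2], c(40L, 600L))
  # concentric circles sampled at the mesh density: node (1, j) on the
  # endo circle, (40, j) on epi, radial direction outward
  contF <- annulusContours(def, n = 600)
  mesh <- generateMesh(contF$endo, contF$epi)
  r1 <- sqrt(rowSums(sweep(mesh@referencePositions[1, , ], 2,
                           def@center)^2))
  rN <- sqrt(rowSums(sweep(mesh@referencePositions[40, , ], 2,
                           def@center)^2))
  expect_true(all(abs(r1 - def@endoRadiusED) < 1e-9))
  expect_true(all(abs(rN - def@epiRadiusED) < 1e-9))
  out <- mesh@radialDir[1, 1, ] %*%
    (mesh@referencePositions[1, 1, ] - def@center)
  expect_gt(out, 0)
  # degenerate transmural count: mesh is exactly the two contours
  mesh2 <- generateMesh(cont$endo, cont$epi, nTransmural = 2,
                        nCircumferential = 16)
  rr <- sqrt(rowSums(sweep(mesh2@referencePositions[2, , ], 2,
                           def@center)^2))
  expect_true(all(abs(rr - def@epiRadiusED) < 1e-9))
  # contours must nest
  expect_error(generateMesh(cont$epi, cont$endo), "inside")
})

test_that("displacement accumulation is material and exact for summation", {
  cont <- annulusContours(annulusDeformation(), n = 32)
  mesh <- generateMesh(cont$endo, cont$epi, nTransmural = 6,
                       nCircumferential = 36)
  gx <- seq(0, 6e-3, length.out = 40)
  gy <- seq(0, 6e-3, length.out = 40)
  zero <- matrix(0, 40, 40)
  mkf <- function(ua, ul)
    new("DisplacementField", gridAxial = gx, gridLateral = gy,
        uAxial = ua, uLateral = ul, corrPeak = zero + 1,
        flags = matrix(0L, 40, 40), level = 3L)
  # all-zero increments leave the mesh at its reference
  m0 <- accumulateDisplacements(mesh, list(mkf(zero, zero), mkf(zero, zero)))
  expect_equal(m0@trackedPositions[, , , 3], m0@referencePositions)
  # constant increments accumulate exactly linearly
  a <- 2e-5; b <- -1e-5
  fl <- mkf(zero + a, zero + b)
  m1 <- accumulateDisplacements(mesh, list(fl, fl, fl))
  expect_equal(m1@trackedPositions[, , 1, 4],
               m1@referencePositions[, , 1] + 3 * a, tolerance = 1e-12)
  expect_equal(m1@trackedPositions[, , 2, 4],
               m1@referencePositions[, , 2] + 3 * b, tolerance = 1e-12)
  expect_true(!any(m1@outOfField))
})

test_that("trajectories from analytic increment fields match ground truth", {
  ph <- reducedPhantom()
  def <- ph$deformation
  times <- ph$series@frameTimes
  gx <- seq(0.1e-3, 4.3e-3, by = 2.5e-5)
  gy <- seq(0.1e-3, 4.3e-3, by = 4.7e-5)
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  mkf <- function(f) {
    ph1 <- (times[f] %% def@cycleDuration) / def@cycleDuration
    ph2 <- (times[f + 1] %% def@cycleDuration) / def@cycleDuration
    X <- pts - annulusDisplacement(def, ph1, pts)
    X <- pts - annulusDisplacement(def, ph1, X)
    du <- annulusDisplacement(def, ph2, X) - annulusDisplacement(def, ph1, X)
    new("DisplacementField", gridAxial = gx, gridLateral = gy,
        uAxial = matrix(du[, 1], length(gx)),
        uLateral = matrix(du[, 2], length(gx)),
        corrPeak = matrix(1, length(gx), length(gy)),
        flags = matrix(0L, length(gx), length(gy)), level = 3L)
  }
  fields <- lapply(seq_len(length(times) - 1), mkf)
  mesh <- generateMesh(ph$contours$endo, ph$contours$epi)
  mesh <- accumulateDisplacements(mesh, fields)
  ptsM <- matrix(mesh@referencePositions, ncol = 2)
  for (f in c(10, 23, 40)) {
    tru <- truthDisplacement(ph$truth, ptsM, f)
    est <- cbind(as.vector(mesh@trackedPositions[, , 1, f]) - ptsM[, 1],
                 as.vector(mesh@trackedPositions[, , 2, f]) - ptsM[, 2])
    rmse <- sqrt(mean((est - tru)^2))
    expect_lt(rmse, 1e-6)          # < 1 um against analytic trajectories
  }
})

test_that("least-squares strain is exact on affine displacement fields", {
  cont <- annulusContours(annulusDeformation(), n = 64)
  mesh <- generateMesh(cont$endo, cont$epi)
  d <- dim(mesh@referencePositions)
  tracked <- array(0, c(d[1], d[2], 2, 2))
  tracked[, , , 1] <- mesh@referencePositions
  # rigid translation: all components zero
  tracked[, , 1, 2] <- mesh@referencePositions[, , 1] + 3e-5
  tracked[, , 2, 2] <- mesh@referencePositions[, , 2] - 2e-5
  mesh@trackedPositions <- tracked
  st <- leastSquaresStrain(mesh, 2)
  expect_lt(max(abs(c(st@eAxial, st@eLateral, st@eShear)), na.rm = TRUE),
            1e-12)
  # linear axial stretch: e_axial = 0.02 exactly
  tracked[, , 1, 2] <- mesh@referencePositions[, , 1] * 1.02
  tracked[, , 2, 2] <- mesh@referencePositions[, , 2]
  mesh@trackedPositions <- tracked
  st <- leastSquaresStrain(mesh, 2)
  expect_lt(max(abs(st@eAxial - 0.02), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(st@eLateral), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(st@eShear), na.rm = TRUE), 1e-9)
})

test_that("quadratic fields are recovered within the kernel-size bound", {
  cont <- annulusContours(annulusDeformation(), n = 64)
  mesh <- generateMesh(cont$endo, cont$epi)
  d <- dim(mesh@referencePositions)
  x <- mesh@referencePositions[, , 1]; y <- mesh@referencePositions[, , 2]
  c2 <- 5                                   # u_ax = c2 * x^2
  tracked <- array(0, c(d[1], d[2], 2, 2))
  tracked[, , , 1] <- mesh@referencePositions
  tracked[, , 1, 2] <- x + c2 * x^2
  tracked[, , 2, 2] <- y
  mesh@trackedPositions <- tracked
  st <- leastSquaresStrain(mesh, 2)
  # analytic gradient 2 c2 x; plane-fit bias is O(c2 * kernel extent)
  bound <- 2 * c2 * 0.5e-3                  # lateral kernel dominates
  err <- abs(st@eAxial - 2 * c2 * x)
  expect_lt(median(err, na.rm = TRUE), bound)
})

test_that("the cardiac transform projects and preserves the trace", {
  mesh <- analyticTrackedMesh()
  st <- leastSquaresStrain(mesh, selectESFrame(mesh))
  stc <- toCardiac(st, mesh)
  tr1 <- st@eAxial + st@eLateral
  tr2 <- stc@eRadial + stc@eLongitudinal
  expect_lt(max(abs(tr1 - tr2), na.rm = TRUE), 1e-9)
  # isotropic tensor: both cardiac components equal the scalar
  iso <- st
  iso@eAxial[] <- 0.07; iso@eLateral[] <- 0.07; iso@eShear[] <- 0
  isoC <- toCardiac(iso, mesh)
  expect_lt(max(abs(isoC@eRadial - 0.07), na.rm = TRUE), 1e-12)
  expect_lt(max(abs(isoC@eLongitudinal - 0.07), na.rm = TRUE), 1e-12)
  # radial direction aligned with the axial axis: e_radial == e_axial
  d <- dim(mesh@referencePositions)
  rd <- array(0, c(d[1], d[2], 2)); rd[, , 1] <- 1
  ld <- array(0, c(d[1], d[2], 2)); ld[, , 2] <- 1
  mesh2 <- mesh; mesh2@radialDir <- rd; mesh2@longitudinalDir <- ld
  ax <- toCardiac(st, mesh2)
  expect_equal(ax@eRadial, st@eAxial)
})

test_that("analytic mesh tracking recovers thickening and shortening", {
  mesh <- analyticTrackedMesh()
  ph <- reducedPhantom()
  es <- selectESFrame(mesh)
  st <- toCardiac(leastSquaresStrain(mesh, es), mesh)
  pts <- matrix(mesh@referencePositions, ncol = 2)
  tru <- truthStrain(ph$truth, pts, es)
  er <- as.vector(st@eRadial)
  el <- as.vector(st@eLongitudinal)
  expect_gt(cor(er, tru$radial, use = "complete.obs"), 0.95)
  expect_lt(mean(abs(er - tru$radial), na.rm = TRUE), 0.01)
  expect_gt(mean(er, na.rm = TRUE), 0)      # thickening is positive
  expect_lt(mean(el, na.rm = TRUE), 0)      # shortening is negative
})

test_that("rigid motion of the whole mesh produces negligible strain", {
  mesh <- analyticTrackedMesh()
  d <- dim(mesh@referencePositions)
  th <- 0.002                                # small rotation, rad
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pts <- matrix(mesh@referencePositions, ncol = 2)
  ctr <- colMeans(pts)
  moved <- sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr + c(1e-4, -5e-5), "+")
  tracked <- array(0, c(d[1], d[2], 2, 2))
  tracked[, , , 1] <- mesh@referencePositions
  tracked[, , , 2] <- array(moved, c(d[1], d[2], 2))
  mesh@trackedPositions <- tracked
  st <- leastSquaresStrain(mesh, 2)
  # infinitesimal strain of a pure rotation is O(theta^2) plus fit error
  expect_lt(max(abs(c(st@eAxial, st@eLateral)), na.rm = TRUE), 1e-3)
})
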
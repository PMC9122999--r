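# Shared fixtures, built once per session and cached.  All phantom sizes
# here are reduced validation geometries (small annulus, small field of
# view) so the whole suite stays desk-scale; the generator physics and the
# tracking configuration are the package defaults.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## small speckle frame pair with a known integer + fractional shift
shiftPair <- function(shiftAxial, shiftLateral = 0, seed = 3,
                      sizeM = 4.4e-3, density = 150) {
  tp <- transducerParams()
  sf <- makeScattererField(c(0, sizeM, 0, sizeM), density, seed = seed)
  f1 <- renderRFFrame(sf, tp)
  u <- cbind(rep(shiftAxial * tp@axialSpacing, nrow(sf@positions)),
             rep(shiftLateral * tp@lateralSpacing, nrow(sf@positions)))
  f2 <- renderRFFrame(sf, tp, u)
  list(a = f1, b = f2, tp = tp)
}

## reduced noiseless contraction phantom shared by kinematics/pipeline tests
reducedPhantom <- function() {
  fixture("reducedPhantom", function() {
    def <- annulusDeformation(center = c(2.2e-3, 2.2e-3),
                              endoRadiusED = 1.0e-3, epiRadiusED = 1.7e-3)
    sim <- simulateSequence(def, transducerParams(), noiseSNRdB = Inf,
                            scattererReplacement = 0, seed = 11)
    cont <- annulusContours(def, n = 64)
    c(sim, list(deformation = def, contours = cont))
  })
}

## analytic mesh tracking on the reduced phantom (no RF tracking): mesh
## moved by the exact deformation, for ES-selection and strain tests
analyticTrackedMesh <- function() {
  fixture("analyticTrackedMesh", function() {
    ph <- reducedPhantom()
    mesh <- generateMesh(ph$contours$endo, ph$contours$epi)
    d <- dim(mesh@referencePositions)
    nFr <- length(ph$series@frameTimes)
    tracked <- array(0, c(d[1], d[2], 2, nFr))
    pts <- matrix(mesh@referencePositions, ncol = 2)
    for (f in seq_len(nFr)) {
      u <- truthDisplacement(ph$truth, pts, f)
      tracked[, , , f] <- array(pts + u, c(d[1], d[2], 2))
    }
    mesh@trackedPositions <- tracked
    mesh
  })
}

## small dysfunctional-quadrant phantom run end-to-end once per session;
## the akinetic arc (90 degrees wide) is centered at angle pi/2, i.e. in
## segment 2 (anterior mid) of the contour-anchored segmentation
quadrantRun <- function() {
  fixture("quadrantRun", function() {
    def <- annulusDeformation(center = c(2.2e-3, 2.2e-3),
                              endoRadiusED = 1.0e-3, epiRadiusED = 1.7e-3,
                              dysfunctionAngle = pi / 2,
                              dysfunctionWidth = pi / 2)
    sim <- simulateSequence(def, transducerParams(), noiseSNRdB = Inf,
                            scattererReplacement = 0, seed = 21)
    cont <- annulusContours(def, n = 64)
    res <- runPipeline(sim$series, cont$endo, cont$epi)
    res$truth <- sim$truth
    res$deformation <- def
    res
  })
}

## brute-force NCC oracle: direct two-loop sum formula
nccOracle <- function(ref, region) {
  nr <- nrow(region) - nrow(ref) + 1
  nc <- ncol(region) - ncol(ref) + 1
  out <- matrix(NA_real_, nr, nc)
  rm <- mean(ref)
  rd <- ref - rm
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      blk <- region[i:(i + nrow(ref) - 1), j:(j + ncol(ref) - 1)]
      bd <- blk - mean(blk)
      out[i, j] <- sum(rd * bd) / sqrt(sum(rd^2) * sum(bd^2))
    }
  }
  out
}
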
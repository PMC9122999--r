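#' Extract one gated cardiac cycle
#'
#' Detects R waves in the ECG trace and returns the frame window spanning
#' one consecutive R-to-R interval: the first frame at or after the first
#' R wave through the last frame strictly before the next. When a
#' respiration trace is present, candidate windows during which the
#' respiratory excursion (absolute deviation from the trace median)
#' exceeds \code{respirationThreshold} are skipped in favour of the next
#' quiet window.
#'
#' @param series an \linkS4class{RFFrameSeries}
#' @param respirationThreshold excursion threshold (same units as the
#'   respiration trace); ignored when no respiration trace is present
#' @return integer c(startFrame, endFrame), 1-based inclusive
#' @export
extractCycle <- function(series, respirationThreshold = NULL) {
  ecg <- series@ecg
  pk <- findRPeaks(ecg$t, ecg$v)
  if (length(pk) < 2)
    stop("fewer than 2 R waves detected: cannot gate a cycle")
  resp <- series@respiration
  for (w in seq_len(length(pk) - 1)) {
    t0 <- pk[w]; t1 <- pk[w + 1]
    frames <- which(series@frameTimes >= t0 - 1e-9 &
                      series@frameTimes < t1 - 1e-9)
    if (length(frames) < 2) next
    if (length(resp) && !is.null(respirationThreshold)) {
      sel <- resp$t >= t0 & resp$t < t1
      exc <- abs(resp$v[sel] - median(resp$v))
      if (length(exc) && max(exc) > respirationThreshold) next
    }
    return(c(frames[1], frames[length(frames)]))
  }
  stop("no quiet cardiac cycle found within the series")
}

## Local-maximum R wave detection with a refractory separation of 30 ms.
findRPeaks <- function(t, v) {
  if (max(v) - min(v) < 1e-9) return(numeric(0))
  thr <- min(v) + 0.5 * (max(v) - min(v))
  n <- length(v)
  vp <- c(-Inf, v, -Inf)              # admit endpoint maxima
  cand <- which(v >= thr)
  cand <- cand[v[cand] >= vp[cand] & v[cand] >= vp[cand + 2]]
  if (!length(cand)) return(numeric(0))
  keep <- cand[1]
  for (i in cand[-1]) {
    if (t[i] - t[keep[length(keep)]] < 0.03) {
      if (v[i] > v[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  t[keep]
}

#' Generate the end-diastolic myocardial mesh
#'
#' Resamples the endocardial and epicardial contours to
#' \code{nCircumferential} arc-length-uniform points starting at their
#' anchor vertices and blends them linearly across \code{nTransmural}
#' transmural stations (defaults 40 x 600 = 24,000 material points). The
#' local radial direction of a circumferential station is the unit
#' endo-to-epi vector; the longitudinal direction is its in-plane
#' perpendicular oriented along increasing circumferential index.
#'
#' @param endo,epi closed contours, n x 2 matrices of (axial, lateral) m
#' @param nTransmural,nCircumferential mesh dimensions
#' @param endoAnchor,epiAnchor vertex index of the anterior-basal anchor
#' @return a \linkS4class{MyocardialMesh}
#' @export
#' @examples
#' cont <- annulusContours(annulusDeformation())
#' mesh <- generateMesh(cont$endo, cont$epi)
#' nNodes(mesh)    # 24000
generateMesh <- function(endo, epi, nTransmural = 40,
                         nCircumferential = 600,
                         endoAnchor = 1, epiAnchor = 1) {
  endo <- rbindPoints(endo); epi <- rbindPoints(epi)
  if (nrow(endo) < 8 || nrow(epi) < 8)
    stop("contours need at least 8 points")
  if (!all(pointsInPolygon(endo, epi)))
    stop("endocardial contour must lie strictly inside the epicardial one")
  eC <- resampleClosed(endo, nCircumferential, endoAnchor)
  pC <- resampleClosed(epi, nCircumferential, epiAnchor)
  ## transmural lines of a star-shaped wall must keep consistent angular
  ## order about the wall centroid
  ctr <- colMeans(pC)
  angE <- atan2(eC[, 2] - ctr[2], eC[, 1] - ctr[1])
  angP <- atan2(pC[, 2] - ctr[2], pC[, 1] - ctr[1])
  d <- atan2(sin(angE - angP), cos(angE - angP))
  if (any(abs(d) > pi / 2))
    stop("transmural lines cross: wall is not star-shaped")
  nT <- nTransmural; nC <- nCircumferential
  ref <- array(0, c(nT, nC, 2))
  frac <- if (nT > 1) (0:(nT - 1)) / (nT - 1) else 0
  for (i in seq_len(nT))
    ref[i, , ] <- eC + frac[i] * (pC - eC)
  rdir <- pC - eC
  rn <- sqrt(rowSums(rdir^2))
  if (any(rn < 1e-12)) stop("coincident endo/epi points")
  rdir <- rdir / rn
  ldir <- cbind(-rdir[, 2], rdir[, 1])
  mid <- (eC + pC) / 2
  tangent <- mid[c(2:nC, 1), ] - mid[c(nC, 1:(nC - 1)), ]
  flip <- rowSums(ldir * tangent) < 0
  ldir[flip, ] <- -ldir[flip, ]
  rArr <- lArr <- array(0, c(nT, nC, 2))
  for (i in seq_len(nT)) { rArr[i, , ] <- rdir; lArr[i, , ] <- ldir }
  new("MyocardialMesh", referencePositions = ref,
      trackedPositions = array(0, c(0, 0, 0, 0)),
      radialDir = rArr, longitudinalDir = lArr,
      outOfField = matrix(FALSE, nT, nC))
}

## Arc-length-uniform resampling of a closed polygon to n points starting
## at the anchor vertex.
resampleClosed <- function(p, n, anchor = 1) {
  m <- nrow(p)
  ord <- c(anchor:m, seq_len(anchor - 1))
  p <- p[ord, , drop = FALSE]
  pc <- rbind(p, p[1, ])
  seg <- sqrt(rowSums(diff(pc)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[m + 1]
  s <- total * (0:(n - 1)) / n
  i <- pmin(findInterval(s, cum, rightmost.closed = TRUE), m)
  t <- (s - cum[i]) / pmax(seg[i], 1e-300)
  pc[i, , drop = FALSE] + t * (pc[i + 1, , drop = FALSE] - pc[i, , drop = FALSE])
}

#' Accumulate incremental displacements over the cycle
#'
#' Material tracking of every mesh point: the position at frame t+1 is the
#' position at frame t plus the bilinear interpolation of the t -> t+1
#' incremental displacement field at the current (deformed) position.
#' Points whose trajectory leaves the displacement grid are frozen at
#' their last valid position and flagged in \code{outOfField}.
#'
#' @param mesh a \linkS4class{MyocardialMesh}
#' @param fields list of \linkS4class{DisplacementField}, one per
#'   consecutive frame pair of the gated window
#' @return the mesh with \code{trackedPositions} filled
#'   (nT x nC x 2 x (length(fields) + 1); frame 1 is the reference)
#' @export
accumulateDisplacements <- function(mesh, fields) {
  d <- dim(mesh@referencePositions)
  nT <- d[1]; nC <- d[2]
  nFr <- length(fields) + 1
  tracked <- array(0, c(nT, nC, 2, nFr))
  tracked[, , , 1] <- mesh@referencePositions
  oob <- matrix(FALSE, nT, nC)
  px <- as.vector(mesh@referencePositions[, , 1])
  py <- as.vector(mesh@referencePositions[, , 2])
  for (f in seq_along(fields)) {
    fl <- fields[[f]]
    ua <- interpGrid(fl@gridAxial, fl@gridLateral, naToZero(fl@uAxial),
                     px, py)
    ul <- interpGrid(fl@gridAxial, fl@gridLateral, naToZero(fl@uLateral),
                     px, py)
    newOob <- matrix(attr(ua, "clamped") | attr(ul, "clamped"), nT, nC)
    oob <- oob | newOob
    ua[oob] <- 0; ul[oob] <- 0          # frozen points stop moving
    px <- px + as.numeric(ua)
    py <- py + as.numeric(ul)
    tracked[, , 1, f + 1] <- px
    tracked[, , 2, f + 1] <- py
  }
  mesh@trackedPositions <- tracked
  mesh@outOfField <- oob
  mesh
}

#' Least-squares Lagrangian strain estimation
#'
#' Fits, for every mesh node, a displacement plane u(x) = u0 + G x over
#' the nodes inside a physical window centered on it (default
#' 0.06 x 0.5 mm, axial x lateral) and reports the symmetric displacement
#' gradient: e_axial = G_aa, e_lateral = G_ll, e_shear =
#' (G_al + G_la) / 2, all with respect to the end-diastolic reference
#' configuration. With \code{greenLagrange = TRUE} the quadratic
#' Green-Lagrange form E = (F'F - I) / 2 is used instead. Rank-deficient
#' neighbourhoods are flagged invalid.
#'
#' @param mesh a tracked \linkS4class{MyocardialMesh}
#' @param frame frame index into the tracked positions
#' @param lsqKernelMm physical window (axial, lateral), mm
#' @param greenLagrange use the quadratic strain form
#' @return a \linkS4class{StrainTensorField} (cartesian components only)
#' @export
leastSquaresStrain <- function(mesh, frame, lsqKernelMm = c(0.06, 0.5),
                               greenLagrange = FALSE) {
  if (length(mesh@trackedPositions) == 0)
    stop("mesh has no tracked positions; run accumulateDisplacements first")
  d <- dim(mesh@referencePositions)
  nT <- d[1]; nC <- d[2]
  posA <- mesh@referencePositions[, , 1]
  posL <- mesh@referencePositions[, , 2]
  uA <- mesh@trackedPositions[, , 1, frame] - posA
  uL <- mesh@trackedPositions[, , 2, frame] - posL
  ok <- !mesh@outOfField
  halfAx <- lsqKernelMm[1] * 1e-3 / 2
  halfLat <- lsqKernelMm[2] * 1e-3 / 2
  ## index search radii: generous cover of the physical window given the
  ## local node spacings
  spT <- median(sqrt(diff(posA)^2 + diff(posL)^2))
  circA <- posA[1, c(2:nC, 1)] - posA[1, ]
  circL <- posL[1, c(2:nC, 1)] - posL[1, ]
  spC <- median(sqrt(circA^2 + circL^2))
  radT <- min(nT - 1, ceiling(max(halfAx, halfLat) / max(spT, 1e-9)) + 1)
  radC <- min(nC %/% 2, ceiling(max(halfAx, halfLat) / max(spC, 1e-9)) + 1)
  fit <- cpp_lsq_strain(posA, posL, uA, uL, ok, halfAx, halfLat,
                        as.integer(radT), as.integer(radC))
  if (greenLagrange) {
    Faa <- fit$duA_dA + 1; Fal <- fit$duA_dL
    Fla <- fit$duL_dA;     Fll <- fit$duL_dL + 1
    eAx <- (Faa^2 + Fla^2 - 1) / 2
    eLat <- (Fal^2 + Fll^2 - 1) / 2
    eSh <- (Faa * Fal + Fla * Fll) / 2
  } else {
    eAx <- fit$duA_dA
    eLat <- fit$duL_dL
    eSh <- (fit$duA_dL + fit$duL_dA) / 2
  }
  bad <- !fit$valid
  eAx[bad] <- NA; eLat[bad] <- NA; eSh[bad] <- NA
  new("StrainTensorField", eAxial = eAx, eLateral = eLat, eShear = eSh,
      eRadial = matrix(numeric(0), 0, 0),
      eLongitudinal = matrix(numeric(0), 0, 0),
      valid = fit$valid & ok, frameIndex = as.integer(frame))
}

#' Cartesian to cardiac coordinate transformation
#'
#' Projects the 2 x 2 cartesian strain tensor of every node onto the local
#' wall directions: e_radial = r' E r and e_longitudinal = l' E l with r
#' the transmural and l the along-wall unit vector. Positive radial strain
#' is wall thickening; negative longitudinal strain is wall shortening.
#' The transformation preserves the tensor trace at every node.
#'
#' @param strain a \linkS4class{StrainTensorField}
#' @param mesh the matching \linkS4class{MyocardialMesh}
#' @return the strain field with \code{eRadial} / \code{eLongitudinal} set
#' @export
toCardiac <- function(strain, mesh) {
  r1 <- mesh@radialDir[, , 1]; r2 <- mesh@radialDir[, , 2]
  l1 <- mesh@longitudinalDir[, , 1]; l2 <- mesh@longitudinalDir[, , 2]
  E11 <- strain@eAxial; E22 <- strain@eLateral; E12 <- strain@eShear
  strain@eRadial <- r1^2 * E11 + 2 * r1 * r2 * E12 + r2^2 * E22
  strain@eLongitudinal <- l1^2 * E11 + 2 * l1 * l2 * E12 + l2^2 * E22
  strain
}
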
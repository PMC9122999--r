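#' Tracking configuration constructor
#'
#' Returns a \linkS4class{TrackingConfig} with the default murine RF
#' displacement-estimation settings (see the class documentation). Any
#' field can be overridden; shortened per-level vectors (for example a
#' single-level configuration) are accepted as long as lengths agree with
#' \code{nLevels}.
#'
#' @param nLevels number of pyramid levels
#' @param ... named slot overrides, see \linkS4class{TrackingConfig}
#' @return a \linkS4class{TrackingConfig}
#' @export
#' @examples
#' cfg <- trackingConfig()                       # murine RF defaults
#' single <- trackingConfig(nLevels = 1,
#'   axialDecimation = 1, lateralDecimation = 1,
#'   axialKernelWavelengths = 1, lateralKernelLines = 10)
trackingConfig <- function(nLevels = 3, ...) {
  defaults <- list(
    rfSamplingFactor = c(1L, 2L),
    axialDecimation = c(3L, 2L, 1L),
    lateralDecimation = c(2L, 1L, 1L),
    axialKernelWavelengths = c(8, 5, 1),
    lateralKernelLines = c(15, 12, 10),
    kernelOverlapPct = c(50, 90),
    axialMedianKernelMm = c(0.13, 0.41),
    lateralMedianKernelMm = c(0.30, 0.90),
    lsqKernelMm = c(0.06, 0.5),
    searchMargin = cbind(c(8L, 8L), c(6L, 8L), c(5L, 8L)),
    maxAbrIterations = 10L,
    abrGamma = 2, abrSigma = 1, abrSnrStop = 10,
    subsampleResolution = 0.01, lateralRefinement = "joint",
    applyAbr = TRUE, applyMedian = TRUE, greenLagrange = FALSE)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown tracking parameter(s): ",
                        paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  intSlots <- c("rfSamplingFactor", "axialDecimation", "lateralDecimation",
                "maxAbrIterations")
  for (s in intSlots) defaults[[s]] <- as.integer(defaults[[s]])
  sm <- defaults$searchMargin
  if (is.null(dim(sm))) sm <- matrix(sm, 2, nLevels)   # one margin per axis
  if (ncol(sm) != nLevels) {
    if (!("searchMargin" %in% names(over))) {
      sm <- matrix(c(8L, 8L), 2, nLevels)   # non-default level counts
    } else if (ncol(sm) == 1) {
      sm <- sm[, rep(1, nLevels), drop = FALSE]
    } else stop("searchMargin must have one column per level")
  }
  storage.mode(sm) <- "integer"
  defaults$searchMargin <- sm
  do.call(new, c(list("TrackingConfig", nLevels = as.integer(nLevels)),
                 defaults))
}

#' 2-D normalized cross-correlation surface
#'
#' Zero-normalized cross-correlation coefficient of a reference block
#' against every admissible placement inside a strictly larger search
#' region. Lag (0, 0) corresponds to the centered placement of the block
#' in the region.
#'
#' @param referenceBlock numeric matrix
#' @param searchRegion numeric matrix, strictly larger in both axes
#' @return a \linkS4class{CorrelationSurface}
#' @export
nccSurface <- function(referenceBlock, searchRegion) {
  if (nrow(searchRegion) <= nrow(referenceBlock) ||
      ncol(searchRegion) <= ncol(referenceBlock))
    stop("search region must be strictly larger than the reference block")
  vals <- cpp_ncc_surface(referenceBlock, searchRegion)
  flagged <- all(is.na(vals))
  off <- -c(floor((nrow(searchRegion) - nrow(referenceBlock)) / 2),
            floor((ncol(searchRegion) - ncol(referenceBlock)) / 2))
  new("CorrelationSurface", values = vals, lagOffsets = as.integer(off),
      flagged = flagged)
}

## Integer argmax with deterministic tie-breaking: smallest lag magnitude,
## then axial-first ordering.  `m` indexed by (lagA, lagL) grid; offs gives
## the lag of m[1, 1].  Returns c(lagA, lagL) or NULL when all-NA.
peakLag <- function(m, offs) {
  mx <- suppressWarnings(max(m, na.rm = TRUE))
  if (!is.finite(mx)) return(NULL)
  idx <- which(m == mx)
  if (length(idx) > 1) {
    la <- (idx - 1) %% nrow(m) + offs[1]
    ll <- (idx - 1) %/% nrow(m) + offs[2]
    idx <- idx[order(la^2 + ll^2, la, ll)][1]
  } else idx <- idx[1]
  c((idx - 1) %% nrow(m) + offs[1], (idx - 1) %/% nrow(m) + offs[2])
}

#' Subsample peak location by 2-D sinc interpolation
#'
#' Whittaker (2-D sinc) interpolation of the correlation surface in a
#' window around its integer peak; the interpolated argmax is located by
#' staged grid refinement down to \code{refinementResolution} lags and is
#' constrained to one lag around the integer peak. A peak on the surface
#' border is returned unrefined with \code{border = TRUE}.
#'
#' @param surface a \linkS4class{CorrelationSurface}
#' @param refinementResolution refinement step, lags
#' @param window half-width of the interpolation window, lags
#' @return list with \code{lagAxial}, \code{lagLateral} (fractional lags)
#'   and \code{border}
#' @export
subsamplePeakSinc <- function(surface, refinementResolution = 0.01,
                              window = 8) {
  pk <- peakLag(surface@values, surface@lagOffsets)
  if (is.null(pk)) stop("surface has no finite values")
  pr <- pk[1] - surface@lagOffsets[1]        # 0-based grid row
  pc <- pk[2] - surface@lagOffsets[2]
  onBorder <- pr == 0 || pr == nrow(surface@values) - 1 ||
    pc == 0 || pc == ncol(surface@values) - 1
  if (onBorder)
    return(list(lagAxial = pk[1], lagLateral = pk[2], border = TRUE))
  fr <- cpp_sinc_peak(surface@values, pr, pc, as.integer(window),
                      refinementResolution)
  list(lagAxial = pk[1] + fr[1], lagLateral = pk[2] + fr[2],
       border = FALSE)
}

#' Median filtering of a displacement field
#'
#' Component-wise 2-D median over node windows obtained by converting the
#' physical kernel (mm) to an odd number of nodes given the node spacing;
#' edge windows are truncated. The default kernels differ per component:
#' 0.13 x 0.41 mm for the axial and 0.30 x 0.90 mm for the lateral
#' displacement component.
#'
#' @param field a \linkS4class{DisplacementField}
#' @param axialKernelMm,lateralKernelMm (axial, lateral) kernel extents, mm
#' @return the filtered \linkS4class{DisplacementField}
#' @export
medianFilterField <- function(field, axialKernelMm = c(0.13, 0.41),
                              lateralKernelMm = c(0.30, 0.90)) {
  sp <- gridSpacing(field)
  win <- function(kmm) c(roundToOdd(kmm[1] * 1e-3 / sp[1]),
                         roundToOdd(kmm[2] * 1e-3 / sp[2]))
  wa <- win(axialKernelMm); wl <- win(lateralKernelMm)
  field@uAxial <- cpp_median2d(field@uAxial, (wa[1] - 1) %/% 2,
                               (wa[2] - 1) %/% 2)
  field@uLateral <- cpp_median2d(field@uLateral, (wl[1] - 1) %/% 2,
                                 (wl[2] - 1) %/% 2)
  field
}

gridSpacing <- function(field) {
  c(if (length(field@gridAxial) > 1) diff(field@gridAxial[1:2]) else 1,
    if (length(field@gridLateral) > 1) diff(field@gridLateral[1:2]) else 1)
}

## Per-level sampling geometry after lateral upsampling and decimation.
levelGeometry <- function(transducer, config, level) {
  fu <- config@rfSamplingFactor[2] / config@rfSamplingFactor[1]
  fa <- config@axialDecimation[level]
  fl <- config@lateralDecimation[level]
  asp0 <- transducer@axialSpacing
  lsp0 <- transducer@lateralSpacing / fu
  list(fa = fa, fl = fl, asp = asp0 * fa, lsp = lsp0 * fl,
       axOrigin = (fa - 1) / 2 * asp0, latOrigin = (fl - 1) / 2 * lsp0)
}

#' Multi-level block-matching displacement estimation
#'
#' Estimates the inter-frame displacement field from frame A to frame B by
#' coarse-to-fine normalized cross-correlation block matching: A-lines are
#' first band-limited upsampled by the lateral RF sampling factor; each
#' pyramid level runs on boxcar-decimated frames, centers its lag search
#' on the upsampled estimate of the coarser level, regularizes the
#' correlation surfaces with adaptive Bayesian iterations, extracts peaks
#' with 2-D sinc subsample refinement, and median-filters the field.
#' Kernel sizes are converted from wavelengths / A-lines to (odd) sample
#' counts per level; node spacing is the kernel size times one minus the
#' overlap.
#'
#' @param frameA,frameB numeric matrices (axial samples x A-lines)
#' @param transducer the \linkS4class{TransducerParams} of the frames
#' @param config a \linkS4class{TrackingConfig}
#' @param prior optional \linkS4class{DisplacementField} seeding the
#'   coarsest level's search centers
#' @param roi optional c(axialMin, axialMax, lateralMin, lateralMax) in
#'   meters restricting the node grid
#' @param returnAll return the per-level list instead of the finest field
#' @return the finest-level \linkS4class{DisplacementField} (or a list of
#'   all levels)
#' @export
multilevelDisplacement <- function(frameA, frameB, transducer,
                                   config = trackingConfig(),
                                   prior = NULL, roi = NULL,
                                   returnAll = FALSE) {
  stopifnot(identical(dim(frameA), dim(frameB)))
  validObject(config)
  fu <- config@rfSamplingFactor[2] / config@rfSamplingFactor[1]
  A0 <- fftUpsampleCols(frameA, fu)
  B0 <- fftUpsampleCols(frameB, fu)
  ## axially decimated levels match on the envelope: the RF carrier is not
  ## representable below ~4 samples per cycle, while the envelope carries
  ## the speckle structure at any decimation
  if (any(config@axialDecimation > 1)) {
    EA0 <- axialEnvelope(A0)
    EB0 <- axialEnvelope(B0)
  }
  lam <- wavelength(transducer)
  fields <- vector("list", config@nLevels)
  prev <- prior
  for (l in seq_len(config@nLevels)) {
    g <- levelGeometry(transducer, config, l)
    if (g$fa > 1) {
      Al <- decimate2d(EA0, g$fa, g$fl)
      Bl <- decimate2d(EB0, g$fa, g$fl)
    } else {
      Al <- decimate2d(A0, g$fa, g$fl)
      Bl <- decimate2d(B0, g$fa, g$fl)
    }
    kA <- roundUpOdd(config@axialKernelWavelengths[l] * lam / g$asp,
                     ensureMin3 = TRUE)
    kL <- roundUpOdd(config@lateralKernelLines[l] * fu / g$fl,
                     ensureMin3 = TRUE)
    if (kA > nrow(Al) || kL > ncol(Al))
      stop(sprintf("level %d kernel (%d x %d) larger than frame (%d x %d)",
                   l, kA, kL, nrow(Al), ncol(Bl)))
    khA <- (kA - 1L) %/% 2L
    khL <- (kL - 1L) %/% 2L
    stepA <- max(1, round(kA * (1 - config@kernelOverlapPct[1] / 100)))
    stepL <- max(1, round(kL * (1 - config@kernelOverlapPct[2] / 100)))
    rows <- seq(khA, nrow(Al) - 1 - khA, by = stepA)   # 0-based centers
    cols <- seq(khL, ncol(Al) - 1 - khL, by = stepL)
    axPos <- g$axOrigin + rows * g$asp
    latPos <- g$latOrigin + cols * g$lsp
    if (!is.null(roi)) {
      ri <- axPos >= roi[1] & axPos <= roi[2]
      ci <- latPos >= roi[3] & latPos <= roi[4]
      if (any(ri)) { rows <- rows[ri]; axPos <- axPos[ri] }
      if (any(ci)) { cols <- cols[ci]; latPos <- latPos[ci] }
    }
    nr <- length(rows); nc <- length(cols)
    nodeR <- rep(rows, times = nc)
    nodeC <- rep(cols, each = nr)
    priorLag <- matrix(0L, nr * nc, 2)
    if (!is.null(prev)) {
      qx <- rep(axPos, times = nc)
      qy <- rep(latPos, each = nr)
      ua <- interpGrid(prev@gridAxial, prev@gridLateral,
                       naToZero(prev@uAxial), qx, qy)
      ul <- interpGrid(prev@gridAxial, prev@gridLateral,
                       naToZero(prev@uLateral), qx, qy)
      priorLag[, 1] <- as.integer(round(ua / g$asp))
      priorLag[, 2] <- as.integer(round(ul / g$lsp))
    }
    mAx <- config@searchMargin[1, l]
    mLat <- config@searchMargin[2, l]
    res <- cpp_ncc_field(Al, Bl, as.integer(nodeR), as.integer(nodeC),
                         priorLag, khA, khL, mAx, mLat)
    surf <- res$surfaces
    sd3 <- dim(surf)
    post <- surf
    if (config@applyAbr && config@maxAbrIterations > 0) {
      q <- cpp_surface_quality(surf)
      dec <- 1 - q$peak
      iters <- ifelse(!is.finite(dec) | !is.finite(q$snr) |
                        q$snr >= config@abrSnrStop | dec <= 0, 0,
                      pmin(config@maxAbrIterations,
                           round(config@maxAbrIterations * pmin(1, dec) *
                                   (1 - q$snr / config@abrSnrStop))))
      if (any(iters > 0)) {
        lik <- cpp_lik_from_ncc(surf, config@abrGamma)
        ab <- cpp_abr(lik, nr, nc, as.integer(iters), config@abrSigma)
        post <- ab$posterior
        dim(post) <- sd3
        post[is.na(surf)] <- NA       # keep inadmissible lags out
      }
    }
    lmode <- match(config@lateralRefinement,
                   c("joint", "row", "pooled", "blend")) - 1L
    ex <- cpp_extract_peaks(post, surf, mAx, mLat, 8L,
                            config@subsampleResolution, lmode)
    flags <- matrix(as.integer(ifelse(res$flag == 1L, 1L, ex$flag)), nr, nc)
    uA <- matrix((priorLag[, 1] + ex$lagA) * g$asp, nr, nc)
    uL <- matrix((priorLag[, 2] + ex$lagL) * g$lsp, nr, nc)
    uA[flags == 1L] <- NA
    uL[flags == 1L] <- NA
    pk <- matrix(ex$peak, nr, nc)
    field <- new("DisplacementField", gridAxial = axPos,
                 gridLateral = latPos, uAxial = uA, uLateral = uL,
                 corrPeak = pk, flags = flags, level = as.integer(l))
    if (config@applyMedian)
      field <- medianFilterField(field, config@axialMedianKernelMm,
                                 config@lateralMedianKernelMm)
    fields[[l]] <- field
    prev <- field
  }
  if (returnAll) fields else fields[[config@nLevels]]
}

naToZero <- function(m) { m[is.na(m)] <- 0; m }

#' Track every consecutive frame pair of a series
#'
#' @param series an \linkS4class{RFFrameSeries}
#' @param config a \linkS4class{TrackingConfig}
#' @param window c(firstFrame, lastFrame) to track (default: all frames)
#' @param roi optional node-grid restriction, as in
#'   \code{\link{multilevelDisplacement}}
#' @param verbose print per-pair progress
#' @return list of \linkS4class{DisplacementField}, one per frame pair
#' @export
trackSequence <- function(series, config = trackingConfig(),
                          window = NULL, roi = NULL, verbose = FALSE) {
  n <- nFrames(series)
  if (is.null(window)) window <- c(1L, n)
  stopifnot(window[1] >= 1, window[2] <= n, window[2] > window[1])
  idx <- window[1]:(window[2] - 1)
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    f <- idx[k]
    out[[k]] <- multilevelDisplacement(series@frames[, , f],
                                       series@frames[, , f + 1],
                                       series@transducer, config,
                                       roi = roi)
    if (verbose) message(sprintf("tracked pair %d -> %d", f, f + 1))
  }
  out
}
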
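#' Accessor generics
#'
#' Small accessor family for the S4 containers: \code{wavelength} returns
#' the acoustic wavelength (sound speed / center frequency) of a
#' \linkS4class{TransducerParams}; \code{nFrames} the number of frames of a
#' series; \code{nNodes} the number of material points of a mesh;
#' \code{peakValue} the maximum of a correlation surface; \code{pfmTable}
#' the per-segment PFM data.frame.
#'
#' @param object an object of the matching class
#' @return see the method descriptions
#' @name accessors
#' @aliases wavelength nFrames nNodes peakValue pfmTable
NULL

#' @rdname accessors
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))

#' @rdname accessors
#' @export
setGeneric("peakValue", function(object) standardGeneric("peakValue"))

#' @rdname accessors
#' @export
setGeneric("pfmTable", function(object) standardGeneric("pfmTable"))

#' @rdname accessors
setMethod("wavelength", "TransducerParams",
          function(object) object@soundSpeed / object@centerFrequency)

#' @rdname accessors
setMethod("nFrames", "RFFrameSeries",
          function(object) dim(object@frames)[3])

#' @rdname accessors
setMethod("nNodes", "MyocardialMesh",
          function(object)
            as.integer(prod(dim(object@referencePositions)[1:2])))

#' @rdname accessors
setMethod("peakValue", "CorrelationSurface",
          function(object) {
            if (object@flagged) return(NA_real_)
            max(object@values, na.rm = TRUE)
          })

#' @rdname accessors
setMethod("pfmTable", "SegmentalPFM", function(object) object@table)

setMethod("show", "TransducerParams", function(object) {
  cat(sprintf(
    "TransducerParams: fc = %.1f MHz, c = %g m/s, lambda = %.1f um\n",
    object@centerFrequency / 1e6, object@soundSpeed,
    1e6 * wavelength(object)))
  cat(sprintf("  sampling: axial %.2f um, lateral %.2f um, %g fps\n",
              1e6 * object@axialSpacing, 1e6 * object@lateralSpacing,
              object@frameRate))
})

setMethod("show", "RFFrameSeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "RFFrameSeries: %d frames of %d samples x %d lines (%.2f x %.2f mm)\n",
    d[3], d[1], d[2], 1e3 * d[1] * object@transducer@axialSpacing,
    1e3 * d[2] * object@transducer@lateralSpacing))
  cat(sprintf("  t = [%.4f, %.4f] s, ECG %s, respiration %s\n",
              min(object@frameTimes), max(object@frameTimes),
              if (length(object@ecg$t)) "present" else "absent",
              if (length(object@respiration)) "present" else "absent"))
})

setMethod("show", "CorrelationSurface", function(object) {
  cat(sprintf(
    "CorrelationSurface: %d x %d lags, origin lag (%d, %d), peak %.4f%s\n",
    nrow(object@values), ncol(object@values), object@lagOffsets[1],
    object@lagOffsets[2], peakValue(object),
    if (object@flagged) " [flagged]" else ""))
})

setMethod("show", "ProbabilitySurface", function(object) {
  cat(sprintf(
    "ProbabilitySurface: %d x %d lags, %d iteration(s) applied, max %.4f\n",
    nrow(object@values), ncol(object@values), object@iterationsApplied,
    max(object@values)))
})

setMethod("show", "DisplacementField", function(object) {
  cat(sprintf(
    "DisplacementField (level %d): %d x %d nodes, |u| max %.2f um, peak NCC median %.3f\n",
    object@level, length(object@gridAxial), length(object@gridLateral),
    1e6 * max(sqrt(object@uAxial^2 + object@uLateral^2), na.rm = TRUE),
    median(object@corrPeak, na.rm = TRUE)))
})

setMethod("show", "MyocardialMesh", function(object) {
  d <- dim(object@referencePositions)
  nf <- if (length(object@trackedPositions)) dim(object@trackedPositions)[4]
        else 0
  cat(sprintf(
    "MyocardialMesh: %d x %d = %d material points, %d tracked frame(s)\n",
    d[1], d[2], d[1] * d[2], nf))
})

setMethod("show", "StrainTensorField", function(object) {
  hasCard <- length(object@eRadial) > 0
  cat(sprintf("StrainTensorField at frame %d (%d x %d nodes)%s\n",
              object@frameIndex, nrow(object@eAxial), ncol(object@eAxial),
              if (hasCard) ", cardiac components present" else ""))
  if (hasCard)
    cat(sprintf("  mean e_radial %.4f, mean e_longitudinal %.4f\n",
                mean(object@eRadial[object@valid], na.rm = TRUE),
                mean(object@eLongitudinal[object@valid], na.rm = TRUE)))
})

setMethod("show", "SegmentalPFM", function(object) {
  cat(sprintf("SegmentalPFM (%s source):\n", object@source))
  print(object@table, row.names = FALSE)
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf(
    "AgreementReport (n = %d): Spearman r = %.3f, Pearson r = %.3f\n",
    object@n, object@spearmanR, object@pearsonR))
  cat(sprintf("  fit: slope %.3f, intercept %.3f\n",
              object@fitSlope, object@fitIntercept))
  cat(sprintf("  Bland-Altman: bias %.2f, LoA [%.2f, %.2f]\n",
              object@bias, object@loaLow, object@loaHigh))
})
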
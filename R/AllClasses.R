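#' @useDynLib abrcsi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cor cor.test lm coef median sd qnorm pt quantile runif rnorm fft dnorm setNames complete.cases
#' @importFrom utils read.csv write.csv head tail
#' @importFrom grDevices convertColor
NULL

#' TransducerParams: acquisition geometry of an RF frame series
#'
#' Holds the transducer and sampling geometry used both to simulate RF
#' frames and to convert physical tracking parameters (kernel lengths in
#' wavelengths, filter kernels in mm) into sample units. The default models
#' a 30 MHz high-frequency probe imaging at 235 frames/s with axial sample
#' spacing of a quarter wavelength.
#'
#' @slot centerFrequency transmit center frequency, Hz
#' @slot soundSpeed assumed speed of sound, m/s
#' @slot axialSpacing axial sample spacing, m
#' @slot lateralSpacing A-line spacing, m
#' @slot frameRate frames per second
#' @slot psfAxialSigma,psfLateralSigma Gaussian point-spread widths, m
#' @exportClass TransducerParams
setClass("TransducerParams",
  representation(centerFrequency = "numeric", soundSpeed = "numeric",
                 axialSpacing = "numeric", lateralSpacing = "numeric",
                 frameRate = "numeric", psfAxialSigma = "numeric",
                 psfLateralSigma = "numeric"),
  validity = function(object) {
    v <- c(object@centerFrequency, object@soundSpeed, object@axialSpacing,
           object@lateralSpacing, object@frameRate, object@psfAxialSigma,
           object@psfLateralSigma)
    if (any(!is.finite(v)) || any(v <= 0))
      return("all transducer parameters must be finite and positive")
    TRUE
  })

#' ScattererField: point scatterers behind a speckle phantom
#'
#' @slot positions n x 2 matrix of (axial, lateral) positions, m
#' @slot amplitudes unitless reflectivities
#' @slot region c(axialMin, axialMax, lateralMin, lateralMax), m
#' @slot seed integer seed the field was drawn with
#' @exportClass ScattererField
setClass("ScattererField",
  representation(positions = "matrix", amplitudes = "numeric",
                 region = "numeric", seed = "integer"),
  validity = function(object) {
    p <- object@positions
    if (ncol(p) != 2) return("positions must be an n x 2 matrix")
    if (length(object@amplitudes) != nrow(p))
      return("one amplitude per scatterer required")
    if (length(object@region) != 4) return("region must have 4 entries")
    if (nrow(p) > 0) {
      r <- object@region
      if (any(p[, 1] < r[1] - 1e-12) || any(p[, 1] > r[2] + 1e-12) ||
          any(p[, 2] < r[3] - 1e-12) || any(p[, 2] > r[4] + 1e-12))
        return("scatterer positions must lie within the region")
      if (any(!is.finite(object@amplitudes)))
        return("amplitudes must be finite")
    }
    TRUE
  })

#' AnnulusDeformation: analytic contraction of a myocardium-like annulus
#'
#' Closed-form deformation of an annular wall: the endocardial radius
#' shrinks, the wall thickens and the wall arc shortens, all modulated by a
#' sin^2(pi * phase) temporal profile so phase 0 and 1 are the identity.
#' An optional "dysfunctional" arc scales the local displacement amplitude
#' down towards \code{dysfunctionFloor}, emulating an akinetic (fibrotic)
#' region with near-zero strain.
#'
#' @slot center annulus center (axial, lateral), m
#' @slot endoRadiusED,epiRadiusED end-diastolic radii, m
#' @slot peakRadialThickening peak endocardial radial strain (dimensionless)
#' @slot peakLongitudinalShortening peak endocardial wall shortening
#'   (dimensionless, stored positive)
#' @slot cycleDuration cardiac cycle length, s
#' @slot dysfunctionAngle center angle of the dysfunctional arc, rad
#'   (length 0 for none)
#' @slot dysfunctionWidth full angular width of the dysfunctional arc, rad
#' @slot dysfunctionFloor residual amplitude inside the arc (0 = akinetic)
#' @exportClass AnnulusDeformation
setClass("AnnulusDeformation",
  representation(center = "numeric", endoRadiusED = "numeric",
                 epiRadiusED = "numeric", peakRadialThickening = "numeric",
                 peakLongitudinalShortening = "numeric",
                 cycleDuration = "numeric", dysfunctionAngle = "numeric",
                 dysfunctionWidth = "numeric", dysfunctionFloor = "numeric"),
  validity = function(object) {
    if (object@endoRadiusED <= 0 ||
        object@endoRadiusED >= object@epiRadiusED)
      return("need 0 < endoRadiusED < epiRadiusED")
    if (object@peakRadialThickening < 0)
      return("peakRadialThickening must be >= 0")
    if (object@peakLongitudinalShortening < 0 ||
        object@peakLongitudinalShortening >= 1)
      return("peakLongitudinalShortening must be in [0, 1)")
    if (object@cycleDuration <= 0) return("cycleDuration must be > 0")
    TRUE
  })

#' RFFrameSeries: beamformed RF frames with geometry, timing and ECG
#'
#' @slot frames numeric array (axial samples x A-lines x frames)
#' @slot transducer a \linkS4class{TransducerParams}
#' @slot frameTimes frame timestamps, s (strictly increasing)
#' @slot ecg list with elements \code{t} and \code{v}
#' @slot respiration list with elements \code{t} and \code{v}, or empty
#' @exportClass RFFrameSeries
setClass("RFFrameSeries",
  representation(frames = "array", transducer = "TransducerParams",
                 frameTimes = "numeric", ecg = "list", respiration = "list"),
  validity = function(object) {
    d <- dim(object@frames)
    if (length(d) != 3) return("frames must be a 3-D array")
    if (length(object@frameTimes) != d[3])
      return("one timestamp per frame required")
    if (d[3] > 1 && any(diff(object@frameTimes) <= 0))
      return("frameTimes must be strictly increasing")
    if (!all(c("t", "v") %in% names(object@ecg)))
      return("ecg must have elements t and v")
    TRUE
  })

#' GroundTruthMotion: analytic displacement and strain of a phantom
#'
#' Wraps the analytic deformation a phantom sequence was rendered from, so
#' any downstream estimate can be compared against its exact value.
#'
#' @slot deformation the \linkS4class{AnnulusDeformation} used
#' @slot frameTimes frame timestamps of the rendered series, s
#' @exportClass GroundTruthMotion
setClass("GroundTruthMotion",
  representation(deformation = "AnnulusDeformation", frameTimes = "numeric"))

#' CorrelationSurface: 2-D NCC coefficients over integer lags
#'
#' @slot values matrix of NCC coefficients (axial lag x lateral lag);
#'   inadmissible lags are NA
#' @slot lagOffsets integer lag of values[1, 1] per axis
#' @slot flagged TRUE when the reference block had zero variance
#' @exportClass CorrelationSurface
setClass("CorrelationSurface",
  representation(values = "matrix", lagOffsets = "integer",
                 flagged = "logical"),
  validity = function(object) {
    v <- object@values
    if (!object@flagged && any(abs(v) > 1 + 1e-9, na.rm = TRUE))
      return("NCC values must lie in [-1, 1]")
    if (length(object@lagOffsets) != 2) return("lagOffsets must be length 2")
    TRUE
  })

#' ProbabilitySurface: normalized posterior over lags
#'
#' @slot values nonnegative matrix summing to 1
#' @slot lagOffsets integer lag of values[1, 1] per axis
#' @slot iterationsApplied regularization iterations applied
#' @slot flagged TRUE when the source surface was degenerate
#' @exportClass ProbabilitySurface
setClass("ProbabilitySurface",
  representation(values = "matrix", lagOffsets = "integer",
                 iterationsApplied = "integer", flagged = "logical"),
  validity = function(object) {
    v <- object@values
    if (any(v < 0)) return("probabilities must be nonnegative")
    if (abs(sum(v) - 1) > 1e-9) return("probabilities must sum to 1")
    TRUE
  })

#' TrackingConfig: multi-level block-matching parameters
#'
#' Defaults reproduce the murine displacement-estimation settings: three
#' pyramid levels, 1:2 axial:lateral RF sampling factor (the A-lines are
#' band-limited upsampled by 2 before matching), axial decimation [3,2,1]
#' and lateral decimation [2,1,1], axial kernels of [8, 5, 1] wavelengths,
#' lateral kernels of [15, 12, 10] A-lines, [50, 90]% kernel overlaps,
#' displacement median filter kernels of 0.13 x 0.41 mm (axial) and
#' 0.30 x 0.90 mm (lateral), 2-D sinc subsample refinement, a 0.06 x 0.5 mm
#' least-squares strain kernel, and at most 10 Bayesian regularization
#' iterations per kernel.
#'
#' @slot nLevels number of pyramid levels
#' @slot rfSamplingFactor axial:lateral RF sampling factor
#' @slot axialDecimation,lateralDecimation per-level decimation factors
#' @slot axialKernelWavelengths per-level axial kernel lengths, wavelengths
#' @slot lateralKernelLines per-level lateral kernel lengths, A-lines
#' @slot kernelOverlapPct (axial, lateral) kernel overlap, percent
#' @slot axialMedianKernelMm,lateralMedianKernelMm median filter kernels, mm
#' @slot lsqKernelMm least-squares strain kernel (axial, lateral), mm
#' @slot searchMargin integer matrix (2 x nLevels) of per-level search
#'   margins in lags post-decimation, rows = (axial, lateral)
#' @slot maxAbrIterations cap on regularization iterations per kernel
#' @slot abrGamma likelihood exponent
#' @slot abrSigma Gaussian lag-compatibility scale, lags
#' @slot abrSnrStop surface SNR above which no regularization is applied
#' @slot subsampleResolution sinc refinement resolution, lags
#' @slot lateralRefinement lateral subsample estimate: "joint" (2-D
#'   argmax), "row" (peak-row profile), "pooled" (carrier-in-phase rows)
#'   or "blend" (mean of joint and row)
#' @slot applyAbr,applyMedian stage switches
#' @slot greenLagrange use the quadratic Green-Lagrange strain form
#' @exportClass TrackingConfig
setClass("TrackingConfig",
  representation(nLevels = "integer", rfSamplingFactor = "integer",
                 axialDecimation = "integer", lateralDecimation = "integer",
                 axialKernelWavelengths = "numeric",
                 lateralKernelLines = "numeric",
                 kernelOverlapPct = "numeric",
                 axialMedianKernelMm = "numeric",
                 lateralMedianKernelMm = "numeric", lsqKernelMm = "numeric",
                 searchMargin = "matrix", maxAbrIterations = "integer",
                 abrGamma = "numeric", abrSigma = "numeric",
                 abrSnrStop = "numeric", subsampleResolution = "numeric",
                 lateralRefinement = "character",
                 applyAbr = "logical", applyMedian = "logical",
                 greenLagrange = "logical"),
  validity = function(object) {
    n <- object@nLevels
    if (n < 1) return("nLevels must be >= 1")
    for (s in c("axialDecimation", "lateralDecimation",
                "axialKernelWavelengths", "lateralKernelLines"))
      if (length(slot(object, s)) != n)
        return(sprintf("%s must have one entry per level", s))
    if (any(object@axialDecimation < 1) || any(object@lateralDecimation < 1))
      return("decimation factors must be >= 1")
    if (any(diff(object@axialDecimation) > 0) ||
        any(diff(object@lateralDecimation) > 0))
      return("decimation factors must be non-increasing across levels")
    sm <- object@searchMargin
    if (nrow(sm) != 2 || ncol(sm) != n || any(sm < 1))
      return("searchMargin must be a positive 2 x nLevels matrix")
    if (any(object@kernelOverlapPct < 0) ||
        any(object@kernelOverlapPct >= 100))
      return("kernel overlaps must be in [0, 100)")
    if (object@maxAbrIterations < 0)
      return("maxAbrIterations must be >= 0")
    if (!object@lateralRefinement %in% c("joint", "row", "pooled", "blend"))
      return("unknown lateralRefinement mode")
    TRUE
  })

#' DisplacementField: inter-frame displacements on a matching grid
#'
#' @slot gridAxial,gridLateral node positions, m (regular grid)
#' @slot uAxial,uLateral displacements, m (axial node x lateral node)
#' @slot corrPeak NCC peak value per node
#' @slot flags integer per node: 0 ok, 1 degenerate kernel, 2 border peak
#' @slot level pyramid level that produced the field
#' @exportClass DisplacementField
setClass("DisplacementField",
  representation(gridAxial = "numeric", gridLateral = "numeric",
                 uAxial = "matrix", uLateral = "matrix",
                 corrPeak = "matrix", flags = "matrix", level = "integer"),
  validity = function(object) {
    d <- c(length(object@gridAxial), length(object@gridLateral))
    for (s in c("uAxial", "uLateral", "corrPeak", "flags"))
      if (!identical(dim(slot(object, s)), as.integer(d)))
        return(sprintf("%s shape must match the node grid", s))
    if (any(abs(object@corrPeak) > 1 + 1e-9, na.rm = TRUE))
      return("correlation peaks must lie in [-1, 1]")
    TRUE
  })

#' MyocardialMesh: material point mesh spanning the myocardial wall
#'
#' A grid of \code{nTransmural x nCircumferential} material points blended
#' between the end-diastolic endocardial and epicardial contours (default
#' 40 x 600 = 24,000 points), with per-node local radial (transmural) and
#' longitudinal (along-wall) unit directions and, after tracking, the
#' per-frame positions of every point.
#'
#' @slot referencePositions array nT x nC x 2 of (axial, lateral), m
#' @slot trackedPositions array nT x nC x 2 x nFrames, m (may be empty)
#' @slot radialDir,longitudinalDir arrays nT x nC x 2 of unit vectors
#' @slot outOfField logical nT x nC, TRUE where tracking left the field
#' @exportClass MyocardialMesh
setClass("MyocardialMesh",
  representation(referencePositions = "array", trackedPositions = "array",
                 radialDir = "array", longitudinalDir = "array",
                 outOfField = "matrix"),
  validity = function(object) {
    d <- dim(object@referencePositions)
    if (length(d) != 3 || d[3] != 2)
      return("referencePositions must be nT x nC x 2")
    r <- object@radialDir; l <- object@longitudinalDir
    if (!identical(dim(r), d) || !identical(dim(l), d))
      return("direction arrays must match referencePositions")
    nr <- sqrt(r[, , 1]^2 + r[, , 2]^2)
    nl <- sqrt(l[, , 1]^2 + l[, , 2]^2)
    dot <- r[, , 1] * l[, , 1] + r[, , 2] * l[, , 2]
    if (max(abs(nr - 1), abs(nl - 1), abs(dot)) > 1e-9)
      return("direction vectors must be orthonormal")
    TRUE
  })

#' StrainTensorField: Lagrangian strain on the myocardial mesh
#'
#' @slot eAxial,eLateral,eShear cartesian strain components per node
#' @slot eRadial,eLongitudinal cardiac components (filled by
#'   \code{\link{toCardiac}}; empty matrices before that)
#' @slot valid logical per node; FALSE where the fit was rank-deficient
#' @slot frameIndex the frame the strain refers to
#' @exportClass StrainTensorField
setClass("StrainTensorField",
  representation(eAxial = "matrix", eLateral = "matrix", eShear = "matrix",
                 eRadial = "matrix", eLongitudinal = "matrix",
                 valid = "matrix", frameIndex = "integer"))

#' FibrosisThresholds: binary strain thresholds for fibrosis maps
#'
#' @slot radial radial strain threshold (fibrotic below), default 0.04
#' @slot longitudinal longitudinal strain threshold (fibrotic above),
#'   default -0.04
#' @exportClass FibrosisThresholds
setClass("FibrosisThresholds",
  representation(radial = "numeric", longitudinal = "numeric"),
  validity = function(object) {
    if (object@radial <= 0) return("radial threshold must be > 0")
    if (object@longitudinal >= 0) return("longitudinal threshold must be < 0")
    TRUE
  })

#' FibrosisMap: per-node fibrotic / non-fibrotic labels
#'
#' @slot labels integer matrix: 1 fibrotic, 0 non-fibrotic, NA excluded
#' @slot source "radial" or "longitudinal"
#' @slot esFrame end-systolic frame index the map was derived from
#' @exportClass FibrosisMap
setClass("FibrosisMap",
  representation(labels = "matrix", source = "character",
                 esFrame = "integer"),
  validity = function(object) {
    if (!object@source %in% c("radial", "longitudinal"))
      return("source must be 'radial' or 'longitudinal'")
    TRUE
  })

#' SegmentalPFM: percentage fibrotic myocardium per AHA segment
#'
#' @slot table data.frame with columns segment_id, segment_name,
#'   n_fibrotic, n_total, pfm_percent, included
#' @slot source map the PFM was computed from
#' @exportClass SegmentalPFM
setClass("SegmentalPFM",
  representation(table = "data.frame", source = "character"),
  validity = function(object) {
    tb <- object@table
    need <- c("segment_id", "segment_name", "n_fibrotic", "n_total",
              "pfm_percent", "included")
    if (!all(need %in% names(tb))) return("missing PFM table columns")
    ok <- tb$included & !is.na(tb$pfm_percent)
    if (any(tb$pfm_percent[ok] < 0 | tb$pfm_percent[ok] > 100))
      return("pfm_percent must lie in [0, 100]")
    TRUE
  })

#' ClassifiedWSI: 4-class labeled whole-slide image
#'
#' Label encoding: 0 background, 1 non-fibrotic myocardium, 2 fibrotic
#' (collagen), 3 blood clot.
#'
#' @slot labels integer matrix of pixel labels
#' @slot pixelSize pixel edge length, m
#' @slot landmarks list with base, apex and centroid pixel coordinates
#'   (each c(row, col)), or empty
#' @exportClass ClassifiedWSI
setClass("ClassifiedWSI",
  representation(labels = "matrix", pixelSize = "numeric",
                 landmarks = "list"),
  validity = function(object) {
    if (object@pixelSize <= 0) return("pixelSize must be > 0")
    if (!all(object@labels %in% 0:3)) return("labels must be in 0..3")
    TRUE
  })

#' AgreementReport: paired method-comparison statistics
#'
#' @slot spearmanR,pearsonR correlation coefficients
#' @slot fitSlope,fitIntercept ordinary least squares fit
#' @slot bias,loaLow,loaHigh Bland-Altman bias and limits of agreement
#' @slot n number of pairs
#' @exportClass AgreementReport
setClass("AgreementReport",
  representation(spearmanR = "numeric", pearsonR = "numeric",
                 fitSlope = "numeric", fitIntercept = "numeric",
                 bias = "numeric", loaLow = "numeric", loaHigh = "numeric",
                 n = "integer"),
  validity = function(object) {
    for (r in c(object@spearmanR, object@pearsonR))
      if (is.finite(r) && abs(r) > 1 + 1e-12)
        return("correlations must lie in [-1, 1]")
    if (is.finite(object@bias) &&
        (object@loaLow > object@bias || object@loaHigh < object@bias))
      return("limits of agreement must bracket the bias")
    TRUE
  })
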
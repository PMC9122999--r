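#' Transducer parameter constructor
#'
#' Defaults describe a 30 MHz high-frequency acquisition at 235 frames/s:
#' acoustic wavelength 51.3 um, axial sample spacing of a quarter
#' wavelength and an A-line spacing of 47 um, so that kernel lengths given
#' in wavelengths and A-lines are realizable on the simulated grid.
#'
#' @param centerFrequency transmit center frequency, Hz
#' @param soundSpeed speed of sound, m/s
#' @param axialSpacing axial sample spacing, m (default wavelength / 4)
#' @param lateralSpacing A-line spacing, m
#' @param frameRate frames per second
#' @param psfAxialSigma,psfLateralSigma Gaussian point-spread widths, m
#' @return a \linkS4class{TransducerParams}
#' @export
#' @examples
#' tp <- transducerParams()
#' wavelength(tp) * 1e6   # ~51.3 um
transducerParams <- function(centerFrequency = 3.0e7, soundSpeed = 1540,
                             axialSpacing = soundSpeed / centerFrequency / 4,
                             lateralSpacing = 4.7e-5, frameRate = 235,
                             psfAxialSigma = 2e-5,
                             psfLateralSigma = 4.7e-5) {
  new("TransducerParams", centerFrequency = centerFrequency,
      soundSpeed = soundSpeed, axialSpacing = axialSpacing,
      lateralSpacing = lateralSpacing, frameRate = frameRate,
      psfAxialSigma = psfAxialSigma, psfLateralSigma = psfLateralSigma)
}

#' Annulus deformation constructor
#'
#' The deformation maps a material point at end-diastolic radius rho0 to
#' rho(rho0, t) = sqrt(Re(t)^2 + k(t) (rho0^2 - Re0^2)) about the annulus
#' center, where Re(t) = Re0 (1 - s w(t)) is the contracted endocardial
#' radius, k(t) = (1 + e w(t)) (1 - s w(t)) sets the transmural stretch,
#' w(t) = sin^2(pi t / cycleDuration), e is the peak radial thickening and
#' s the peak longitudinal (along-wall) shortening, both realized exactly
#' at the endocardium at mid cycle. Defaults (20% thickening, 15%
#' shortening, 0.185 s cycle, 1.5 / 2.5 mm radii) are in the range of
#' healthy murine left-ventricular deformation at ~325 bpm.
#'
#' @param center annulus center (axial, lateral), m
#' @param endoRadiusED,epiRadiusED end-diastolic radii, m
#' @param peakRadialThickening peak endocardial radial strain
#' @param peakLongitudinalShortening peak endocardial wall shortening
#'   (positive number; the strain itself is negative)
#' @param cycleDuration cardiac cycle, s
#' @param dysfunctionAngle,dysfunctionWidth,dysfunctionFloor optional
#'   akinetic arc: center angle and full width (rad) over which the local
#'   displacement amplitude is scaled down to \code{dysfunctionFloor}
#' @return an \linkS4class{AnnulusDeformation}
#' @export
annulusDeformation <- function(center = c(3e-3, 3e-3),
                               endoRadiusED = 1.5e-3, epiRadiusED = 2.5e-3,
                               peakRadialThickening = 0.20,
                               peakLongitudinalShortening = 0.15,
                               cycleDuration = 0.185,
                               dysfunctionAngle = numeric(0),
                               dysfunctionWidth = 0,
                               dysfunctionFloor = 0.05) {
  new("AnnulusDeformation", center = center, endoRadiusED = endoRadiusED,
      epiRadiusED = epiRadiusED,
      peakRadialThickening = peakRadialThickening,
      peakLongitudinalShortening = peakLongitudinalShortening,
      cycleDuration = cycleDuration, dysfunctionAngle = dysfunctionAngle,
      dysfunctionWidth = dysfunctionWidth,
      dysfunctionFloor = dysfunctionFloor)
}

#' Draw a random scatterer field
#'
#' Scatterer count is fixed at \code{round(density * area)}; positions are
#' uniform over the region and amplitudes i.i.d. standard normal.
#' Identical seeds give bit-identical fields.
#'
#' @param region c(axialMin, axialMax, lateralMin, lateralMax), m
#' @param densityPerMm2 scatterers per square millimeter (>= 0)
#' @param seed integer seed
#' @return a \linkS4class{ScattererField}
#' @export
makeScattererField <- function(region, densityPerMm2, seed = 1L) {
  stopifnot(length(region) == 4, region[2] > region[1], region[4] > region[3])
  if (!is.finite(densityPerMm2) || densityPerMm2 < 0)
    stop("densityPerMm2 must be a nonnegative number")
  areaMm2 <- (region[2] - region[1]) * (region[4] - region[3]) * 1e6
  n <- round(densityPerMm2 * areaMm2)
  pos <- matrix(numeric(0), 0, 2)
  amp <- numeric(0)
  if (n > 0) {
    rs <- localRNG(seed)
    on.exit(restoreRNG(rs))
    pos <- cbind(runif(n, region[1], region[2]),
                 runif(n, region[3], region[4]))
    amp <- rnorm(n)
  }
  new("ScattererField", positions = pos, amplitudes = amp,
      region = as.numeric(region), seed = as.integer(seed))
}

## amplitude modulation of the dysfunctional arc: raised cosine from 1
## (outside) down to the floor at the arc center; smooth in theta.
dysfunctionAmplitude <- function(deformation, theta) {
  if (length(deformation@dysfunctionAngle) == 0 ||
      deformation@dysfunctionWidth <= 0)
    return(rep(1, length(theta)))
  d <- theta - deformation@dysfunctionAngle
  d <- atan2(sin(d), cos(d))                       # wrap to (-pi, pi]
  half <- deformation@dysfunctionWidth / 2
  g <- ifelse(abs(d) >= half, 0, 0.5 * (1 + cos(pi * d / half)))
  1 - (1 - deformation@dysfunctionFloor) * g
}

## mapping parameters at a phase fraction
annulusPhase <- function(deformation, phaseFraction) {
  w <- sin(pi * phaseFraction)^2
  s <- deformation@peakLongitudinalShortening
  e <- deformation@peakRadialThickening
  list(Re0 = deformation@endoRadiusED,
       Re = deformation@endoRadiusED * (1 - s * w),
       k = (1 + e * w) * (1 - s * w))
}

#' Analytic annulus displacement
#'
#' Displacement of material points of the annulus at a cycle phase
#' fraction. Phase 0 and 1 are the identity by construction.
#'
#' @param deformation an \linkS4class{AnnulusDeformation}
#' @param phaseFraction cycle phase in [0, 1]
#' @param points n x 2 matrix of material (end-diastolic) positions, m
#' @return n x 2 matrix of (axial, lateral) displacements, m
#' @export
annulusDisplacement <- function(deformation, phaseFraction, points) {
  stopifnot(phaseFraction >= 0, phaseFraction <= 1)
  points <- rbindPoints(points)
  rel <- sweep(points, 2, deformation@center)
  rho0 <- sqrt(rowSums(rel^2))
  if (any(rho0 < 1e-12))
    stop("material point at the annulus center: direction undefined")
  p <- annulusPhase(deformation, phaseFraction)
  rho <- sqrt(pmax(0, p$Re^2 + p$k * (rho0^2 - p$Re0^2)))
  a <- dysfunctionAmplitude(deformation, atan2(rel[, 2], rel[, 1]))
  dr <- a * (rho - rho0)
  cbind(dr * rel[, 1] / rho0, dr * rel[, 2] / rho0)
}

#' Analytic annulus strain
#'
#' Exact radial (transmural) and longitudinal (along-wall) engineering
#' strain of the annulus deformation at material points: the radial
#' stretch is k rho0 / rho and the circumferential stretch rho / rho0,
#' both scaled by the local dysfunction amplitude.
#'
#' @inheritParams annulusDisplacement
#' @return list with numeric vectors \code{radial} and \code{longitudinal}
#' @export
analyticStrain <- function(deformation, phaseFraction, points) {
  stopifnot(phaseFraction >= 0, phaseFraction <= 1)
  points <- rbindPoints(points)
  rel <- sweep(points, 2, deformation@center)
  rho0 <- sqrt(rowSums(rel^2))
  if (any(rho0 < 1e-12))
    stop("material point at the annulus center: direction undefined")
  p <- annulusPhase(deformation, phaseFraction)
  rho <- sqrt(pmax(0, p$Re^2 + p$k * (rho0^2 - p$Re0^2)))
  a <- dysfunctionAmplitude(deformation, atan2(rel[, 2], rel[, 1]))
  list(radial = a * (p$k * rho0 / rho - 1),
       longitudinal = a * (rho / rho0 - 1))
}

#' End-diastolic contours of the annulus
#'
#' Concentric endocardial and epicardial circles of the phantom, usable as
#' inputs to \code{\link{generateMesh}}. Points run counterclockwise from
#' the anterior-basal anchor at \code{anchorAngle}.
#'
#' @param deformation an \linkS4class{AnnulusDeformation}
#' @param n points per contour
#' @param anchorAngle angle of the anterior-basal anchor point, rad
#' @return list with n x 2 matrices \code{endo} and \code{epi}
#' @export
annulusContours <- function(deformation, n = 64, anchorAngle = 0) {
  th <- anchorAngle + 2 * pi * (0:(n - 1)) / n
  circ <- function(r)
    cbind(deformation@center[1] + r * cos(th),
          deformation@center[2] + r * sin(th))
  list(endo = circ(deformation@endoRadiusED),
       epi = circ(deformation@epiRadiusED))
}

#' Render one RF frame from a scatterer field
#'
#' Each (displaced) scatterer contributes a separable point-spread
#' response: axially a Gaussian-windowed cosine whose echo-time frequency
#' is the transducer center frequency, laterally a Gaussian. The frame is
#' linear in the scatterer amplitudes.
#'
#' @param scatterers a \linkS4class{ScattererField}
#' @param transducer a \linkS4class{TransducerParams}
#' @param displacement NULL, an n x 2 displacement matrix (m), or a
#'   function(points) returning one
#' @param nAxial,nLateral frame dimensions; default covers the field region
#' @return numeric matrix (axial samples x A-lines)
#' @export
renderRFFrame <- function(scatterers, transducer, displacement = NULL,
                          nAxial = NULL, nLateral = NULL) {
  if (nrow(scatterers@positions) == 0)
    stop("scatterer field is empty")
  if (transducer@psfAxialSigma < transducer@axialSpacing ||
      transducer@psfLateralSigma < transducer@lateralSpacing)
    warning("point-spread sigma below one sample spacing: aliasing likely")
  r <- scatterers@region
  if (is.null(nAxial))
    nAxial <- floor((r[2] - r[1]) / transducer@axialSpacing) + 1
  if (is.null(nLateral))
    nLateral <- floor((r[4] - r[3]) / transducer@lateralSpacing) + 1
  pos <- scatterers@positions
  if (is.function(displacement)) displacement <- displacement(pos)
  if (!is.null(displacement)) pos <- pos + displacement
  axPos <- r[1] + (0:(nAxial - 1)) * transducer@axialSpacing
  latPos <- r[3] + (0:(nLateral - 1)) * transducer@lateralSpacing
  ## one-way depth-time convention: the carrier has spatial period
  ## lambda = c / fc, i.e. 4 samples per cycle at lambda/4 spacing
  kRF <- 2 * pi * transducer@centerFrequency / transducer@soundSpeed
  cpp_render_frame(cbind(pos, scatterers@amplitudes), axPos, latPos,
                   transducer@psfAxialSigma, transducer@psfLateralSigma,
                   kRF)
}

## synthetic ECG: unit-amplitude Gaussian R waves at each cycle start on a
## small sinusoidal baseline; sampled at `fs` Hz
syntheticECG <- function(duration, cycleDuration, fs = 2000) {
  t <- seq(0, duration, by = 1 / fs)
  v <- 0.05 * sin(2 * pi * t / cycleDuration + pi / 3)
  for (tr in seq(0, duration + cycleDuration / 2, by = cycleDuration))
    v <- v + exp(-(t - tr)^2 / (2 * 0.003^2))
  list(t = t, v = v)
}

#' Simulate an RF frame sequence of the contracting annulus
#'
#' Renders a frozen speckle scatterer field moved by the analytic annulus
#' deformation into a sequence of RF frames, together with a synthetic ECG
#' whose R waves mark each cycle start. Out-of-plane decorrelation is
#' emulated by optional additive white noise (relative to the RF signal
#' power of the first frame) and by replacing a fraction of scatterers
#' with fresh ones at every frame transition. The default noise condition
#' is a 20 dB RF signal-to-noise ratio with 2% scatterer replacement;
#' \code{noiseSNRdB = Inf, scattererReplacement = 0} gives a noiseless
#' sequence. Identical seeds and configurations give bit-identical output.
#'
#' @param deformation an \linkS4class{AnnulusDeformation}
#' @param transducer a \linkS4class{TransducerParams}
#' @param nFrames number of frames; default covers one full cycle
#' @param densityPerMm2 scatterer density
#' @param noiseSNRdB additive RF noise level, dB (Inf = none)
#' @param scattererReplacement fraction of scatterers renewed per frame
#' @param region field of view; default a square covering the annulus with
#'   a 0.5 mm margin
#' @param seed integer seed for all randomness
#' @return list with elements \code{series} (\linkS4class{RFFrameSeries})
#'   and \code{truth} (\linkS4class{GroundTruthMotion})
#' @export
#' @examples
#' sim <- simulateSequence(nFrames = 3, densityPerMm2 = 20, seed = 7)
#' sim$series
simulateSequence <- function(deformation = annulusDeformation(),
                             transducer = transducerParams(),
                             nFrames = NULL, densityPerMm2 = 150,
                             noiseSNRdB = 20, scattererReplacement = 0.02,
                             region = NULL, seed = 1L) {
  if (is.null(nFrames))
    nFrames <- floor(deformation@cycleDuration * transducer@frameRate) + 1
  if (nFrames < 2) stop("need at least 2 frames")
  if (is.null(region)) {
    m <- deformation@epiRadiusED + 5e-4
    region <- c(deformation@center[1] - m, deformation@center[1] + m,
                deformation@center[2] - m, deformation@center[2] + m)
  }
  scat <- makeScattererField(region, densityPerMm2, seed = seed)
  rs <- localRNG(seed + 1000L)
  on.exit(restoreRNG(rs))
  times <- (0:(nFrames - 1)) / transducer@frameRate
  phases <- (times %% deformation@cycleDuration) / deformation@cycleDuration
  nRepl <- round(scattererReplacement * nrow(scat@positions))
  frames <- NULL
  noiseSd <- 0
  for (f in seq_len(nFrames)) {
    if (f > 1 && nRepl > 0) {
      idx <- sample.int(nrow(scat@positions), nRepl)
      scat@positions[idx, 1] <- runif(nRepl, region[1], region[2])
      scat@positions[idx, 2] <- runif(nRepl, region[3], region[4])
      scat@amplitudes[idx] <- rnorm(nRepl)
    }
    u <- annulusDisplacement(deformation, phases[f], scat@positions)
    fr <- renderRFFrame(scat, transducer, u)
    if (is.null(frames))
      frames <- array(0, c(nrow(fr), ncol(fr), nFrames))
    if (f == 1 && is.finite(noiseSNRdB))
      noiseSd <- sqrt(mean(fr^2)) * 10^(-noiseSNRdB / 20)
    if (noiseSd > 0) fr <- fr + rnorm(length(fr), sd = noiseSd) * 1
    frames[, , f] <- fr
  }
  ecg <- syntheticECG(max(times) + 1 / transducer@frameRate,
                      deformation@cycleDuration)
  series <- new("RFFrameSeries", frames = frames, transducer = transducer,
                frameTimes = times, ecg = ecg, respiration = list())
  truth <- new("GroundTruthMotion", deformation = deformation,
               frameTimes = times)
  list(series = series, truth = truth)
}

#' Ground-truth displacement and strain lookups
#'
#' Evaluate the analytic motion of a simulated sequence at material points
#' for a given frame: \code{truthDisplacement} returns displacements from
#' the end-diastolic reference, \code{truthStrain} the analytic radial and
#' longitudinal strain fields.
#'
#' @param truth a \linkS4class{GroundTruthMotion}
#' @param points n x 2 matrix of material positions, m
#' @param frame frame index (1-based)
#' @return displacements (n x 2 matrix) or a list of strain vectors
#' @export
truthDisplacement <- function(truth, points, frame) {
  annulusDisplacement(truth@deformation, truthPhase(truth, frame), points)
}

#' @rdname truthDisplacement
#' @export
truthStrain <- function(truth, points, frame) {
  analyticStrain(truth@deformation, truthPhase(truth, frame), points)
}

truthPhase <- function(truth, frame) {
  t <- truth@frameTimes[frame]
  (t %% truth@deformation@cycleDuration) / truth@deformation@cycleDuration
}

#' IQ demodulation round trip
#'
#' \code{iqDemodulate} converts real RF A-lines to complex baseband IQ by
#' analytic-signal construction (FFT half-spectrum) and mixing down at the
#' transducer center frequency in depth time (one-way convention, matching
#' the rendered carrier); \code{iqRemodulate} reconstructs RF by remixing
#' and taking the real part. The round trip is exact for band-limited RF.
#'
#' @param series an \linkS4class{RFFrameSeries}
#' @param iq complex array from \code{iqDemodulate}
#' @param transducer the matching \linkS4class{TransducerParams}
#' @return complex IQ array / real RF array of the same shape
#' @export
iqDemodulate <- function(series) {
  d <- dim(series@frames)
  tp <- series@transducer
  ts <- tp@axialSpacing / tp@soundSpeed     # one-way depth-time period
  mix <- exp(-2i * pi * tp@centerFrequency * ts * (0:(d[1] - 1)))
  iq <- array(0i, d)
  for (f in seq_len(d[3]))
    for (j in seq_len(d[2]))
      iq[, j, f] <- analyticSignal(series@frames[, j, f]) * mix
  iq
}

#' @rdname iqDemodulate
#' @export
iqRemodulate <- function(iq, transducer) {
  d <- dim(iq)
  ts <- transducer@axialSpacing / transducer@soundSpeed
  mix <- exp(2i * pi * transducer@centerFrequency * ts * (0:(d[1] - 1)))
  out <- array(0, d)
  for (f in seq_len(d[3]))
    for (j in seq_len(d[2]))
      out[, j, f] <- Re(iq[, j, f] * mix)
  out
}
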
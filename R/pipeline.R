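#' Default pipeline configuration
#'
#' Nested list of every stage's parameters: the phantom block (geometry,
#' noise, seed handling), the tracking block (see
#' \code{\link{trackingConfig}}), the fibrosis block (strain thresholds)
#' and the root seed. Round-trips losslessly through YAML; unknown keys
#' are rejected on read.
#'
#' @return named list
#' @export
pipelineConfig <- function() {
  list(
    version = pkgVersion(),
    seed = 1L,
    phantom = list(endo_radius_mm = 1.5, epi_radius_mm = 2.5,
                   peak_radial_thickening = 0.20,
                   peak_longitudinal_shortening = 0.15,
                   cycle_duration_s = 0.185, density_per_mm2 = 150,
                   noise_snr_db = 20, scatterer_replacement = 0.02),
    tracking = list(n_levels = 3, axial_decimation = c(3, 2, 1),
                    lateral_decimation = c(2, 1, 1),
                    axial_kernel_wavelengths = c(8, 5, 1),
                    lateral_kernel_lines = c(15, 12, 10),
                    kernel_overlap_pct = c(50, 90),
                    search_margin = c(8, 4), max_abr_iterations = 10,
                    abr_gamma = 2, abr_sigma = 1, abr_snr_stop = 10,
                    subsample_resolution = 0.01),
    kinematics = list(n_transmural = 40, n_circumferential = 600,
                      lsq_kernel_mm = c(0.06, 0.5),
                      green_lagrange = FALSE),
    fibrosis = list(radial_threshold = 0.04,
                    longitudinal_threshold = -0.04))
}

pkgVersion <- function()
  as.character(utils::packageVersion("abrcsi"))

#' Write / read a pipeline configuration as YAML
#'
#' @param config configuration list from \code{\link{pipelineConfig}}
#' @param path YAML file path
#' @return \code{readPipelineConfig} returns the configuration list
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  ref <- pipelineConfig()
  bad <- setdiff(names(cfg), names(ref))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (blk in intersect(names(cfg), c("phantom", "tracking", "kinematics",
                                      "fibrosis"))) {
    bad <- setdiff(names(cfg[[blk]]), names(ref[[blk]]))
    if (length(bad))
      stop(sprintf("unknown key(s) in block '%s': %s", blk,
                   paste(bad, collapse = ", ")))
  }
  cfg
}

## TrackingConfig from the config list's tracking block
trackingFromConfig <- function(tr) {
  trackingConfig(nLevels = tr$n_levels,
                 axialDecimation = tr$axial_decimation,
                 lateralDecimation = tr$lateral_decimation,
                 axialKernelWavelengths = tr$axial_kernel_wavelengths,
                 lateralKernelLines = tr$lateral_kernel_lines,
                 kernelOverlapPct = tr$kernel_overlap_pct,
                 searchMargin = tr$search_margin,
                 maxAbrIterations = tr$max_abr_iterations,
                 abrGamma = tr$abr_gamma, abrSigma = tr$abr_sigma,
                 abrSnrStop = tr$abr_snr_stop,
                 subsampleResolution = tr$subsample_resolution)
}

#' Run the strain-to-fibrosis pipeline on a frame series
#'
#' Executes the in vivo analysis chain in order: ECG gating, multi-level
#' regularized block matching of every consecutive frame pair in the
#' gated window, mesh generation from the end-diastolic contours,
#' Lagrangian accumulation, end-systole selection by smallest chamber
#' area, least-squares strain with cartesian-to-cardiac transformation,
#' binary threshold fibrosis maps from both strain sources, six-segment
#' division and segmental PFM. The returned log records the
#' configuration hash, seed and per-stage timings.
#'
#' @param series an \linkS4class{RFFrameSeries}
#' @param endo,epi end-diastolic contours (n x 2 matrices, m)
#' @param config configuration list, see \code{\link{pipelineConfig}}
#' @param qualityMask per-segment inclusion mask (signal dropouts)
#' @param roi optional tracking region of interest, m
#' @param verbose print stage progress
#' @return list with the mesh, ES frame, ES strain field, both fibrosis
#'   maps, both \linkS4class{SegmentalPFM} tables and a run log
#' @export
runPipeline <- function(series, endo, epi, config = pipelineConfig(),
                        qualityMask = rep(TRUE, 6), roi = NULL,
                        verbose = FALSE) {
  t0 <- proc.time()[3]
  timings <- c()
  stage <- function(name, expr) {
    s <- proc.time()[3]
    r <- tryCatch(force(expr),
                  error = function(e) stop(sprintf("stage '%s' failed: %s",
                                                   name, conditionMessage(e)),
                                           call. = FALSE))
    timings[[name]] <<- round(proc.time()[3] - s, 3)
    if (verbose) message(sprintf("stage %-12s %6.2f s", name,
                                 proc.time()[3] - s))
    r
  }
  window <- stage("gate", extractCycle(series))
  tcfg <- trackingFromConfig(config$tracking)
  fields <- stage("track", trackSequence(series, tcfg, window = window,
                                         roi = roi, verbose = verbose))
  mesh <- stage("mesh", generateMesh(endo, epi,
                                     config$kinematics$n_transmural,
                                     config$kinematics$n_circumferential))
  mesh <- stage("accumulate", accumulateDisplacements(mesh, fields))
  es <- stage("es", selectESFrame(mesh))
  strain <- stage("strain", {
    st <- leastSquaresStrain(mesh, es, config$kinematics$lsq_kernel_mm,
                             config$kinematics$green_lagrange)
    toCardiac(st, mesh)
  })
  thr <- fibrosisThresholds(config$fibrosis$radial_threshold,
                            config$fibrosis$longitudinal_threshold)
  segments <- segmentMyocardium(mesh)
  mapR <- stage("threshold", thresholdFibrosis(strain, "radial", thr))
  mapL <- thresholdFibrosis(strain, "longitudinal", thr)
  pfmR <- stage("pfm", pfmStrain(mapR, segments, qualityMask))
  pfmL <- pfmStrain(mapL, segments, qualityMask)
  log <- list(version = pkgVersion(),
              configHash = fnvHash(yaml::as.yaml(config)),
              seed = config$seed, window = window, esFrame = es,
              timings = timings, totalSeconds = proc.time()[3] - t0)
  list(mesh = mesh, fields = fields, esFrame = es, strain = strain,
       fibrosisRadial = mapR, fibrosisLongitudinal = mapL,
       pfmRadial = pfmR, pfmLongitudinal = pfmL, segments = segments,
       log = log)
}

## ------------------------------------------------------------------
## container I/O: RDS for arrays, CSV for tabular, JSON for reports.
## Every container carries a schema version and the package version.

SCHEMA_VERSION <- "1"

#' Frame series container I/O
#'
#' Writes/reads an \linkS4class{RFFrameSeries} with a schema version tag;
#' a version mismatch or a truncated container is rejected.
#'
#' @param series an \linkS4class{RFFrameSeries}
#' @param path file path
#' @return \code{readSeries} returns the series
#' @export
writeSeries <- function(series, path) {
  stopifnot(is(series, "RFFrameSeries"))
  saveRDS(list(schema = SCHEMA_VERSION, version = pkgVersion(),
               series = series), path)
  invisible(path)
}

#' @rdname writeSeries
#' @export
readSeries <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable series container '",
                                           path, "': ",
                                           conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$schema))
    stop("not a frame-series container: ", path)
  if (!identical(obj$schema, SCHEMA_VERSION))
    stop(sprintf("schema version mismatch in '%s': found %s, expected %s",
                 path, obj$schema, SCHEMA_VERSION))
  validObject(obj$series)
  obj$series
}

#' Contour CSV I/O
#'
#' Contours are stored as CSV with columns \code{x_mm}, \code{y_mm} and
#' \code{role} (endo / epi); coordinates in mm, x axial and y lateral.
#'
#' @param endo,epi n x 2 contour matrices, m
#' @param path CSV path
#' @return \code{readContours} returns list(endo, epi) in meters
#' @export
writeContours <- function(endo, epi, path) {
  df <- rbind(data.frame(x_mm = endo[, 1] * 1e3, y_mm = endo[, 2] * 1e3,
                         role = "endo"),
              data.frame(x_mm = epi[, 1] * 1e3, y_mm = epi[, 2] * 1e3,
                         role = "epi"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeContours
#' @export
readContours <- function(path) {
  df <- read.csv(path)
  need <- c("x_mm", "y_mm", "role")
  if (!all(need %in% names(df)))
    stop("contour file '", path, "' must have columns ",
         paste(need, collapse = ", "))
  pick <- function(role) {
    sel <- df$role == role
    if (!any(sel)) stop("contour file lacks role '", role, "'")
    cbind(df$x_mm[sel], df$y_mm[sel]) * 1e-3
  }
  list(endo = pick("endo"), epi = pick("epi"))
}

#' Segmental PFM CSV I/O
#'
#' The first line is a comment stamping the package version and
#' configuration hash; the table re-reads identically.
#'
#' @param pfm a \linkS4class{SegmentalPFM}
#' @param path CSV path
#' @param configHash hash string embedded in the header stamp
#' @return \code{readPFM} returns the \linkS4class{SegmentalPFM}
#' @export
writePFM <- function(pfm, path, configHash = "unconfigured") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# abrcsi %s source=%s config=%s", pkgVersion(),
                     pfm@source, configHash), con)
  write.csv(pfm@table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writePFM
#' @export
readPFM <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "# abrcsi"))
    stop("'", path, "' is not a segmental PFM file")
  src <- sub(".*source=(\\S+).*", "\\1", header)
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  new("SegmentalPFM", table = tab, source = src)
}

#' Write an agreement report as JSON
#'
#' @param report an \linkS4class{AgreementReport}
#' @param path JSON path
#' @param configHash configuration stamp
#' @return the path, invisibly
#' @export
writeReport <- function(report, path, configHash = "unconfigured") {
  jsonlite::write_json(
    list(version = pkgVersion(), config = configHash,
         spearman_r = report@spearmanR, pearson_r = report@pearsonR,
         fit_slope = report@fitSlope, fit_intercept = report@fitIntercept,
         bias = report@bias, loa_low = report@loaLow,
         loa_high = report@loaHigh, n = report@n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
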
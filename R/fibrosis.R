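#' Fibrosis threshold constructor
#'
#' Binary strain thresholds separating fibrotic from contractile
#' myocardium at end-systole: radial strain below +4% or longitudinal
#' strain above -4% marks a node fibrotic (healthy walls thicken radially
#' and shorten longitudinally).
#'
#' @param radial radial strain threshold (> 0)
#' @param longitudinal longitudinal strain threshold (< 0)
#' @return a \linkS4class{FibrosisThresholds}
#' @export
fibrosisThresholds <- function(radial = 0.04, longitudinal = -0.04) {
  new("FibrosisThresholds", radial = radial, longitudinal = longitudinal)
}

#' Select the end-systolic frame
#'
#' End-systole is the tracked frame with the smallest left-ventricular
#' chamber area, measured as the shoelace polygon area of the tracked
#' endocardial ring (transmural index 1). Ties resolve to the earliest
#' frame; a self-intersecting tracked ring is skipped with a warning.
#'
#' @param mesh a tracked \linkS4class{MyocardialMesh}
#' @return integer frame index into the tracked window
#' @export
selectESFrame <- function(mesh) {
  if (length(mesh@trackedPositions) == 0)
    stop("mesh has no tracked positions")
  nFr <- dim(mesh@trackedPositions)[4]
  areas <- rep(NA_real_, nFr)
  for (f in seq_len(nFr)) {
    ring <- cbind(mesh@trackedPositions[1, , 1, f],
                  mesh@trackedPositions[1, , 2, f])
    if (ringSelfIntersects(ring)) {
      warning(sprintf("tracked endocardial ring self-intersects at frame %d; skipped", f))
      next
    }
    areas[f] <- polygonArea(ring)
  }
  if (all(is.na(areas))) stop("no valid endocardial ring in any frame")
  which.min(areas)        # earliest on ties
}

## Cheap self-intersection screen: the ring's winding about its centroid
## must be monotone (star-shaped check, O(n)).
ringSelfIntersects <- function(ring) {
  ctr <- colMeans(ring)
  ang <- atan2(ring[, 2] - ctr[2], ring[, 1] - ctr[1])
  d <- diff(c(ang, ang[1]))
  d <- atan2(sin(d), cos(d))
  abs(sum(d)) < pi          # net winding must be +-2*pi
}

#' Threshold an end-systolic strain image into a fibrosis map
#'
#' Radial source: nodes with strain strictly below the radial threshold
#' are fibrotic. Longitudinal source: nodes with strain strictly above the
#' longitudinal threshold are fibrotic. Nodes with undefined strain are
#' excluded.
#'
#' @param esStrain a \linkS4class{StrainTensorField} with cardiac
#'   components (see \code{\link{toCardiac}})
#' @param source "radial" or "longitudinal"
#' @param thresholds a \linkS4class{FibrosisThresholds}
#' @return a \linkS4class{FibrosisMap}
#' @export
thresholdFibrosis <- function(esStrain, source = c("radial", "longitudinal"),
                              thresholds = fibrosisThresholds()) {
  source <- match.arg(source)
  if (length(esStrain@eRadial) == 0)
    stop("strain field lacks cardiac components; apply toCardiac first")
  v <- if (source == "radial") esStrain@eRadial else esStrain@eLongitudinal
  lab <- matrix(NA_integer_, nrow(v), ncol(v))
  okNodes <- esStrain@valid & !is.na(v)
  if (source == "radial") {
    lab[okNodes] <- as.integer(v[okNodes] < thresholds@radial)
  } else {
    lab[okNodes] <- as.integer(v[okNodes] > thresholds@longitudinal)
  }
  new("FibrosisMap", labels = lab, source = source,
      esFrame = esStrain@frameIndex)
}

#' Six-segment AHA division of the mesh
#'
#' Splits the circumferential index range into six contiguous near-equal
#' blocks starting at the anterior-basal anchor (circumferential index 1),
#' ordered anterior base, anterior mid, anterior apex, posterior apex,
#' posterior mid, posterior base; every transmural node inherits its
#' column's segment. When the circumference is not divisible by 6 the
#' remainder is distributed one column at a time to the leading segments.
#'
#' @param mesh a \linkS4class{MyocardialMesh}
#' @return integer matrix (nT x nC) of segment labels 1..6
#' @export
segmentMyocardium <- function(mesh) {
  d <- dim(mesh@referencePositions)
  nT <- d[1]; nC <- d[2]
  bounds <- floor(nC * (0:6) / 6)
  colSeg <- rep(1L, nC)
  for (s in 1:6) colSeg[(bounds[s] + 1):bounds[s + 1]] <- s
  matrix(rep(colSeg, each = nT), nT, nC)
}

#' Segment names in anatomical order
#' @return character vector of the six segment names
#' @export
segmentNames <- function() {
  c("anterior base", "anterior mid", "anterior apex",
    "posterior apex", "posterior mid", "posterior base")
}

#' Percentage fibrotic myocardium per segment
#'
#' PFM of a segment is 100 times the number of fibrotic nodes over the
#' number of countable (fibrotic + non-fibrotic) nodes; excluded nodes are
#' removed from both counts. Segments masked out by \code{qualityMask}
#' (signal dropout, reverberation, shadowing) or with no countable node
#' report no number.
#'
#' @param map a \linkS4class{FibrosisMap}
#' @param segments segment label matrix from
#'   \code{\link{segmentMyocardium}}
#' @param qualityMask logical vector of length 6; FALSE excludes a segment
#' @return a \linkS4class{SegmentalPFM}
#' @export
pfmStrain <- function(map, segments, qualityMask = rep(TRUE, 6)) {
  stopifnot(identical(dim(map@labels), dim(segments)),
            length(qualityMask) == 6)
  tab <- data.frame(segment_id = 1:6, segment_name = segmentNames(),
                    n_fibrotic = NA_integer_, n_total = NA_integer_,
                    pfm_percent = NA_real_, included = FALSE,
                    stringsAsFactors = FALSE)
  for (s in 1:6) {
    lab <- map@labels[segments == s]
    lab <- lab[!is.na(lab)]
    tab$n_fibrotic[s] <- sum(lab == 1L)
    tab$n_total[s] <- length(lab)
    if (!qualityMask[s]) next
    if (length(lab) == 0) {
      warning(sprintf("segment %d has no countable node; excluded", s))
      next
    }
    tab$pfm_percent[s] <- 100 * tab$n_fibrotic[s] / tab$n_total[s]
    tab$included[s] <- TRUE
  }
  new("SegmentalPFM", table = tab, source = map@source)
}
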
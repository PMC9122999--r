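#' Reference palette of a Masson's trichrome slide
#'
#' One sRGB reference colour per class: collagen (fibrosis) stains blue,
#' viable myocardium dark purple-red, blood clots dark red, and the slide
#' background is near white. Rows are named by class in label order
#' (background = 0, non-fibrotic = 1, fibrotic = 2, clot = 3).
#'
#' @return 4 x 3 numeric matrix of sRGB values in [0, 1]
#' @export
mtPalette <- function() {
  rbind(background = c(0.97, 0.97, 0.98),
        non_fibrotic = c(0.55, 0.25, 0.40),
        fibrotic = c(0.35, 0.45, 0.75),
        clot = c(0.45, 0.10, 0.15))
}

#' Deterministic 4-class colour classification of a stained slide
#'
#' Assigns every pixel to the nearest palette reference colour in CIELAB
#' (a perceptual colour space), giving a deterministic stand-in for a
#' trained pixel classifier: the quantitative object downstream is the
#' label image, however it was produced.
#'
#' @param rgbImage numeric array (rows x cols x 3), sRGB in [0, 1]
#' @param palette 4 x 3 reference colour matrix, see \code{\link{mtPalette}}
#' @param pixelSize pixel edge length, m (reference WSI mapping 0.25 um)
#' @param landmarks optional landmark list (base, apex, centroid)
#' @return a \linkS4class{ClassifiedWSI}
#' @export
classifyPixels <- function(rgbImage, palette = mtPalette(),
                           pixelSize = 0.25e-6, landmarks = list()) {
  stopifnot(length(dim(rgbImage)) == 3, dim(rgbImage)[3] == 3)
  if (anyDuplicated(round(palette, 10)))
    stop("palette contains duplicate reference colours")
  d <- dim(rgbImage)
  px <- matrix(rgbImage, d[1] * d[2], 3)
  labPx <- convertColor(px, from = "sRGB", to = "Lab")
  labRef <- convertColor(palette, from = "sRGB", to = "Lab")
  dist <- sapply(seq_len(nrow(labRef)), function(k)
    rowSums(sweep(labPx, 2, labRef[k, ])^2))
  lab <- max.col(-dist, ties.method = "first") - 1L   # 0-based labels
  new("ClassifiedWSI", labels = matrix(lab, d[1], d[2]),
      pixelSize = pixelSize, landmarks = landmarks)
}

#' Six-segment division of a classified slide
#'
#' Assigns pixels to six equal angular sectors about the cavity centroid,
#' anchored at the base landmark and swept towards the apex landmark so
#' that the sector order matches the in vivo segment order (anterior base
#' through posterior base).
#'
#' @param classified a \linkS4class{ClassifiedWSI}
#' @param landmarks list with c(row, col) entries \code{base},
#'   \code{apex} and \code{centroid}; defaults to the slide's own
#' @return integer matrix of segment labels 1..6 (all pixels labelled;
#'   background is excluded later by the PFM denominator rule)
#' @export
segmentWSI <- function(classified, landmarks = classified@landmarks) {
  if (!all(c("base", "apex", "centroid") %in% names(landmarks)))
    stop("landmarks must provide base, apex and centroid")
  d <- dim(classified@labels)
  ctr <- landmarks$centroid
  tissue <- classified@labels != 0L
  if (sum(tissue) == 0) stop("no tissue pixels in the slide")
  rows <- range(which(rowSums(tissue) > 0))
  cols <- range(which(colSums(tissue) > 0))
  if (ctr[1] < rows[1] || ctr[1] > rows[2] ||
      ctr[2] < cols[1] || ctr[2] > cols[2])
    warning("cavity centroid lies outside the tissue bounding region")
  a0 <- atan2(landmarks$base[2] - ctr[2], landmarks$base[1] - ctr[1])
  aApex <- atan2(landmarks$apex[2] - ctr[2], landmarks$apex[1] - ctr[1])
  ## sweep towards the apex; antipodal base/apex defaults to the positive
  ## rotational direction
  sweepSign <- if (sin(aApex - a0) >= -1e-9) 1 else -1
  r <- rep(seq_len(d[1]), times = d[2]) - ctr[1]
  c <- rep(seq_len(d[2]), each = d[1]) - ctr[2]
  phi <- sweepSign * (atan2(c, r) - a0)
  phi <- phi %% (2 * pi)
  seg <- pmin(1L + as.integer(floor(phi / (pi / 3))), 6L)
  matrix(seg, d[1], d[2])
}

#' Percentage fibrotic myocardium from a classified slide
#'
#' Per segment: 100 times fibrotic pixels over (total minus background)
#' pixels. Blood-clot pixels are tissue-region and count in the
#' denominator but never as fibrotic. Segments that are entirely
#' background are excluded with a warning.
#'
#' @param classified a \linkS4class{ClassifiedWSI}
#' @param segments segment label matrix from \code{\link{segmentWSI}}
#' @return data.frame with per-segment counts and \code{pfm_percent}
#' @export
pfmHistology <- function(classified, segments) {
  stopifnot(identical(dim(classified@labels), dim(segments)))
  out <- data.frame(segment_id = 1:6, segment_name = segmentNames(),
                    n_fibrotic = NA_integer_, n_total = NA_integer_,
                    n_background = NA_integer_, pfm_percent = NA_real_,
                    included = FALSE, stringsAsFactors = FALSE)
  for (s in 1:6) {
    lab <- classified@labels[segments == s]
    out$n_total[s] <- length(lab)
    out$n_background[s] <- sum(lab == 0L)
    out$n_fibrotic[s] <- sum(lab == 2L)
    denom <- out$n_total[s] - out$n_background[s]
    if (denom <= 0) {
      warning(sprintf("segment %d is entirely background; excluded", s))
      next
    }
    out$pfm_percent[s] <- 100 * out$n_fibrotic[s] / denom
    out$included[s] <- TRUE
  }
  out
}

#' Synthetic stained-slide generator
#'
#' Rasterizes an annular "myocardium" with per-segment fibrotic wedges
#' realizing requested area fractions, paints it in the Masson's
#' trichrome palette with optional Gaussian colour noise, and records the
#' exact label image and the per-segment PFM computed from it. A small
#' clot disc sits inside the cavity. Deterministic per seed.
#'
#' @param size image side, pixels
#' @param fibrosisFraction length-6 vector of per-segment fibrotic area
#'   fractions in [0, 1]
#' @param noiseSigma Gaussian colour noise standard deviation (sRGB units)
#' @param seed integer seed
#' @param pixelSize pixel edge length, m
#' @return list with \code{rgb} (array), \code{truth}
#'   (\linkS4class{ClassifiedWSI}), \code{segments} (label matrix),
#'   \code{truthPFM} (data.frame) and \code{landmarks}
#' @export
synthWSI <- function(size = 240, fibrosisFraction = rep(0, 6),
                     noiseSigma = 0, seed = 1L, pixelSize = 0.25e-6) {
  stopifnot(length(fibrosisFraction) == 6)
  if (any(fibrosisFraction < 0 | fibrosisFraction > 1))
    stop("infeasible fibrosis fraction: need values in [0, 1]")
  ctr <- c((size + 1) / 2, (size + 1) / 2)
  rIn <- 0.24 * size; rOut <- 0.42 * size; rClot <- 0.08 * size
  r <- rep(seq_len(size), times = size) - ctr[1]
  c <- rep(seq_len(size), each = size) - ctr[2]
  rad <- sqrt(r^2 + c^2)
  landmarks <- list(base = c(1, ctr[2]), apex = c(size, ctr[2]),
                    centroid = ctr)
  a0 <- atan2(landmarks$base[2] - ctr[2], landmarks$base[1] - ctr[1])
  phi <- ((atan2(c, r) - a0) %% (2 * pi))
  segIdx <- pmin(1L + as.integer(floor(phi / (pi / 3))), 6L)
  inWall <- rad >= rIn & rad <= rOut
  lab <- integer(size * size)               # background
  lab[inWall] <- 1L
  within <- (phi - (segIdx - 1) * pi / 3)   # angle into own sector
  fib <- inWall & within < fibrosisFraction[segIdx] * pi / 3
  lab[fib] <- 2L
  lab[rad <= rClot] <- 3L
  labels <- matrix(lab, size, size)
  truth <- new("ClassifiedWSI", labels = labels, pixelSize = pixelSize,
               landmarks = landmarks)
  segments <- segmentWSI(truth)
  truthPFM <- pfmHistology(truth, segments)
  pal <- mtPalette()
  rgb <- array(0, c(size, size, 3))
  for (ch in 1:3) rgb[, , ch] <- matrix(pal[lab + 1L, ch], size, size)
  if (noiseSigma > 0) {
    rs <- localRNG(seed)
    on.exit(restoreRNG(rs))
    rgb <- rgb + array(rnorm(length(rgb), sd = noiseSigma), dim(rgb))
    rgb[rgb < 0] <- 0; rgb[rgb > 1] <- 1
  }
  list(rgb = rgb, truth = truth, segments = segments, truthPFM = truthPFM,
       landmarks = landmarks)
}

#' Read / write label images as PNG
#'
#' Label images are stored as 8-bit grayscale PNG with the label encoding
#' 0 = background, 1 = non-fibrotic, 2 = fibrotic, 3 = clot scaled by 64
#' grey levels for inspectability.
#'
#' @param path PNG file path
#' @param classified a \linkS4class{ClassifiedWSI}
#' @param pixelSize pixel size of a read slide, m
#' @return \code{readLabelImage} returns a \linkS4class{ClassifiedWSI}
#' @export
writeLabelImage <- function(classified, path) {
  png::writePNG(classified@labels / 255 * 64, path)
  invisible(path)
}

#' @rdname writeLabelImage
#' @export
readLabelImage <- function(path, pixelSize = 0.25e-6) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  lab <- round(img * 255 / 64)
  new("ClassifiedWSI", labels = matrix(as.integer(lab), nrow(img), ncol(img)),
      pixelSize = pixelSize, landmarks = list())
}
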
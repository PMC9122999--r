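## Internal numeric helpers shared across modules.

## Seed the RNG locally, returning the previous state for restoration.
localRNG <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  old
}

restoreRNG <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

## Coerce a point, vector or data.frame to an n x 2 numeric matrix.
rbindPoints <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 2)
  points
}

## Analytic signal via FFT half-spectrum doubling.
analyticSignal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

## Column-wise envelope (magnitude of the analytic signal) of an RF frame.
axialEnvelope <- function(mat) {
  n <- nrow(mat)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(mat) * h
  Mod(stats::mvfft(X, inverse = TRUE)) / n
}

## Band-limited (FFT zero-padding) upsampling of the columns dimension by
## an integer factor; used for the lateral RF sampling factor.
fftUpsampleCols <- function(mat, factor) {
  if (factor == 1) return(mat)
  n <- ncol(mat)
  m <- n * factor
  half <- floor(n / 2)
  nneg <- n - half - 1
  out <- matrix(0, nrow(mat), m)
  for (i in seq_len(nrow(mat))) {
    X <- fft(mat[i, ])
    Y <- complex(length.out = m)
    Y[1:(half + 1)] <- X[1:(half + 1)]
    if (nneg > 0) Y[(m - nneg + 1):m] <- X[(half + 2):n]
    if (n %% 2 == 0) {              # split the Nyquist bin
      Y[half + 1] <- X[half + 1] / 2
      Y[m - half + 1] <- X[half + 1] / 2
    }
    out[i, ] <- Re(fft(Y, inverse = TRUE)) / n
  }
  out
}

## Boxcar anti-alias + subsample along rows (axial) or cols (lateral).
decimate2d <- function(mat, facRow, facCol) {
  if (facRow > 1) {
    nr <- floor(nrow(mat) / facRow)
    idx <- rep(seq_len(nr), each = facRow)
    mat <- rowsum(mat[seq_len(nr * facRow), , drop = FALSE], idx) / facRow
  }
  if (facCol > 1) {
    nc <- floor(ncol(mat) / facCol)
    idx <- rep(seq_len(nc), each = facCol)
    mat <- t(rowsum(t(mat[, seq_len(nc * facCol), drop = FALSE]), idx)) /
      facCol
  }
  mat
}

## Bilinear interpolation of values V on a regular grid (gx rows, gy cols)
## at query points; queries outside the grid are clamped to the border and
## reported in the `clamped` attribute.
interpGrid <- function(gx, gy, V, qx, qy) {
  clamped <- qx < gx[1] | qx > gx[length(gx)] |
    qy < gy[1] | qy > gy[length(gy)]
  qx <- pmin(pmax(qx, gx[1]), gx[length(gx)])
  qy <- pmin(pmax(qy, gy[1]), gy[length(gy)])
  i <- pmin(pmax(findInterval(qx, gx), 1), length(gx) - 1)
  j <- pmin(pmax(findInterval(qy, gy), 1), length(gy) - 1)
  if (length(gx) == 1) i <- rep(1L, length(qx))
  if (length(gy) == 1) j <- rep(1L, length(qy))
  tx <- if (length(gx) > 1) (qx - gx[i]) / (gx[i + 1] - gx[i]) else 0
  ty <- if (length(gy) > 1) (qy - gy[j]) / (gy[j + 1] - gy[j]) else 0
  i1 <- pmin(i + 1, length(gx)); j1 <- pmin(j + 1, length(gy))
  v <- (1 - tx) * (1 - ty) * V[cbind(i, j)] +
    tx * (1 - ty) * V[cbind(i1, j)] +
    (1 - tx) * ty * V[cbind(i, j1)] +
    tx * ty * V[cbind(i1, j1)]
  attr(v, "clamped") <- clamped
  v
}

## Smallest odd integer >= x (and >= 3 when ensureMin3).
roundUpOdd <- function(x, ensureMin3 = FALSE) {
  k <- ceiling(x)
  if (k %% 2 == 0) k <- k + 1
  if (ensureMin3 && k < 3) k <- 3
  as.integer(max(k, 1))
}

## Nearest odd integer >= 1 (for physical-unit window conversions).
roundToOdd <- function(x) {
  k <- max(1, round(x))
  if (k %% 2 == 0) k <- k + 1
  as.integer(k)
}

## Polynomial rolling hash of a character vector, reported as 8 hex
## digits; used to stamp outputs with their configuration.
fnvHash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261 %% 2147483647
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

## Shoelace polygon area (absolute) of an n x 2 matrix of vertices.
polygonArea <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

## Ray-casting point-in-polygon test (polygon closed implicitly).
pointsInPolygon <- function(points, poly) {
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  jx <- px[c(2:n, 1)]; jy <- py[c(2:n, 1)]
  apply(rbindPoints(points), 1, function(q) {
    cross <- (py > q[2]) != (jy > q[2])
    xin <- px + (q[2] - py) / (jy - py) * (jx - px)
    sum(cross & q[1] < xin) %% 2 == 1
  })
}
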
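#' Convert an NCC surface to a likelihood
#'
#' Negative coefficients are clamped to zero, the remainder raised to the
#' exponent \code{gamma} (default 2) and normalized to sum 1. A surface
#' with no positive coefficient is returned as the uniform distribution
#' with the \code{flagged} slot set.
#'
#' @param surface a \linkS4class{CorrelationSurface}
#' @param gamma likelihood exponent (> 0)
#' @return a \linkS4class{ProbabilitySurface}
#' @export
nccToLikelihood <- function(surface, gamma = 2) {
  stopifnot(is(surface, "CorrelationSurface"), gamma > 0)
  v <- pmax(surface@values, 0)^gamma
  v[is.na(v)] <- 0
  tot <- sum(v)
  flagged <- FALSE
  if (tot <= 0) {
    v[] <- 1 / length(v)
    flagged <- TRUE
  } else v <- v / tot
  new("ProbabilitySurface", values = v, lagOffsets = surface@lagOffsets,
      iterationsApplied = 0L, flagged = flagged)
}

#' Quality metrics of an NCC surface
#'
#' Decorrelation is 1 minus the peak coefficient (0 for a perfect match,
#' up to 2 for perfect anticorrelation); SNR is the peak-to-mean ratio of
#' the surface after shifting it nonnegative. A constant surface has
#' SNR 1 by convention.
#'
#' @param surface a \linkS4class{CorrelationSurface}
#' @return list with elements \code{decorrelation} and \code{snr}
#' @export
surfaceQuality <- function(surface) {
  v <- as.vector(surface@values)
  v <- v[!is.na(v)]
  if (length(v) == 0 || surface@flagged)
    return(list(decorrelation = NA_real_, snr = NA_real_))
  peak <- max(v)
  shifted <- v - min(0, min(v))
  m <- mean(shifted)
  snr <- if (m <= 0) 1 else max(shifted) / m
  list(decorrelation = 1 - peak, snr = snr)
}

#' Data-driven regularization iteration count
#'
#' Maps surface quality to the number of Bayesian regularization
#' iterations a kernel receives: zero for clean surfaces (SNR at or above
#' \code{snrStop}, or no decorrelation), growing with decorrelation and
#' shrinking with SNR, hard-capped at \code{maxIter} (default 10).
#' The rule is monotone: non-decreasing in decorrelation and
#' non-increasing in SNR.
#'
#' @param quality list from \code{\link{surfaceQuality}}
#' @param maxIter iteration cap
#' @param snrStop SNR at which regularization switches off
#' @return integer iteration count in [0, maxIter]
#' @export
adaptiveIterations <- function(quality, maxIter = 10L, snrStop = 10) {
  stopifnot(maxIter >= 0)
  d <- quality$decorrelation
  s <- quality$snr
  if (!is.finite(d) || !is.finite(s)) return(0L)
  if (s >= snrStop || d <= 0) return(0L)
  as.integer(min(maxIter,
                 round(maxIter * min(1, d) * (1 - s / snrStop))))
}

#' Iterative Bayesian regularization of a grid of surfaces
#'
#' Each node's posterior is iteratively updated to be proportional to its
#' own likelihood times the product over its 4-neighbours of the
#' neighbour's current posterior convolved with a Gaussian lag
#' compatibility kernel (scale \code{sigma} lags, zero-padded support of
#' 3 sigma); products are accumulated in log space and renormalized.
#' Updates are synchronous. Each node runs its own iteration count
#' (\code{iterations}, typically from \code{\link{adaptiveIterations}}),
#' all capped at \code{maxIter}; a finished node keeps its posterior but
#' still informs its neighbours.
#'
#' @param likelihoods array (lagA x lagL x nNodes) of normalized
#'   likelihoods, or a list of \linkS4class{ProbabilitySurface}
#' @param gridDim c(rows, cols) of the node grid; nodes are ordered
#'   column-major
#' @param sigma compatibility kernel scale, lags
#' @param maxIter hard iteration cap
#' @param iterations per-node iteration counts (default: maxIter for all)
#' @return list with \code{posterior} (array, same shape) and
#'   \code{iterations} (applied count per node)
#' @export
abrIterate <- function(likelihoods, gridDim, sigma = 1, maxIter = 10L,
                       iterations = NULL) {
  offs <- NULL
  if (is.list(likelihoods)) {
    offs <- likelihoods[[1]]@lagOffsets
    likelihoods <- simplify2array(lapply(likelihoods, slot, "values"))
  }
  d <- dim(likelihoods)
  stopifnot(length(d) == 3, prod(gridDim) == d[3], maxIter >= 0)
  if (is.null(iterations)) iterations <- rep(maxIter, d[3])
  iterations <- pmin(as.integer(iterations), as.integer(maxIter))
  res <- cpp_abr(likelihoods, as.integer(gridDim[1]),
                 as.integer(gridDim[2]), iterations, sigma)
  dim(res$posterior) <- d
  list(posterior = res$posterior, iterations = res$applied,
       lagOffsets = offs)
}
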
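#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties), with a
#' p-value from the t approximation or from a seeded permutation test.
#' Constant input is flagged rather than propagating NaN.
#'
#' @param a,b paired numeric vectors (n >= 3)
#' @param method p-value method
#' @param nPerm permutations for \code{method = "permutation"}
#' @param seed permutation seed
#' @return list with \code{r}, \code{p} and \code{n}
#' @export
#' @examples
#' spearmanR(c(1, 2, 3, 4), c(1, 3, 2, 4))$r   # 0.8
spearmanR <- function(a, b, method = c("t", "permutation"),
                      nPerm = 9999, seed = 1L) {
  method <- match.arg(method)
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3) stop("need at least 3 pairs")
  if (sd(a) == 0 || sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, constant = TRUE))
  r <- cor(rank(a), rank(b))
  if (method == "t") {
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
  } else {
    rs <- localRNG(seed)
    on.exit(restoreRNG(rs))
    ra <- rank(a); rb <- rank(b)
    perm <- replicate(nPerm, abs(cor(ra, sample(rb))))
    p <- (1 + sum(perm >= abs(r))) / (nPerm + 1)
  }
  list(r = r, p = p, n = n, constant = FALSE)
}

#' Fisher r-to-z confidence interval for a correlation
#'
#' @param r correlation coefficient
#' @param n number of pairs (> 3)
#' @param conf confidence level
#' @return c(lower, upper)
#' @export
fisherCI <- function(r, n, conf = 0.95) {
  stopifnot(n > 3, abs(r) < 1)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - conf) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Bland-Altman agreement of two paired measurements
#'
#' Differences are reference minus test (here: histopathology PFM minus
#' strain PFM); the bias is their mean and the limits of agreement are
#' bias +- 1.96 standard deviations.
#'
#' @param reference,test paired numeric vectors (n >= 2)
#' @return list with \code{bias}, \code{loaLow}, \code{loaHigh},
#'   \code{sd} and \code{n}
#' @export
blandAltman <- function(reference, test) {
  keep <- is.finite(reference) & is.finite(test)
  d <- reference[keep] - test[keep]
  if (length(d) < 2) stop("need at least 2 pairs")
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s,
       sd = s, n = length(d))
}

#' Ordinary least-squares fit of paired measurements
#'
#' Fits y = slope * x + intercept by OLS and reports the Pearson
#' correlation alongside.
#'
#' @param x predictor (non-constant)
#' @param y response
#' @return list with \code{slope}, \code{intercept}, \code{pearsonR},
#'   \code{n}
#' @export
linearFit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stop("need at least 2 pairs")
  if (sd(x) == 0) stop("constant predictor: fit undefined")
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       pearsonR = cor(x, y), n = length(x))
}

#' Full agreement report for paired segmental PFM series
#'
#' Combines Spearman and Pearson correlation, the OLS trend of the
#' reference on the test measurement, and Bland-Altman bias with limits
#' of agreement (reference minus test).
#'
#' @param reference,test paired numeric vectors, e.g. histopathology PFM
#'   and strain PFM per (subject, segment)
#' @return an \linkS4class{AgreementReport}
#' @export
agreementReport <- function(reference, test) {
  keep <- is.finite(reference) & is.finite(test)
  reference <- reference[keep]; test <- test[keep]
  sp <- spearmanR(reference, test)
  fit <- linearFit(test, reference)
  ba <- blandAltman(reference, test)
  new("AgreementReport", spearmanR = sp$r, pearsonR = fit$pearsonR,
      fitSlope = fit$slope, fitIntercept = fit$intercept,
      bias = ba$bias, loaLow = ba$loaLow, loaHigh = ba$loaHigh,
      n = as.integer(length(reference)))
}
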
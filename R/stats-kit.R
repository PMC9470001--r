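## Statistical machinery for the stratified analyses: bootstrap sign
## tests, Kendall correlation on category means, FDR, weighted-Z
## combination, residual-SE weights, nested ANCOVA, Cox-Snell pseudo-R2.

#' Two-tailed bootstrap sign test on replicate differences
#'
#' For a vector of per-replicate differences between two categories,
#' computes k- (negative replicates), k+ (positive replicates; exact
#' zeros count in neither) and the two-tailed p-value
#' \code{P = (2 min(k-, k+) + 1) / (N + 1)} with N the number of
#' replicates.
#'
#' @param deltas numeric vector of replicate differences
#' @return list with kMinus, kPlus, N, p
#' @examples
#' bootPairwiseP(rep(1, 100))$p  # 1/101
#' @export
bootPairwiseP <- function(deltas) {
  if (!length(deltas)) stop("deltas must be nonempty")
  kMinus <- sum(deltas < 0)
  kPlus <- sum(deltas > 0)
  N <- length(deltas)
  p <- (2 * min(kMinus, kPlus) + 1) / (N + 1)
  list(kMinus = kMinus, kPlus = kPlus, N = N, p = min(p, 1))
}

#' Kendall correlation between category rank and category means
#'
#' Tie-corrected Kendall's tau (tau-b) with a two-sided p-value: exact
#' for 8 or fewer untied pairs, normal approximation with tie correction
#' otherwise (as in \code{stats::cor.test}).
#'
#' @param x ordered category ranks (e.g. age class, 1 = oldest)
#' @param y per-category statistic means
#' @return list with tau, p; both NA (flagged via \code{degenerate}) when
#'   either vector has zero variance
#' @export
kendallTau <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 categories")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(tau = NA_real_, p = NA_real_, degenerate = TRUE))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall",
                    exact = length(x) <= 8 && !anyDuplicated(x) &&
                      !anyDuplicated(y)))
  list(tau = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvals numeric vector of p-values in [0, 1]
#' @return adjusted p-values (monotone step-up)
#' @export
bhFdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Weighted-Z (weighted Stouffer) combination of p-values
#'
#' Combines one-sided p-values with positive weights:
#' \code{Z = sum(w_i qnorm(1 - p_i)) / sqrt(sum(w_i^2))}, combined
#' p = 1 - pnorm(Z). Boundary p-values are clamped to the open unit
#' interval with a warning. With equal weights this reduces to the
#' unweighted Stouffer method.
#'
#' @param pvals one-sided p-values
#' @param weights positive weights (default equal)
#' @return list with z and p
#' @examples
#' weightedZ(c(0.05, 0.05))$p  # 0.00999
#' @export
weightedZ <- function(pvals, weights = rep(1, length(pvals))) {
  stopifnot(length(pvals) == length(weights))
  if (any(weights <= 0)) stop("weights must be positive")
  eps <- 1e-15
  if (any(pvals <= 0 | pvals >= 1)) {
    warning("boundary p-values clamped to (0, 1)")
    pvals <- pmin(pmax(pvals, eps), 1 - eps)
  }
  z <- sum(weights * stats::qnorm(1 - pvals)) / sqrt(sum(weights^2))
  list(z = z, p = 1 - stats::pnorm(z))
}

#' Residual-based weight for the weighted-Z combination
#'
#' Ordinary least squares of the response on the design matrix; the
#' weight is the reciprocal of the squared residual standard error,
#' \code{1 / (RSS / (n - p))}. A perfect fit (RSS = 0) yields an
#' infinite weight, which is flagged and capped.
#'
#' @param y response vector
#' @param X design matrix (including the intercept column)
#' @param cap ceiling applied to the weight (default 1e12)
#' @return list with weight, sigma2 (residual variance), capped flag
#' @export
residualSeWeight <- function(y, X, cap = 1e12) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X))
    stop("need more observations than design columns")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (nrow(X) - ncol(X))
  capped <- sigma2 <= 0 || 1 / sigma2 > cap
  if (capped) warning("perfect or near-perfect fit: weight capped")
  list(weight = if (capped) cap else 1 / sigma2, sigma2 = sigma2,
       capped = capped)
}

#' Nested linear-model (ANCOVA) comparison
#'
#' Standard F-test of a full against a reduced ordinary-least-squares
#' model; the reduced terms must be nested within the full terms. Used
#' for asking whether e.g. the chromosome and its interaction with age
#' improve on an age-only model.
#'
#' @param data data.frame of the modeling variables
#' @param full,reduced model formulas, reduced nested in full
#' @return list with F, p, dfNum, dfDen
#' @export
ancovaCompare <- function(data, full, reduced) {
  mf <- stats::lm(full, data = data)
  mr <- stats::lm(reduced, data = data)
  tf <- attr(stats::terms(mf), "term.labels")
  tr <- attr(stats::terms(mr), "term.labels")
  if (!all(tr %in% tf))
    stop("reduced model terms are not nested in the full model")
  dfNum <- mr$df.residual - mf$df.residual
  if (dfNum <= 0) stop("models do not differ (0 numerator df)")
  an <- stats::anova(mr, mf)
  list(F = an$F[2], p = an$`Pr(>F)`[2], dfNum = an$Df[2],
       dfDen = mf$df.residual)
}

#' Cox-Snell pseudo-R2 from nested log-likelihoods
#'
#' \code{1 - exp(-(2/N) (lnL_full - lnL_reduced))}: the standard
#' Cox-Snell form for comparing a full likelihood against a reduced one
#' over N observations (here, sites).
#'
#' @param lnFull,lnReduced log-likelihoods, lnFull >= lnReduced
#' @param n number of observations (sites), positive
#' @return pseudo-R2 in [0, 1)
#' @examples
#' coxSnellR2(10, 0, 1000)  # 0.0198
#' @export
coxSnellR2 <- function(lnFull, lnReduced, n) {
  if (n <= 0) stop("n must be positive")
  if (lnFull < lnReduced)
    stop("full-model log-likelihood below reduced-model log-likelihood")
  1 - exp(-(2 / n) * (lnFull - lnReduced))
}

#' Percentile bootstrap summary of replicate statistics
#'
#' @param replicates numeric vector or matrix (rows = replicates)
#' @param B requested replicate count (default: rows available)
#' @return a \linkS4class{BootstrapResult}
#' @export
bootstrapSummary <- function(replicates, B = NULL) {
  m <- as.matrix(replicates)
  if (is.null(colnames(m))) colnames(m) <- paste0("stat", seq_len(ncol(m)))
  if (is.null(B)) B <- nrow(m)
  ci <- apply(m, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  new("BootstrapResult", replicates = m, B = as.integer(B),
      nDropped = as.integer(B - nrow(m)),
      mean = colMeans(m, na.rm = TRUE), ciLow = ci[1, ], ciHigh = ci[2, ])
}
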
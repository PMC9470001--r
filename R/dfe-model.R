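## Poisson random field expectations under a Gamma-Exponential DFE.
##
## The deleterious class is a reflected Gamma on S < 0 (shape, mean
## meanDel), the beneficial class an Exponential on S > 0 (mean meanBen),
## mixed with weight pBen. Expected polymorphism per frequency class i:
##   lambda_syn,i    = L_syn * theta * r_i / i
##   lambda_nonsyn,i = L_nonsyn * theta * r_i * Int phi(S) H(i, n, S) dS
## with the standard diffusion sojourn kernel
##   H(i,n,S) = Int_0^1 C(n,i) x^i (1-x)^(n-i)
##              (1 - exp(-S(1-x))) / ((1 - exp(-S)) x (1-x)) dx.
## The S-integral is discretized by equal-mass quantile nodes of the two
## mixture components; the x-integral uses composite Gauss-Legendre with
## panels refined toward both endpoints, where the kernel develops
## boundary layers for large |S|.

.gaussLegendre <- function(k) {
  i <- seq_len(k - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = (2 * e$vectors[1, ]^2)[ord])
}

.xGrid <- function(nodesPerPanel = 12L) {
  brk <- c(0, 1e-5, 1e-4, 1e-3, 1e-2, 0.1, 0.3, 0.5, 0.7, 0.9, 0.99,
           0.999, 0.9999, 1)
  g <- .gaussLegendre(nodesPerPanel)
  x <- numeric(0); w <- numeric(0)
  for (j in seq_len(length(brk) - 1L)) {
    a <- brk[j]; b <- brk[j + 1L]
    x <- c(x, (g$x + 1) / 2 * (b - a) + a)
    w <- c(w, g$w / 2 * (b - a))
  }
  list(x = x, w = w)
}

#' Quadrature controls for the DFE expectations
#'
#' @param nDel,nBen numbers of equal-mass quantile nodes discretizing the
#'   deleterious Gamma and beneficial Exponential components
#' @param nodesPerPanel Gauss-Legendre nodes per panel of the composite
#'   frequency integral
#' @param truncDel hard truncation for deleterious effects (|S| above this
#'   contributes nothing to polymorphism or fixation)
#' @return list of controls passed to \code{\link{expectedSfs}} and
#'   \code{\link{fitDfe}}
#' @export
dfeQuadControl <- function(nDel = 100L, nBen = 40L, nodesPerPanel = 12L,
                           truncDel = 1e5) {
  list(nDel = as.integer(nDel), nBen = as.integer(nBen),
       nodesPerPanel = as.integer(nodesPerPanel), truncDel = truncDel)
}

## log(expm1(y)) stable for large y
.logExpm1 <- function(y) ifelse(y > 33, y, log(expm1(y)))

## matrix of (1 - e^{-S(1-x)}) / (1 - e^{-S}), rows x, cols S
.sojournRatio <- function(S, x) {
  R <- matrix(0, length(x), length(S))
  neg <- S < -1e-8
  pos <- S > 1e-8
  zer <- !neg & !pos
  if (any(neg)) {
    Sn <- S[neg]
    R[, neg] <- exp(.logExpm1(outer(1 - x, -Sn)) -
                      rep(.logExpm1(-Sn), each = length(x)))
  }
  if (any(pos)) {
    Sp <- S[pos]
    R[, pos] <- -expm1(outer(1 - x, -Sp)) / rep(-expm1(-Sp), each = length(x))
  }
  if (any(zer)) R[, zer] <- 1 - x
  R
}

## C(n,i) x^{i-1} (1-x)^{n-i-1}, rows i = 1..n-1, cols x
.freqBasis <- function(n, grid) {
  ii <- seq_len(n - 1L)
  lx <- log(grid$x); l1x <- log1p(-grid$x)
  exp(outer(ii, lx, function(i, l) lchoose(n, i) + (i - 1) * l) +
        outer(n - ii - 1L, l1x))
}

.basisCache <- new.env(parent = emptyenv())

.getBasis <- function(n, nodesPerPanel) {
  key <- sprintf("n%d_p%d", n, nodesPerPanel)
  if (is.null(.basisCache[[key]])) {
    grid <- .xGrid(nodesPerPanel)
    .basisCache[[key]] <- list(grid = grid, B = .freqBasis(n, grid))
  }
  .basisCache[[key]]
}

## equal-mass discretization of the DFE into (S, weight) nodes
.dfeNodes <- function(params, quad) {
  Sd <- numeric(0); wd <- numeric(0)
  if (params@pBen < 1) {
    u <- (seq_len(quad$nDel) - 0.5) / quad$nDel
    q <- stats::qgamma(u, shape = params@shape,
                       scale = abs(params@meanDel) / params@shape)
    q <- pmin(q, quad$truncDel)
    Sd <- -q
    wd <- rep((1 - params@pBen) / quad$nDel, quad$nDel)
  }
  Sb <- numeric(0); wb <- numeric(0)
  if (params@pBen > 0) {
    u <- (seq_len(quad$nBen) - 0.5) / quad$nBen
    Sb <- stats::qexp(u, rate = 1 / params@meanBen)
    wb <- rep(params@pBen / quad$nBen, quad$nBen)
  }
  list(S = c(Sd, Sb), w = c(wd, wb))
}

#' Relative fixation rate of a semidominant mutation
#'
#' Kimura's fixation probability scaled by the neutral one:
#' \code{S / (1 - exp(-S))} with S = 4 Ne s, continuous through S = 0
#' where it equals 1. Numerically stable for |S| large.
#'
#' @param S numeric vector of scaled selection coefficients
#' @return numeric vector of relative fixation rates
#' @examples
#' fixationRateRelative(c(-2, 0, 2))
#' @export
fixationRateRelative <- function(S) {
  out <- ifelse(abs(S) < 1e-8, 1 + S / 2, S / (-expm1(-S)))
  ## -expm1(-S) overflows to -Inf for very negative S, giving 0 correctly;
  ## guard the NaN case S/-Inf when S itself is -Inf
  out[!is.finite(S)] <- NA_real_
  out
}

#' Expected unfolded SFS under the DFE
#'
#' Poisson random field expectations for the synonymous (neutral) and
#' nonsynonymous (DFE-weighted) frequency classes at sample size n.
#'
#' @param params a \linkS4class{DFEParams}
#' @param n haplotype sample size
#' @param lSyn,lNonsyn effective site numbers of the two classes
#' @param quad quadrature controls from \code{\link{dfeQuadControl}}
#' @return list with numeric vectors \code{lambdaSyn}, \code{lambdaNonsyn}
#'   of length n - 1
#' @export
expectedSfs <- function(params, n, lSyn, lNonsyn, quad = dfeQuadControl()) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2")
  bb <- .getBasis(n, quad$nodesPerPanel)
  nodes <- .dfeNodes(params, quad)
  H <- bb$B %*% (.sojournRatio(nodes$S, bb$grid$x) * bb$grid$w)  # (n-1) x K
  hbar <- as.numeric(H %*% nodes$w)
  r <- if (length(params@distortion)) params@distortion else rep(1, n - 1L)
  if (length(r) != n - 1L)
    stop("distortion vector must have length n - 1")
  lambdaSyn <- lSyn * params@theta * r / seq_len(n - 1L)
  lambdaNonsyn <- lNonsyn * params@theta * r * hbar
  if (any(!is.finite(lambdaSyn)) || any(!is.finite(lambdaNonsyn)))
    stop(sprintf(
      "non-finite expected SFS (shape=%g meanDel=%g pBen=%g meanBen=%g theta=%g)",
      params@shape, params@meanDel, params@pBen, params@meanBen, params@theta))
  list(lambdaSyn = lambdaSyn, lambdaNonsyn = lambdaNonsyn)
}

#' Poisson random field log-likelihood of one category
#'
#' Independent Poisson likelihood of the observed synonymous and
#' nonsynonymous frequency-class counts under the expectations of
#' \code{\link{expectedSfs}}. Divergence does not enter the likelihood;
#' it is used only for the omega computation (model-based alpha).
#'
#' @param counts a \linkS4class{CategoryCounts}
#' @param params a \linkS4class{DFEParams}
#' @param quad quadrature controls
#' @return log-likelihood (can be -Inf when a zero expectation meets a
#'   positive count)
#' @export
loglikPoisson <- function(counts, params, quad = dfeQuadControl()) {
  n <- sampleSize(counts)
  lam <- expectedSfs(params, n, counts@lSyn, counts@lNonsyn, quad)
  k <- c(counts@sfsSyn@counts, counts@sfsNonsyn@counts)
  l <- c(lam$lambdaSyn, lam$lambdaNonsyn)
  ll <- sum(ifelse(l > 0, k * log(l) - l - lgamma(k + 1),
                   ifelse(k > 0, -Inf, 0)))
  ll
}

#' Expected nonadaptive substitution rate under a DFE
#'
#' The nonadaptive component of the nonsynonymous/synonymous rate ratio:
#' the fixation-rate integral of the deleterious (S < 0) part of the DFE,
#' \code{(1 - pBen) * E[ S/(1 - exp(-S)) ]} over the reflected Gamma.
#'
#' @param params a \linkS4class{DFEParams}
#' @param quad quadrature controls
#' @return nonnegative scalar omega_na
#' @export
omegaNaExpected <- function(params, quad = dfeQuadControl()) {
  if (params@pBen >= 1) return(0)
  u <- (seq_len(quad$nDel) - 0.5) / quad$nDel
  q <- stats::qgamma(u, shape = params@shape,
                     scale = abs(params@meanDel) / params@shape)
  q <- pmin(q, quad$truncDel)
  (1 - params@pBen) * mean(fixationRateRelative(-q))
}

#' Expected adaptive substitution rate under a DFE
#'
#' The beneficial-side analogue of \code{\link{omegaNaExpected}}:
#' \code{pBen * E[ S/(1 - exp(-S)) ]} over the Exponential on S > 0.
#' Used by the synthetic-data generator to define true rates.
#'
#' @inheritParams omegaNaExpected
#' @return nonnegative scalar omega_a
#' @export
omegaAExpected <- function(params, quad = dfeQuadControl()) {
  if (params@pBen <= 0) return(0)
  u <- (seq_len(quad$nBen) - 0.5) / quad$nBen
  q <- stats::qexp(u, rate = 1 / params@meanBen)
  params@pBen * mean(fixationRateRelative(q))
}

#' Rate ratio omega from divergence counts
#'
#' \code{(Dn/Ln) / (Ds/Ls)}; errors when Ds is zero.
#'
#' @param counts a \linkS4class{CategoryCounts}
#' @return nonnegative scalar
#' @export
omegaFromCounts <- function(counts) {
  if (counts@dSyn <= 0)
    stop("omega undefined: no synonymous divergence in this category")
  (counts@dNonsyn / counts@lNonsyn) / (counts@dSyn / counts@lSyn)
}
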
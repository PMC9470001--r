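#' @import methods
NULL

#' Unfolded site frequency spectrum for one site class
#'
#' Holds the derived-allele count spectrum of a single site class
#' (synonymous, nonsynonymous, or fourfold sites of a given mutation type)
#' at a fixed haplotype sample size \code{n}. Class \code{i} of the vector
#' counts sites at which the derived allele is carried by exactly \code{i}
#' of the \code{n} sampled haplotypes, for \code{i = 1..n-1}. \code{nSites}
#' is the effective number of sites of this class over which the spectrum
#' was collected (may be fractional when degeneracy is apportioned).
#'
#' @slot sampleSize integer haplotype count n (>= 2)
#' @slot counts numeric vector of length n-1, nonnegative (fractional values
#'   arise from expected-value down-sampling)
#' @slot nSites nonnegative number of sites of this class
#' @slot siteClass one of "synonymous", "nonsynonymous",
#'   "fourfold_by_muttype"
#'
#' @exportClass SiteFrequencySpectrum
setClass("SiteFrequencySpectrum",
  representation(
    sampleSize = "integer",
    counts = "numeric",
    nSites = "numeric",
    siteClass = "character"
  )
)

setValidity("SiteFrequencySpectrum", function(object) {
  msg <- character()
  if (length(object@sampleSize) != 1L || object@sampleSize < 2L)
    msg <- c(msg, "sampleSize must be a single integer >= 2")
  if (length(object@counts) != object@sampleSize - 1L)
    msg <- c(msg, sprintf("counts must have length sampleSize - 1 (%d), got %d",
                          object@sampleSize - 1L, length(object@counts)))
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    msg <- c(msg, "counts must be finite and nonnegative")
  if (length(object@nSites) != 1L || !is.finite(object@nSites) || object@nSites < 0)
    msg <- c(msg, "nSites must be a single nonnegative number")
  if (!object@siteClass %in% c("synonymous", "nonsynonymous", "fourfold_by_muttype"))
    msg <- c(msg, "unknown siteClass")
  if (length(msg)) msg else TRUE
})

#' Pooled counts for one analysis cell
#'
#' The complete sufficient data for one cell of the analysis (a gene, or a
#' pool of genes in a stratum-by-group cell): synonymous and nonsynonymous
#' unfolded SFS at a common sample size, fixed-difference counts against
#' the outgroup, and effective site totals.
#'
#' @slot sfsSyn,sfsNonsyn \linkS4class{SiteFrequencySpectrum} objects
#'   sharing one sample size
#' @slot dSyn,dNonsyn nonnegative divergence (fixed difference) counts
#' @slot lSyn,lNonsyn effective numbers of synonymous / nonsynonymous sites
#' @slot label character identifier of the cell
#'
#' @exportClass CategoryCounts
setClass("CategoryCounts",
  representation(
    sfsSyn = "SiteFrequencySpectrum",
    sfsNonsyn = "SiteFrequencySpectrum",
    dSyn = "numeric",
    dNonsyn = "numeric",
    lSyn = "numeric",
    lNonsyn = "numeric",
    label = "character"
  )
)

setValidity("CategoryCounts", function(object) {
  msg <- character()
  if (object@sfsSyn@sampleSize != object@sfsNonsyn@sampleSize)
    msg <- c(msg, "synonymous and nonsynonymous SFS must share one sample size")
  if (object@dSyn < 0 || object@dNonsyn < 0)
    msg <- c(msg, "divergence counts must be nonnegative")
  if (object@lSyn < 0 || object@lNonsyn < 0)
    msg <- c(msg, "site totals must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Parameters of the Gamma-Exponential distribution of fitness effects
#'
#' Fitness effects are scaled selection coefficients S = 4 Ne s. The
#' deleterious class (probability 1 - pBen) follows a reflected Gamma on
#' S < 0 with shape \code{shape} and mean \code{meanDel} (negative); the
#' beneficial class (probability \code{pBen}) follows an Exponential on
#' S > 0 with mean \code{meanBen}. \code{theta} is the per-site
#' mutation-scaled diversity entering the Poisson random field
#' expectations. \code{distortion} is an optional vector of per-class
#' multipliers r_i shared by both site classes (r_1 = 1); length zero
#' disables it.
#'
#' @exportClass DFEParams
setClass("DFEParams",
  representation(
    shape = "numeric",
    meanDel = "numeric",
    pBen = "numeric",
    meanBen = "numeric",
    theta = "numeric",
    distortion = "numeric"
  )
)

setValidity("DFEParams", function(object) {
  msg <- character()
  if (!(is.finite(object@shape) && object@shape > 0))
    msg <- c(msg, "shape must be positive")
  if (!(is.finite(object@meanDel) && object@meanDel < 0))
    msg <- c(msg, "meanDel must be negative")
  if (!(is.finite(object@pBen) && object@pBen >= 0 && object@pBen <= 1))
    msg <- c(msg, "pBen must lie in [0, 1]")
  if (!(is.finite(object@meanBen) && object@meanBen > 0))
    msg <- c(msg, "meanBen must be positive")
  if (!(is.finite(object@theta) && object@theta > 0))
    msg <- c(msg, "theta must be positive")
  if (length(object@distortion)) {
    if (any(!is.finite(object@distortion)) || any(object@distortion <= 0))
      msg <- c(msg, "distortion multipliers must be positive and finite")
    if (abs(object@distortion[1] - 1) > 1e-12)
      msg <- c(msg, "first distortion multiplier must equal 1")
  }
  if (length(msg)) msg else TRUE
})

#' A fitted DFE with derived substitution rates
#'
#' @slot params the maximum-likelihood \linkS4class{DFEParams}
#' @slot loglik maximized Poisson random field log-likelihood
#' @slot omega dN/dS-style rate ratio (Dn/Ln)/(Ds/Ls)
#' @slot omegaNa expected nonadaptive component under the fitted DFE
#' @slot omegaA adaptive component, omega - omegaNa (may be negative)
#' @slot alpha omegaA / omega (NA when omega is zero)
#' @slot converged logical optimizer status
#' @slot nEval number of likelihood evaluations spent
#'
#' @exportClass DFEFit
setClass("DFEFit",
  representation(
    params = "DFEParams",
    loglik = "numeric",
    omega = "numeric",
    omegaNa = "numeric",
    omegaA = "numeric",
    alpha = "numeric",
    converged = "logical",
    nEval = "integer"
  )
)

setValidity("DFEFit", function(object) {
  msg <- character()
  if (is.finite(object@omega) && object@omega < 0)
    msg <- c(msg, "omega must be nonnegative")
  if (is.finite(object@omegaNa) && object@omegaNa < 0)
    msg <- c(msg, "omegaNa must be nonnegative")
  if (is.finite(object@omega) && is.finite(object@omegaNa) &&
      abs(object@omegaA - (object@omega - object@omegaNa)) > 1e-8 * max(1, abs(object@omega)))
    msg <- c(msg, "omegaA must equal omega - omegaNa")
  if (length(msg)) msg else TRUE
})

#' One gene's counts and metadata
#'
#' @slot geneId character identifier
#' @slot stratum integer phylostratum (1 = oldest)
#' @slot counts the gene's \linkS4class{CategoryCounts}
#' @slot length protein length in amino acids (NA allowed)
#' @slot expression mean expression level (NA allowed)
#' @slot rsa mean relative solvent accessibility in [0, 1] (NA allowed)
#' @slot disorder mean intrinsic disorder (hot loop) score in [0, 1] (NA allowed)
#' @slot evalue BLAST E-value of the deepest homolog hit (NA allowed)
#' @slot pnps ratio of nonsynonymous to synonymous polymorphism (NA allowed)
#' @slot chromosome chromosome label
#' @slot goTerms character vector of GO term identifiers
#'
#' @exportClass GeneRecord
setClass("GeneRecord",
  representation(
    geneId = "character",
    stratum = "integer",
    counts = "CategoryCounts",
    length = "numeric",
    expression = "numeric",
    rsa = "numeric",
    disorder = "numeric",
    evalue = "numeric",
    pnps = "numeric",
    chromosome = "character",
    goTerms = "character"
  ),
  prototype(
    length = NA_real_, expression = NA_real_, rsa = NA_real_,
    disorder = NA_real_, evalue = NA_real_, pnps = NA_real_,
    chromosome = NA_character_, goTerms = character()
  )
)

setValidity("GeneRecord", function(object) {
  msg <- character()
  if (length(object@stratum) != 1L || is.na(object@stratum) || object@stratum < 1L)
    msg <- c(msg, "stratum must be a positive integer")
  for (s in c("rsa", "disorder")) {
    v <- slot(object, s)
    if (!is.na(v) && (v < 0 || v > 1))
      msg <- c(msg, sprintf("%s must lie in [0, 1]", s))
  }
  if (!is.na(object@evalue) && object@evalue < 0)
    msg <- c(msg, "evalue must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Grantham-distance partition of one-step amino-acid pairs
#'
#' @slot distance symmetric 20 x 20 Grantham distance matrix, zero diagonal
#' @slot pairs data.frame of unordered amino-acid pairs reachable by a
#'   single nucleotide change: columns aa1, aa2, distance, mutTypes
#'   (comma-separated unordered nucleotide pairs such as "A<>T")
#' @slot bins integer vector over rows of \code{pairs}, bin index 1..nBins
#' @slot gbar mean Grantham distance of the member pairs per bin
#' @slot breaks numeric bin boundaries used (for reporting)
#'
#' @exportClass GranthamPartition
setClass("GranthamPartition",
  representation(
    distance = "matrix",
    pairs = "data.frame",
    bins = "integer",
    gbar = "numeric",
    breaks = "numeric"
  )
)

setValidity("GranthamPartition", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@distance, t(object@distance))))
    msg <- c(msg, "distance matrix must be symmetric")
  if (any(diag(object@distance) != 0))
    msg <- c(msg, "distance matrix must have zero diagonal")
  if (any(object@distance < 0))
    msg <- c(msg, "distances must be nonnegative")
  if (length(object@bins) != nrow(object@pairs))
    msg <- c(msg, "bins must assign every pair")
  nb <- length(object@gbar)
  for (b in seq_len(nb)) {
    d <- object@pairs$distance[object@bins == b]
    if (length(d) && (object@gbar[b] < min(d) - 1e-9 || object@gbar[b] > max(d) + 1e-9))
      msg <- c(msg, sprintf("gbar of bin %d outside member distance range", b))
  }
  if (length(msg)) msg else TRUE
})

#' Site-weighted mean Grantham distances of adaptive and nonadaptive
#' substitutions
#'
#' @slot gbarA,gbarNa the weighted means over distance bins
#' @slot omegaA,omegaNa per-bin adaptive / nonadaptive rates
#' @slot gbarBin per-bin mean Grantham distance
#' @slot nSites per-bin nonsynonymous site counts (the weights)
#'
#' @exportClass GbarResult
setClass("GbarResult",
  representation(
    gbarA = "numeric",
    gbarNa = "numeric",
    omegaA = "numeric",
    omegaNa = "numeric",
    gbarBin = "numeric",
    nSites = "numeric"
  )
)

setValidity("GbarResult", function(object) {
  msg <- character()
  tot <- sum(object@nSites)
  if (tot > 0) {
    if (abs(object@gbarA - sum(object@omegaA * object@gbarBin * object@nSites) / tot) >
        1e-8 * max(1, abs(object@gbarA)))
      msg <- c(msg, "gbarA does not reproduce its weighted sum")
    if (abs(object@gbarNa - sum(object@omegaNa * object@gbarBin * object@nSites) / tot) >
        1e-8 * max(1, abs(object@gbarNa)))
      msg <- c(msg, "gbarNa does not reproduce its weighted sum")
  }
  if (length(msg)) msg else TRUE
})

#' Bootstrap replicates of a statistic (or several)
#'
#' @slot replicates matrix, one row per retained replicate, one column per
#'   statistic
#' @slot B requested number of replicates
#' @slot nDropped replicates dropped for fit failure
#' @slot mean,ciLow,ciHigh per-statistic mean and 95 percent percentile
#'   interval over retained replicates
#'
#' @exportClass BootstrapResult
setClass("BootstrapResult",
  representation(
    replicates = "matrix",
    B = "integer",
    nDropped = "integer",
    mean = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric"
  )
)

setValidity("BootstrapResult", function(object) {
  msg <- character()
  if (nrow(object@replicates) + object@nDropped != object@B)
    msg <- c(msg, "retained + dropped replicates must equal B")
  ok <- is.finite(object@ciLow) & is.finite(object@ciHigh)
  if (any(object@ciLow[ok] > object@ciHigh[ok]))
    msg <- c(msg, "ciLow must not exceed ciHigh")
  if (length(msg)) msg else TRUE
})
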
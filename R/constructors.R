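#' Construct a SiteFrequencySpectrum
#'
#' @param counts numeric vector of derived-allele class counts, length n-1
#' @param nSites effective number of sites of the class
#' @param siteClass "synonymous", "nonsynonymous" or "fourfold_by_muttype"
#' @param sampleSize haplotype count n; defaults to length(counts) + 1
#' @return a \linkS4class{SiteFrequencySpectrum}
#' @examples
#' SiteFrequencySpectrum(c(5, 2, 1), nSites = 100, siteClass = "synonymous")
#' @export
SiteFrequencySpectrum <- function(counts, nSites, siteClass,
                                  sampleSize = length(counts) + 1L) {
  new("SiteFrequencySpectrum",
      sampleSize = as.integer(sampleSize),
      counts = as.numeric(counts),
      nSites = as.numeric(nSites),
      siteClass = siteClass)
}

#' Construct a CategoryCounts cell
#'
#' @param sfsSyn,sfsNonsyn synonymous / nonsynonymous
#'   \linkS4class{SiteFrequencySpectrum} objects at one sample size
#' @param dSyn,dNonsyn fixed-difference counts against the outgroup
#' @param lSyn,lNonsyn effective site totals; default to the nSites of the
#'   two spectra
#' @param label cell identifier
#' @return a \linkS4class{CategoryCounts}
#' @export
CategoryCounts <- function(sfsSyn, sfsNonsyn, dSyn, dNonsyn,
                           lSyn = sfsSyn@nSites, lNonsyn = sfsNonsyn@nSites,
                           label = "") {
  new("CategoryCounts",
      sfsSyn = sfsSyn, sfsNonsyn = sfsNonsyn,
      dSyn = as.numeric(dSyn), dNonsyn = as.numeric(dNonsyn),
      lSyn = as.numeric(lSyn), lNonsyn = as.numeric(lNonsyn),
      label = as.character(label))
}

#' Construct DFE parameters (Gamma-Exponential)
#'
#' @param shape Gamma shape of the deleterious class
#' @param meanDel mean scaled selection coefficient of the deleterious
#'   class, negative (S = 4 Ne s)
#' @param pBen probability that a new nonsynonymous mutation is beneficial
#' @param meanBen mean scaled coefficient of the beneficial (Exponential)
#'   class, positive
#' @param theta per-site mutation-scaled diversity
#' @param distortion optional vector of per-frequency-class multipliers
#'   r_i (r_1 = 1), shared between site classes; default disabled
#' @return a \linkS4class{DFEParams}
#' @examples
#' DFEParams(shape = 0.3, meanDel = -2000, pBen = 0.01, meanBen = 10,
#'           theta = 0.01)
#' @export
DFEParams <- function(shape, meanDel, pBen = 0, meanBen = 10, theta = 0.01,
                      distortion = numeric()) {
  new("DFEParams", shape = as.numeric(shape), meanDel = as.numeric(meanDel),
      pBen = as.numeric(pBen), meanBen = as.numeric(meanBen),
      theta = as.numeric(theta), distortion = as.numeric(distortion))
}

#' Construct a GeneRecord
#'
#' @param geneId gene identifier
#' @param stratum phylostratum index, 1 = oldest
#' @param counts the gene's \linkS4class{CategoryCounts}
#' @param length,expression,rsa,disorder,evalue,pnps optional cofactors
#' @param chromosome,goTerms optional chromosome label and GO annotations
#' @return a \linkS4class{GeneRecord}
#' @export
GeneRecord <- function(geneId, stratum, counts, length = NA_real_,
                       expression = NA_real_, rsa = NA_real_,
                       disorder = NA_real_, evalue = NA_real_,
                       pnps = NA_real_, chromosome = NA_character_,
                       goTerms = character()) {
  new("GeneRecord", geneId = as.character(geneId),
      stratum = as.integer(stratum), counts = counts,
      length = as.numeric(length), expression = as.numeric(expression),
      rsa = as.numeric(rsa), disorder = as.numeric(disorder),
      evalue = as.numeric(evalue), pnps = as.numeric(pnps),
      chromosome = as.character(chromosome), goTerms = as.character(goTerms))
}

## ---- accessors ----

#' @rdname accessors
#' @param object an adaptwalk S4 object
#' @export
setGeneric("sampleSize", function(object) standardGeneric("sampleSize"))

#' @rdname accessors
#' @export
setMethod("sampleSize", "SiteFrequencySpectrum", function(object) object@sampleSize)

#' @rdname accessors
#' @export
setMethod("sampleSize", "CategoryCounts", function(object) object@sfsSyn@sampleSize)

#' Accessors for adaptwalk objects
#'
#' Small read-only accessors: \code{sampleSize}, \code{sfsCounts},
#' \code{nSites}, \code{divergence}, \code{siteTotals}, \code{omegaValues},
#' \code{dfeParams}.
#'
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("sfsCounts", function(object) standardGeneric("sfsCounts"))

#' @rdname accessors
#' @export
setMethod("sfsCounts", "SiteFrequencySpectrum", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("nSites", function(object) standardGeneric("nSites"))

#' @rdname accessors
#' @export
setMethod("nSites", "SiteFrequencySpectrum", function(object) object@nSites)

#' @rdname accessors
#' @export
setGeneric("divergence", function(object) standardGeneric("divergence"))

#' @rdname accessors
#' @export
setMethod("divergence", "CategoryCounts",
          function(object) c(syn = object@dSyn, nonsyn = object@dNonsyn))

#' @rdname accessors
#' @export
setGeneric("siteTotals", function(object) standardGeneric("siteTotals"))

#' @rdname accessors
#' @export
setMethod("siteTotals", "CategoryCounts",
          function(object) c(syn = object@lSyn, nonsyn = object@lNonsyn))

#' @rdname accessors
#' @export
setGeneric("omegaValues", function(object) standardGeneric("omegaValues"))

#' @rdname accessors
#' @export
setMethod("omegaValues", "DFEFit", function(object)
  c(omega = object@omega, omegaNa = object@omegaNa,
    omegaA = object@omegaA, alpha = object@alpha))

#' @rdname accessors
#' @export
setGeneric("dfeParams", function(object) standardGeneric("dfeParams"))

#' @rdname accessors
#' @export
setMethod("dfeParams", "DFEFit", function(object) object@params)

## ---- show methods ----

setMethod("show", "SiteFrequencySpectrum", function(object) {
  cat(sprintf("SiteFrequencySpectrum (%s), n = %d, L = %.6g\n",
              object@siteClass, object@sampleSize, object@nSites))
  cat("  counts:", paste(signif(object@counts, 4), collapse = " "), "\n")
})

setMethod("show", "CategoryCounts", function(object) {
  cat(sprintf("CategoryCounts '%s', n = %d\n", object@label,
              sampleSize(object)))
  cat(sprintf("  nonsyn: L = %.6g, D = %g, SFS total = %.6g\n",
              object@lNonsyn, object@dNonsyn, sum(object@sfsNonsyn@counts)))
  cat(sprintf("  syn:    L = %.6g, D = %g, SFS total = %.6g\n",
              object@lSyn, object@dSyn, sum(object@sfsSyn@counts)))
})

setMethod("show", "DFEParams", function(object) {
  cat(sprintf(
    "Gamma-Exponential DFE: shape = %.4g, meanDel = %.4g, pBen = %.4g, meanBen = %.4g, theta = %.4g\n",
    object@shape, object@meanDel, object@pBen, object@meanBen, object@theta))
  if (length(object@distortion))
    cat("  distortion r_i enabled (length", length(object@distortion), ")\n")
})

setMethod("show", "DFEFit", function(object) {
  cat("DFEFit:", if (object@converged) "converged" else "NOT converged",
      sprintf("(loglik = %.4f, %d evaluations)\n", object@loglik, object@nEval))
  show(object@params)
  cat(sprintf("  omega = %.5g, omegaNa = %.5g, omegaA = %.5g, alpha = %s\n",
              object@omega, object@omegaNa, object@omegaA,
              ifelse(is.na(object@alpha), "NA", sprintf("%.5g", object@alpha))))
})

setMethod("show", "GeneRecord", function(object) {
  cat(sprintf("GeneRecord %s (stratum %d, chromosome %s)\n",
              object@geneId, object@stratum, object@chromosome))
})

setMethod("show", "GranthamPartition", function(object) {
  cat(sprintf("GranthamPartition: %d one-step pairs in %d bins\n",
              nrow(object@pairs), length(object@gbar)))
  cat("  per-bin mean distance:", paste(round(object@gbar, 1), collapse = " "), "\n")
})

setMethod("show", "GbarResult", function(object) {
  cat(sprintf("GbarResult: gbarA = %.4g, gbarNa = %.4g over %d bins\n",
              object@gbarA, object@gbarNa, length(object@gbarBin)))
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("BootstrapResult: B = %d (%d dropped)\n",
              object@B, object@nDropped))
  tab <- rbind(mean = object@mean, ciLow = object@ciLow, ciHigh = object@ciHigh)
  print(signif(tab, 5))
})
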
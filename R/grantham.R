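## Grantham physicochemical distances, one-mutational-step amino-acid
## pairs, distance bins, and the site-weighted mean-distance statistics
## for adaptive and nonadaptive substitutions.

## Grantham (1974) side-chain property values: composition c, polarity p,
## molecular volume v, and the distance formula constants.
.granthamProperties <- function() {
  data.frame(
    aa = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
           "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
    c = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
          0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
    p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
          6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
    v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
          136, 55, 96, 85, 56, 119, 54, 83, 105, 170),
    stringsAsFactors = FALSE
  )
}

#' Grantham distance matrix
#'
#' The 20 x 20 symmetric matrix of physicochemical distances between
#' amino acids. \code{source = "table"} loads the integer table shipped
#' with the package (the canonical values used throughout);
#' \code{source = "formula"} recomputes distances from the side-chain
#' composition, polarity and volume values with the published weighting
#' constants (alpha = 1.833, beta = 0.1018, gamma = 0.000399) and the
#' normalization that sets the mean inter-residue distance to 100. The
#' two agree to integer rounding; formula mode serves as a cross-check.
#'
#' @param source "table" or "formula"
#' @return named 20 x 20 numeric matrix (one-letter amino-acid codes),
#'   zero diagonal
#' @examples
#' D <- granthamMatrix()
#' D["L", "I"]  # 5
#' @export
granthamMatrix <- function(source = c("table", "formula")) {
  source <- match.arg(source)
  if (source == "table") {
    path <- system.file("extdata", "grantham_distances.tsv",
                        package = "adaptwalk")
    m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1,
                                     check.names = FALSE, sep = "\t"))
    storage.mode(m) <- "double"
    return(m)
  }
  pr <- .granthamProperties()
  a <- 1.833; b <- 0.1018; g <- 0.000399
  n <- nrow(pr)
  D <- matrix(0, n, n, dimnames = list(pr$aa, pr$aa))
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(a * (pr$c[i] - pr$c[j])^2 + b * (pr$p[i] - pr$p[j])^2 +
                      g * (pr$v[i] - pr$v[j])^2)
  rho <- 100 / mean(D[upper.tri(D)])
  D <- D * rho
  ord <- sort(pr$aa)
  D[ord, ord]
}

.pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

.mutType <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "<>")
}

#' One-mutational-step amino-acid pairs
#'
#' Brute-force enumeration over all sense codons and their nine
#' single-nucleotide neighbors. Changes involving a stop codon are
#' excluded. For each unordered amino-acid pair the set of mutation types
#' (unordered nucleotide pairs such as "A<>T") is recorded, together with
#' every codon participating in an interconversion of that type (needed
#' to weight the fourfold synonymous spectra by codon frequency).
#'
#' @param code genetic code table as in \code{\link{classifyDegeneracy}}
#' @return list with \code{pairs} (data.frame: aa1, aa2, mutTypes
#'   comma-string) and \code{edges} (data.frame: aa1, aa2, mutType,
#'   codon1, codon2, one row per codon interconversion)
#' @export
enumerateStepPairs <- function(code = .codonTable()) {
  codons <- names(code)[code != "*"]
  rows <- list()
  for (cd in codons) {
    nts <- strsplit(cd, "")[[1]]
    for (p in 1:3) for (alt in setdiff(.NUC, nts[p])) {
      nts2 <- nts; nts2[p] <- alt
      cd2 <- paste(nts2, collapse = "")
      if (code[cd2] == "*") next
      if (code[cd] == code[cd2]) next
      if (cd >= cd2) next  # each unordered codon edge once
      rows[[length(rows) + 1L]] <- data.frame(
        aa1 = pmin(code[cd], code[cd2]), aa2 = pmax(code[cd], code[cd2]),
        mutType = .mutType(nts[p], alt),
        codon1 = cd, codon2 = cd2, stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, rows)
  rownames(edges) <- NULL
  key <- .pairKey(edges$aa1, edges$aa2)
  pairs <- do.call(rbind, lapply(split(edges, key), function(e) {
    data.frame(aa1 = e$aa1[1], aa2 = e$aa2[1],
               mutTypes = paste(sort(unique(e$mutType)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  list(pairs = pairs, edges = edges)
}

#' Equal-count Grantham-distance partition of one-step pairs
#'
#' Assigns every one-step amino-acid pair to one of \code{nBins} bins of
#' (as nearly as possible) equal pair count, ordered by Grantham
#' distance, and records the mean distance per bin and the bin
#' boundaries.
#'
#' @param nBins number of bins (default 10)
#' @param distance Grantham matrix, see \code{\link{granthamMatrix}}
#' @param stepPairs result of \code{\link{enumerateStepPairs}}
#' @return a \linkS4class{GranthamPartition}
#' @export
granthamPartition <- function(nBins = 10L,
                              distance = granthamMatrix("table"),
                              stepPairs = enumerateStepPairs()) {
  pairs <- stepPairs$pairs
  pairs$distance <- distance[cbind(pairs$aa1, pairs$aa2)]
  ord <- order(pairs$distance, pairs$aa1, pairs$aa2)
  bins <- integer(nrow(pairs))
  bins[ord] <- ceiling(seq_len(nrow(pairs)) * nBins / nrow(pairs))
  gbar <- vapply(seq_len(nBins), function(b) mean(pairs$distance[bins == b]),
                 numeric(1))
  breaks <- vapply(seq_len(nBins), function(b) max(pairs$distance[bins == b]),
                   numeric(1))
  new("GranthamPartition", distance = distance, pairs = pairs,
      bins = as.integer(bins), gbar = gbar, breaks = breaks)
}

#' Codon-frequency-weighted fourfold synonymous SFS for one pair
#'
#' For an amino-acid pair separated by several mutation types, the
#' synonymous reference spectrum is the weighted average of the fourfold
#' spectra of those mutation types, each weighted by the summed frequency
#' of the pair's codons whose interconversion uses that type.
#'
#' @param pair character vector of the two amino acids
#' @param sfsByMuttype named list, mutation type -> either a
#'   \linkS4class{SiteFrequencySpectrum} or a list with elements
#'   \code{sfs}, \code{d}, \code{l} (as from
#'   \code{\link{fourfoldSfsByMuttype}})
#' @param codonFreqs named numeric vector of codon frequencies
#' @param stepPairs result of \code{\link{enumerateStepPairs}}
#' @return same shape as the elements of \code{sfsByMuttype}: a weighted
#'   \linkS4class{SiteFrequencySpectrum}, or a list \code{sfs}/\code{d}/
#'   \code{l} of class-wise weighted averages; the weights used are
#'   attached as attribute \code{weights}
#' @export
weightedFourfoldSfs <- function(pair, sfsByMuttype, codonFreqs,
                                stepPairs = enumerateStepPairs()) {
  e <- stepPairs$edges
  sel <- .pairKey(e$aa1, e$aa2) == .pairKey(pair[1], pair[2])
  if (!any(sel)) stop("not a one-step amino-acid pair: ",
                      paste(pair, collapse = "/"))
  e <- e[sel, , drop = FALSE]
  types <- sort(unique(e$mutType))
  missing <- setdiff(types, names(sfsByMuttype))
  if (length(missing))
    stop("no fourfold SFS for mutation type(s): ", paste(missing, collapse = ", "))
  w <- vapply(types, function(tp) {
    cds <- unique(c(e$codon1[e$mutType == tp], e$codon2[e$mutType == tp]))
    sum(codonFreqs[cds], na.rm = TRUE)
  }, numeric(1))
  if (sum(w) <= 0) stop("zero total codon-frequency weight for pair ",
                        paste(pair, collapse = "/"))
  w <- w / sum(w)
  els <- sfsByMuttype[types]
  isSfs <- is(els[[1]], "SiteFrequencySpectrum")
  getSfs <- function(x) if (is(x, "SiteFrequencySpectrum")) x else x$sfs
  counts <- Reduce(`+`, Map(function(x, wi) getSfs(x)@counts * wi, els, w))
  L <- sum(vapply(seq_along(els), function(i)
    w[i] * (if (isSfs) getSfs(els[[i]])@nSites else els[[i]]$l), numeric(1)))
  sfs <- SiteFrequencySpectrum(counts, nSites = L,
                               siteClass = "fourfold_by_muttype",
                               sampleSize = getSfs(els[[1]])@sampleSize)
  out <- if (isSfs) sfs else
    list(sfs = sfs,
         d = sum(vapply(seq_along(els), function(i) w[i] * els[[i]]$d, numeric(1))),
         l = L)
  attr(out, "weights") <- w
  out
}

#' Pool per-pair counts into Grantham-distance bins
#'
#' Within one age class, pools the nonsynonymous spectra and divergence
#' of all pairs of a bin, and builds the synonymous side by summing each
#' pair's codon-frequency-weighted fourfold spectrum (weights as in
#' \code{\link{weightedFourfoldSfs}}). Records the nonsynonymous site
#' count N_i per bin. Empty bins are flagged with N_i = 0 and no counts.
#'
#' @param pairData named list keyed "A|C" etc.: per pair a list with
#'   \code{sfs} (nonsynonymous \linkS4class{SiteFrequencySpectrum}),
#'   \code{d} (nonsynonymous divergence) and \code{l} (nonsynonymous
#'   sites)
#' @param partition a \linkS4class{GranthamPartition}
#' @param sfsByMuttype,codonFreqs fourfold reference spectra and codon
#'   frequencies, see \code{\link{weightedFourfoldSfs}}
#' @param stepPairs result of \code{\link{enumerateStepPairs}}
#' @return data.frame with columns bin, gbar, nSites and list column
#'   \code{counts} (\linkS4class{CategoryCounts} or NULL for empty bins)
#' @export
perBinCounts <- function(pairData, partition, sfsByMuttype, codonFreqs,
                         stepPairs = enumerateStepPairs()) {
  key <- .pairKey(partition@pairs$aa1, partition@pairs$aa2)
  nBins <- length(partition@gbar)
  rows <- data.frame(bin = seq_len(nBins), gbar = partition@gbar,
                     nSites = 0)
  cells <- vector("list", nBins)
  for (b in seq_len(nBins)) {
    inBin <- key[partition@bins == b]
    present <- intersect(inBin, names(pairData))
    if (!length(present)) next
    sfsN <- NULL; dN <- 0; lN <- 0
    sfsS <- NULL; dS <- 0; lS <- 0
    for (pk in present) {
      pd <- pairData[[pk]]
      pair <- strsplit(pk, "|", fixed = TRUE)[[1]]
      syn <- weightedFourfoldSfs(pair, sfsByMuttype, codonFreqs, stepPairs)
      synL <- if (is(syn, "SiteFrequencySpectrum"))
        list(sfs = syn, d = 0, l = syn@nSites) else syn
      sfsN <- if (is.null(sfsN)) pd$sfs@counts else sfsN + pd$sfs@counts
      dN <- dN + pd$d; lN <- lN + pd$l
      sfsS <- if (is.null(sfsS)) synL$sfs@counts else sfsS + synL$sfs@counts
      dS <- dS + synL$d; lS <- lS + synL$l
    }
    n <- pairData[[present[1]]]$sfs@sampleSize
    cells[[b]] <- CategoryCounts(
      SiteFrequencySpectrum(sfsS, nSites = lS, siteClass = "synonymous",
                            sampleSize = n),
      SiteFrequencySpectrum(sfsN, nSites = lN, siteClass = "nonsynonymous",
                            sampleSize = n),
      dSyn = dS, dNonsyn = dN, lSyn = lS, lNonsyn = lN,
      label = sprintf("bin%d", b))
    rows$nSites[b] <- lN
  }
  rows$counts <- cells
  rows
}

#' Site-weighted mean Grantham distance of adaptive and nonadaptive
#' substitutions
#'
#' Given per-bin adaptive and nonadaptive rates and nonsynonymous site
#' counts, computes the weighted sums
#' \code{gbarA = sum_i omegaA_i gbar_i N_i / sum_i N_i} (and likewise
#' \code{gbarNa}). Bins without data (N_i = 0 or missing rates) are
#' excluded from both sums; negative per-bin rates are propagated as-is.
#'
#' @param omegaA,omegaNa numeric per-bin rates (NA = empty bin)
#' @param gbarBin per-bin mean Grantham distances
#' @param nSites per-bin nonsynonymous site counts
#' @return a \linkS4class{GbarResult}
#' @examples
#' gbarStat(c(0.1, 0.3), c(0, 0), c(10, 100), c(1000, 500))@gbarA  # 10.667
#' @export
gbarStat <- function(omegaA, omegaNa, gbarBin, nSites) {
  keep <- is.finite(omegaA) & is.finite(omegaNa) & is.finite(nSites) &
    nSites > 0
  if (sum(nSites[keep]) <= 0)
    stop("no nonsynonymous sites in any usable bin")
  oA <- omegaA[keep]; oNa <- omegaNa[keep]
  gb <- gbarBin[keep]; Ni <- nSites[keep]
  new("GbarResult",
      gbarA = sum(oA * gb * Ni) / sum(Ni),
      gbarNa = sum(oNa * gb * Ni) / sum(Ni),
      omegaA = oA, omegaNa = oNa, gbarBin = gb, nSites = Ni)
}

#' Per-stratum Grantham-distance summaries of fixed differences
#'
#' Pools all one-step amino-acid fixed differences of each stratum and
#' reports the median and quartiles of their Grantham distances.
#' Substitutions whose pair is not reachable in one mutational step are
#' ignored; strata without qualifying substitutions get NA rows.
#'
#' @param substitutions data.frame with columns \code{stratum},
#'   \code{aa1}, \code{aa2}
#' @param distance Grantham matrix
#' @param stepPairs result of \code{\link{enumerateStepPairs}}
#' @return data.frame with columns stratum, n, median, q1, q3
#' @export
meanGranthamPerStratum <- function(substitutions,
                                   distance = granthamMatrix("table"),
                                   stepPairs = enumerateStepPairs()) {
  okPairs <- .pairKey(stepPairs$pairs$aa1, stepPairs$pairs$aa2)
  key <- .pairKey(substitutions$aa1, substitutions$aa2)
  keep <- key %in% okPairs
  substitutions <- substitutions[keep, , drop = FALSE]
  strata <- sort(unique(substitutions$stratum))
  out <- do.call(rbind, lapply(strata, function(s) {
    d <- distance[cbind(substitutions$aa1[substitutions$stratum == s],
                        substitutions$aa2[substitutions$stratum == s])]
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(stratum = s, n = length(d), median = q[2], q1 = q[1], q3 = q[3])
  }))
  rownames(out) <- NULL
  out
}
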
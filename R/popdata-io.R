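## Site classification and SFS construction from per-gene codon alignments.
## Coordinates are 0-based half-open internally; the reading frame starts at
## alignment column 0 and the alignment length must be a multiple of 3.

.NUC <- c("A", "C", "G", "T")

.codonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

.translate1 <- function(codon, code = .codonTable()) {
  aa <- code[codon]
  ifelse(is.na(aa), NA_character_, aa)
}

#' Degeneracy class of a codon position
#'
#' A position is fourfold degenerate when all three alternative nucleotides
#' leave the amino acid unchanged, zerofold when all three change it (a
#' change to a stop codon counts as changing the amino acid), twofold when
#' exactly one alternative is synonymous, and "other" otherwise. Codons
#' that are themselves stop codons, or that contain a non-ACGT character,
#' return NA (the site is treated as missing, never as an error).
#'
#' @param codon character vector of 3-letter codons
#' @param position integer vector of codon positions (1..3), recycled
#' @param code named character vector mapping codons to amino acids;
#'   defaults to the standard nuclear code
#' @return character vector in {"zero","two","four","other"} or NA
#' @examples
#' classifyDegeneracy("GGA", 3)  # "four"
#' classifyDegeneracy("TGG", 2)  # "zero"
#' @export
classifyDegeneracy <- function(codon, position, code = .codonTable()) {
  n <- max(length(codon), length(position))
  codon <- rep_len(toupper(codon), n)
  position <- rep_len(as.integer(position), n)
  out <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    cd <- strsplit(codon[k], "")[[1]]
    if (length(cd) != 3L || any(!cd %in% .NUC)) next
    aa0 <- code[codon[k]]
    if (is.na(aa0) || aa0 == "*") next
    alt <- setdiff(.NUC, cd[position[k]])
    aas <- vapply(alt, function(nt) {
      cd2 <- cd; cd2[position[k]] <- nt
      code[paste(cd2, collapse = "")]
    }, character(1))
    nsyn <- sum(aas == aa0 & aas != "*")
    out[k] <- if (nsyn == 3L) "four" else if (nsyn == 0L) "zero"
              else if (nsyn == 1L) "two" else "other"
  }
  out
}

.majorAllele <- function(column) {
  tab <- table(factor(column[column %in% .NUC], levels = .NUC))
  if (sum(tab) == 0L) return(NA_character_)
  names(tab)[which.max(tab)]  # deterministic tie-break: A < C < G < T
}

#' Per-site annotation table from a codon alignment
#'
#' Walks every alignment column of an in-frame ingroup alignment plus one
#' aligned outgroup sequence and records, per site: the consensus codon
#' context, degeneracy class, ingroup allele counts, outgroup allele, and
#' the resulting site type. Sites are typed as "mono" (no information),
#' "poly" (biallelic ingroup polymorphism polarized by the outgroup),
#' "div" (ingroup fixed for an allele differing from the outgroup),
#' "missing" (outgroup allele unavailable, or unusable codon context) or
#' "skipped" (more than two ingroup alleles, or outgroup matching neither
#' allele of a polymorphism -- such sites cannot be polarized and are
#' excluded from both the SFS and the divergence counts).
#'
#' Effective site totals Lsyn/Lnonsyn are tallied over usable consensus
#' codons by degeneracy: fourfold positions count 1 synonymous site,
#' zerofold 1 nonsynonymous site, twofold and other positions are split
#' 1/3 synonymous, 2/3 nonsynonymous by mutational opportunity. They are
#' attached as attributes \code{lSyn}, \code{lNonsyn}.
#'
#' @param ingroup a \code{Biostrings::DNAStringSet}, character vector of
#'   equal-length sequences, or character matrix (rows = haplotypes)
#' @param outgroup single aligned outgroup sequence (character or
#'   \code{DNAString})
#' @param code genetic code table as in \code{\link{classifyDegeneracy}}
#' @return data.frame with one row per alignment column plus attributes
#'   \code{lSyn}, \code{lNonsyn}, \code{nSkipped}
#' @export
buildSiteTable <- function(ingroup, outgroup, code = .codonTable()) {
  M <- .alignmentMatrix(ingroup)
  og <- .seqChars(outgroup)
  if (ncol(M) != length(og))
    stop("outgroup length does not match the ingroup alignment")
  if (ncol(M) %% 3L != 0L)
    stop("alignment length is not a multiple of 3 (frame error)")
  nsite <- ncol(M)
  ncodon <- nsite %/% 3L

  res <- data.frame(
    site = seq_len(nsite) - 1L,
    codonIndex = rep(seq_len(ncodon) - 1L, each = 3L),
    codonPos = rep(1:3, ncodon),
    degeneracy = NA_character_,
    cons = NA_character_,
    type = NA_character_,
    class = NA_character_,
    anc = NA_character_, der = NA_character_,
    aaAnc = NA_character_, aaDer = NA_character_,
    d = NA_integer_, m = NA_integer_,
    stringsAsFactors = FALSE
  )

  lSyn <- 0; lNonsyn <- 0; nSkipped <- 0L
  for (ci in seq_len(ncodon)) {
    cols <- (3L * (ci - 1L) + 1L):(3L * ci)
    cons <- vapply(cols, function(j) .majorAllele(M[, j]), character(1))
    codonOk <- !any(is.na(cons))
    consCodon <- if (codonOk) paste(cons, collapse = "") else NA_character_
    if (codonOk && (is.na(code[consCodon]) || code[consCodon] == "*"))
      codonOk <- FALSE
    for (p in 1:3) {
      j <- cols[p]
      if (!codonOk) { res$type[j] <- "missing"; next }
      deg <- classifyDegeneracy(consCodon, p, code)
      res$degeneracy[j] <- deg
      res$cons[j] <- cons[p]
      lSyn <- lSyn + switch(deg, four = 1, zero = 0, 1 / 3)
      lNonsyn <- lNonsyn + switch(deg, four = 0, zero = 1, 2 / 3)
      col <- M[, j]
      valid <- col %in% .NUC
      alleles <- unique(col[valid])
      m <- sum(valid)
      ogA <- og[j]
      if (length(alleles) > 2L) {
        res$type[j] <- "skipped"; nSkipped <- nSkipped + 1L; next
      }
      if (!ogA %in% .NUC) { res$type[j] <- "missing"; next }
      if (length(alleles) == 0L) { res$type[j] <- "missing"; next }
      if (length(alleles) == 1L) {
        if (alleles == ogA) { res$type[j] <- "mono"; next }
        ## fixed difference; classify with the ingroup codon as context
        cd2 <- cons; cd2[p] <- ogA
        aaIn <- code[consCodon]
        aaOut <- code[paste(cd2, collapse = "")]
        res$type[j] <- "div"
        res$anc[j] <- ogA; res$der[j] <- alleles
        res$aaAnc[j] <- aaOut; res$aaDer[j] <- aaIn
        res$class[j] <- if (!is.na(aaOut) && aaOut == aaIn) "synonymous" else "nonsynonymous"
        next
      }
      ## biallelic polymorphism
      if (!ogA %in% alleles) {
        res$type[j] <- "skipped"; nSkipped <- nSkipped + 1L; next
      }
      derived <- setdiff(alleles, ogA)
      dcount <- sum(col[valid] == derived)
      cdA <- cons; cdA[p] <- ogA
      cdD <- cons; cdD[p] <- derived
      aaA <- code[paste(cdA, collapse = "")]
      aaD <- code[paste(cdD, collapse = "")]
      res$type[j] <- "poly"
      res$anc[j] <- ogA; res$der[j] <- derived
      res$aaAnc[j] <- aaA; res$aaDer[j] <- aaD
      res$class[j] <- if (!is.na(aaA) && aaA == aaD) "synonymous" else "nonsynonymous"
      res$d[j] <- dcount; res$m[j] <- m
    }
  }
  attr(res, "lSyn") <- lSyn
  attr(res, "lNonsyn") <- lNonsyn
  attr(res, "nSkipped") <- nSkipped
  res
}

.alignmentMatrix <- function(ingroup) {
  if (inherits(ingroup, "DNAStringSet"))
    ingroup <- as.character(ingroup)
  if (is.character(ingroup)) {
    lens <- nchar(ingroup)
    if (length(unique(lens)) != 1L)
      stop("ingroup sequences are not aligned (unequal lengths)")
    return(do.call(rbind, strsplit(toupper(ingroup), "")))
  }
  if (is.matrix(ingroup)) return(toupper(ingroup))
  stop("unsupported ingroup representation")
}

.seqChars <- function(x) {
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet"))
    x <- as.character(x)[1]
  strsplit(toupper(x), "")[[1]]
}

#' Unfolded SFS and divergence counts for one gene
#'
#' Builds the per-gene \linkS4class{CategoryCounts}: synonymous and
#' nonsynonymous unfolded SFS polarized by the outgroup, fixed-difference
#' counts, and effective site totals, optionally down-sampling every
#' polymorphic site to a common haplotype number.
#'
#' @param ingroup,outgroup as in \code{\link{buildSiteTable}}
#' @param nTarget common haplotype number for the SFS; defaults to the
#'   number of ingroup sequences (sites with fewer valid genotypes are
#'   discarded)
#' @param mode down-sampling mode, see \code{\link{downsampleSfs}}
#' @param seed RNG seed for random-mode down-sampling
#' @param label gene identifier stored in the result
#' @return a \linkS4class{CategoryCounts}
#' @export
buildUnfoldedSfs <- function(ingroup, outgroup, nTarget = NULL,
                             mode = c("random", "expected"), seed = 1L,
                             label = "") {
  mode <- match.arg(mode)
  M <- .alignmentMatrix(ingroup)
  if (is.null(nTarget)) nTarget <- nrow(M)
  st <- buildSiteTable(ingroup, outgroup)
  sfsS <- downsampleSfs(st, nTarget, mode = mode, seed = seed,
                        siteClass = "synonymous")
  sfsN <- downsampleSfs(st, nTarget, mode = mode, seed = seed + 1L,
                        siteClass = "nonsynonymous")
  dS <- sum(st$type == "div" & st$class == "synonymous", na.rm = TRUE)
  dN <- sum(st$type == "div" & st$class == "nonsynonymous", na.rm = TRUE)
  sfsS@nSites <- attr(st, "lSyn")
  sfsN@nSites <- attr(st, "lNonsyn")
  CategoryCounts(sfsS, sfsN, dSyn = dS, dNonsyn = dN,
                 lSyn = attr(st, "lSyn"), lNonsyn = attr(st, "lNonsyn"),
                 label = label)
}

#' Down-sample polymorphic sites to a common haplotype number
#'
#' Projects each polymorphic site with \code{m >= nTarget} valid genotypes
#' onto a sample of \code{nTarget} haplotypes; sites with fewer genotypes
#' are discarded. In \code{random} mode one hypergeometric draw without
#' replacement is made per site (reproducible under \code{seed}); sites
#' monomorphic after sampling are dropped. In \code{expected} mode each
#' site distributes probability mass over derived-count classes by the
#' hypergeometric law; the mass falling on classes 0 and nTarget is the
#' expected monomorphic loss and is likewise dropped, so per-site retained
#' + dropped mass is exactly 1.
#'
#' @param sites a site table from \code{\link{buildSiteTable}}, or any
#'   data.frame with columns \code{d} (derived count), \code{m} (valid
#'   genotypes) and optionally \code{type}/\code{class}
#' @param nTarget target haplotype number, >= 2
#' @param mode "random" or "expected"
#' @param seed RNG seed used in random mode
#' @param siteClass restrict to "synonymous" or "nonsynonymous" sites when
#'   a \code{class} column is present; NULL uses all polymorphic rows
#' @return a \linkS4class{SiteFrequencySpectrum}; the number of sites
#'   dropped (monomorphic after sampling, or insufficient coverage) is
#'   attached as attributes \code{nDroppedMono}, \code{nDroppedCoverage}
#' @export
downsampleSfs <- function(sites, nTarget, mode = c("random", "expected"),
                          seed = 1L, siteClass = NULL) {
  mode <- match.arg(mode)
  nTarget <- as.integer(nTarget)
  if (nTarget < 2L) stop("nTarget must be at least 2")
  df <- sites
  if (!is.null(df$type)) df <- df[df$type == "poly" & !is.na(df$d), , drop = FALSE]
  if (!is.null(siteClass) && !is.null(df$class))
    df <- df[df$class == siteClass, , drop = FALSE]
  cls <- if (is.null(siteClass)) "synonymous" else siteClass
  counts <- numeric(nTarget - 1L)
  droppedMono <- 0; droppedCov <- 0L
  if (nrow(df)) {
    low <- df$m < nTarget
    droppedCov <- sum(low)
    df <- df[!low, , drop = FALSE]
  }
  if (nrow(df)) {
    if (mode == "random") {
      withr_seed <- function(expr) {
        old <- if (exists(".Random.seed", envir = globalenv()))
          get(".Random.seed", envir = globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
        set.seed(seed); expr
      }
      draws <- withr_seed(
        stats::rhyper(nrow(df), m = df$d, n = df$m - df$d, k = nTarget))
      keep <- draws > 0L & draws < nTarget
      droppedMono <- sum(!keep)
      counts <- tabulate(draws[keep], nbins = nTarget - 1L)
    } else {
      for (r in seq_len(nrow(df))) {
        pj <- stats::dhyper(seq(0L, nTarget), m = df$d[r], n = df$m[r] - df$d[r],
                            k = nTarget)
        counts <- counts + pj[2:nTarget]
        droppedMono <- droppedMono + pj[1] + pj[nTarget + 1L]
      }
    }
  }
  out <- SiteFrequencySpectrum(counts, nSites = sum(counts),
                               siteClass = cls, sampleSize = nTarget)
  attr(out, "nDroppedMono") <- droppedMono
  attr(out, "nDroppedCoverage") <- droppedCov
  out
}

#' Fourfold synonymous spectra split by mutation type
#'
#' Collects, from a site table, the unfolded SFS, divergence count and
#' effective site number of fourfold degenerate sites for each unordered
#' nucleotide pair ("A<>C", ..., "G<>T"). The fourfold site total is
#' apportioned to mutation types by opportunity: each fourfold site with
#' consensus allele X contributes 1/3 of a site to each pair containing X.
#'
#' @param sites site table from \code{\link{buildSiteTable}}
#' @param nTarget,mode,seed down-sampling controls as in
#'   \code{\link{downsampleSfs}}
#' @return named list (one element per observed mutation type) of lists
#'   with elements \code{sfs}, \code{d}, \code{l}
#' @export
fourfoldSfsByMuttype <- function(sites, nTarget, mode = c("random", "expected"),
                                 seed = 1L) {
  mode <- match.arg(mode)
  ff <- sites[!is.na(sites$degeneracy) & sites$degeneracy == "four", , drop = FALSE]
  mt <- function(a, b) paste(sort(c(a, b)), collapse = "<>")
  allTypes <- utils::combn(.NUC, 2, FUN = function(p) mt(p[1], p[2]))
  ## opportunity-based L per mutation type
  lByType <- stats::setNames(numeric(length(allTypes)), allTypes)
  ## every fourfold site, polymorphic or not, contributes opportunity from
  ## its consensus allele
  for (r in seq_len(nrow(ff))) {
    a <- ff$cons[r]
    if (is.na(a)) next
    for (b in setdiff(.NUC, a)) lByType[mt(a, b)] <- lByType[mt(a, b)] + 1 / 3
  }
  out <- list()
  for (tp in allTypes) {
    nts <- strsplit(tp, "<>", fixed = TRUE)[[1]]
    sel <- ff$type %in% c("poly", "div") &
      !is.na(ff$anc) & !is.na(ff$der) &
      ff$anc %in% nts & ff$der %in% nts & ff$anc != ff$der
    sub <- ff[sel, , drop = FALSE]
    if (!nrow(sub) && lByType[tp] == 0) next
    sfs <- downsampleSfs(sub, nTarget, mode = mode, seed = seed)
    sfs@siteClass <- "fourfold_by_muttype"
    out[[tp]] <- list(sfs = sfs, d = sum(sub$type == "div"), l = lByType[tp])
  }
  out
}

## ---- SFS-exchange text format ----
## One category per line:
## name \t n \t L_nonsyn \t SFS_N(1..n-1) \t L_syn \t SFS_S(1..n-1) \t D_nonsyn \t D_syn
## '#' starts a comment line.

#' Read categories from an SFS-exchange file
#'
#' @param path file path
#' @return named list of \linkS4class{CategoryCounts}
#' @seealso \code{\link{writeSfsExchange}}
#' @export
readSfsExchange <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (ln == "" || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 5L)
      stop(sprintf("SFS-exchange parse error at line %d: too few fields", k))
    name <- fields[1]
    n <- suppressWarnings(as.integer(fields[2]))
    if (is.na(n) || n < 2L)
      stop(sprintf("SFS-exchange parse error at line %d: bad sample size", k))
    need <- 2L + 1L + (n - 1L) + 1L + (n - 1L) + 2L
    if (length(fields) != need)
      stop(sprintf("SFS-exchange parse error at line %d: expected %d fields for n = %d, got %d",
                   k, need, n, length(fields)))
    num <- suppressWarnings(as.numeric(fields[-1]))
    if (any(is.na(num)))
      stop(sprintf("SFS-exchange parse error at line %d: non-numeric field", k))
    lN <- num[2]; sfsN <- num[3:(n + 1L)]
    lS <- num[n + 2L]; sfsS <- num[(n + 3L):(2L * n + 1L)]
    dN <- num[2L * n + 2L]; dS <- num[2L * n + 3L]
    if (any(c(sfsN, sfsS) < 0) || dN < 0 || dS < 0 || lN < 0 || lS < 0)
      stop(sprintf("SFS-exchange parse error at line %d: negative count", k))
    out[[name]] <- CategoryCounts(
      SiteFrequencySpectrum(sfsS, nSites = lS, siteClass = "synonymous",
                            sampleSize = n),
      SiteFrequencySpectrum(sfsN, nSites = lN, siteClass = "nonsynonymous",
                            sampleSize = n),
      dSyn = dS, dNonsyn = dN, lSyn = lS, lNonsyn = lN, label = name)
  }
  out
}

#' Write categories to an SFS-exchange file
#'
#' @param x a \linkS4class{CategoryCounts} or a list of them
#' @param path destination file
#' @return invisibly, the path
#' @export
writeSfsExchange <- function(x, path) {
  if (is(x, "CategoryCounts")) x <- stats::setNames(list(x), x@label)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SFS-exchange: name n L_nonsyn SFS_N(1..n-1) L_syn SFS_S(1..n-1) D_nonsyn D_syn",
             con)
  for (nm in names(x)) {
    cc <- x[[nm]]
    n <- sampleSize(cc)
    fields <- c(nm, n,
                format(cc@lNonsyn, digits = 15), format(cc@sfsNonsyn@counts, digits = 15),
                format(cc@lSyn, digits = 15), format(cc@sfsSyn@counts, digits = 15),
                format(cc@dNonsyn, digits = 15), format(cc@dSyn, digits = 15))
    writeLines(paste(trimws(fields), collapse = "\t"), con)
  }
  invisible(path)
}

#' Pool several CategoryCounts into one
#'
#' Class-wise addition of SFS counts, divergence and site totals; all
#' inputs must share one sample size. Pooling is additive and invariant to
#' the order of the inputs.
#'
#' @param ccList list of \linkS4class{CategoryCounts}
#' @param label label of the pooled cell
#' @return a \linkS4class{CategoryCounts}
#' @export
poolCounts <- function(ccList, label = "pooled") {
  stopifnot(length(ccList) >= 1L)
  ns <- vapply(ccList, sampleSize, integer(1))
  if (length(unique(ns)) != 1L)
    stop("cannot pool categories with different sample sizes")
  n <- ns[1]
  add <- function(f) Reduce(`+`, lapply(ccList, f))
  CategoryCounts(
    SiteFrequencySpectrum(add(function(cc) cc@sfsSyn@counts),
                          nSites = add(function(cc) cc@lSyn),
                          siteClass = "synonymous", sampleSize = n),
    SiteFrequencySpectrum(add(function(cc) cc@sfsNonsyn@counts),
                          nSites = add(function(cc) cc@lNonsyn),
                          siteClass = "nonsynonymous", sampleSize = n),
    dSyn = add(function(cc) cc@dSyn), dNonsyn = add(function(cc) cc@dNonsyn),
    lSyn = add(function(cc) cc@lSyn), lNonsyn = add(function(cc) cc@lNonsyn),
    label = label)
}
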
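## Assignment of genes to phylostrata and analysis cells: clade merging,
## cofactor high/low splits, E-value and pn/ps-mode filters, GO groupings.

#' A stratum-merging scheme
#'
#' Maps each input phylostratum (1 = oldest) to a merged age class. The
#' mapping must be monotone nondecreasing in age order and contiguous
#' (merged classes are consecutive runs of strata), so the age ordering
#' of the merged classes is preserved.
#'
#' @param mapping integer vector; element s is the merged class of
#'   stratum s. NA drops the stratum explicitly.
#' @param name scheme label
#' @return a list of class "StratumScheme"
#' @examples
#' # 12 strata -> 6 classes: merge 3-4, 5-6, 7-10 and 11-12
#' stratumScheme(c(1, 2, 3, 3, 4, 4, 5, 5, 5, 5, 6, 6), "length-scheme")
#' @export
stratumScheme <- function(mapping, name = "scheme") {
  mapping <- as.integer(mapping)
  obs <- mapping[!is.na(mapping)]
  if (length(obs)) {
    if (any(diff(obs[!is.na(obs)]) < 0))
      stop("stratum scheme must be monotone in age order")
    runs <- rle(obs)$values
    if (any(duplicated(runs)))
      stop("stratum scheme must merge contiguous strata only")
    if (!identical(sort(unique(obs)), seq_len(max(obs))))
      stop("merged class labels must be 1..K without gaps")
  }
  structure(list(mapping = mapping, name = name), class = "StratumScheme")
}

#' @export
print.StratumScheme <- function(x, ...) {
  cat(sprintf("StratumScheme '%s': %d strata -> %d classes\n", x$name,
              length(x$mapping), max(x$mapping, na.rm = TRUE)))
  invisible(x)
}

#' Merge phylostrata into age classes
#'
#' @param genes list of \linkS4class{GeneRecord}
#' @param scheme a \code{\link{stratumScheme}}; must cover every stratum
#'   observed in \code{genes} (NA mappings drop their genes)
#' @return list of genes with \code{stratum} replaced by the merged class
#'   index (1 = oldest); genes in dropped strata are removed
#' @export
mergeStrata <- function(genes, scheme) {
  strata <- vapply(genes, function(g) g@stratum, integer(1))
  uncovered <- setdiff(unique(strata), seq_along(scheme$mapping))
  if (length(uncovered))
    stop("scheme does not cover strata: ", paste(sort(uncovered), collapse = ", "))
  out <- list()
  for (g in genes) {
    cl <- scheme$mapping[g@stratum]
    if (is.na(cl)) next
    g@stratum <- cl
    out[[length(out) + 1L]] <- g
  }
  out
}

.cofactorValues <- function(genes, cofactor) {
  ok <- c("length", "expression", "rsa", "disorder", "evalue", "pnps")
  if (!cofactor %in% ok)
    stop("unknown cofactor field: ", cofactor)
  vapply(genes, function(g) slot(g, cofactor), numeric(1))
}

#' Median split of genes into low/high cofactor groups
#'
#' The threshold is the median of the defined cofactor values; ties at
#' the threshold are assigned to the low group (a deterministic rule
#' giving two roughly equal-sized groups). Genes with a missing cofactor
#' are dropped.
#'
#' @param genes list of \linkS4class{GeneRecord}
#' @param cofactor one of "length", "expression", "rsa", "disorder",
#'   "evalue", "pnps"
#' @return list with elements \code{low}, \code{high} (gene lists) and
#'   \code{threshold}
#' @export
splitHighLow <- function(genes, cofactor) {
  v <- .cofactorValues(genes, cofactor)
  keep <- !is.na(v)
  genes <- genes[keep]; v <- v[keep]
  if (length(v) < 2L)
    stop("cofactor defined for fewer than 2 genes")
  if (length(unique(v)) == 1L)
    stop("all cofactor values identical: no split possible")
  thr <- stats::median(v)
  list(low = genes[v <= thr], high = genes[v > thr], threshold = thr)
}

#' Retain genes with BLAST E-value strictly below a cutoff
#'
#' Genes with a missing E-value are dropped. The number of genes retained
#' is reported as a message.
#'
#' @param genes list of \linkS4class{GeneRecord}
#' @param cutoff positive E-value cutoff (e.g. 1e-150 or 1e-100)
#' @return filtered gene list
#' @export
filterByEvalue <- function(genes, cutoff) {
  if (!(is.finite(cutoff) || is.infinite(cutoff)) || cutoff <= 0)
    stop("cutoff must be positive")
  ev <- vapply(genes, function(g) g@evalue, numeric(1))
  keep <- !is.na(ev) & ev < cutoff
  message(sprintf("filterByEvalue: retained %d of %d genes (cutoff %g)",
                  sum(keep), length(genes), cutoff))
  genes[keep]
}

#' Half-sample mode estimator
#'
#' Robust deterministic mode of a unimodal sample: recursively keeps the
#' shortest half of the sorted data until at most 3 points remain.
#'
#' @param x numeric vector (NAs removed)
#' @return scalar mode estimate
#' @export
halfSampleMode <- function(x) {
  x <- sort(x[!is.na(x)])
  while (length(x) > 3L) {
    h <- ceiling(length(x) / 2)
    widths <- x[h:length(x)] - x[seq_len(length(x) - h + 1L)]
    j <- which.min(widths)  # ties: leftmost
    x <- x[j:(j + h - 1L)]
  }
  if (length(x) == 3L) {
    if (x[2] - x[1] < x[3] - x[2]) mean(x[1:2])
    else if (x[3] - x[2] < x[2] - x[1]) mean(x[2:3])
    else x[2]
  } else mean(x)
}

#' Filter genes to a window around the modal pn/ps value
#'
#' Retains genes whose pn/ps lies within \code{kSd} standard deviations
#' of the modal pn/ps (half-sample mode estimator). This is the control
#' for nonadaptive-rate variation: restricting to the modal purifying
#' regime removes the correlation between pn/ps and gene age.
#'
#' @param genes list of \linkS4class{GeneRecord}
#' @param kSd window half-width in SD units (e.g. 0.02 or 0.05)
#' @return filtered gene list (genes with undefined pn/ps are dropped)
#' @export
filterByPnpsMode <- function(genes, kSd) {
  v <- vapply(genes, function(g) g@pnps, numeric(1))
  def <- !is.na(v)
  if (!any(def)) stop("pn/ps undefined for all genes")
  mode <- halfSampleMode(v[def])
  sdv <- stats::sd(v[def])
  keep <- def & abs(v - mode) <= kSd * sdv
  if (sdv == 0) keep <- def  # all equal: everything is at the mode
  message(sprintf("filterByPnpsMode: mode %.4g, retained %d of %d genes",
                  mode, sum(keep), length(genes)))
  genes[keep]
}

#' Group genes by GO term, keeping terms rich in young genes
#'
#' Only GO terms annotating strictly more than \code{minYoung} genes in
#' the young strata are kept; a gene appears under every qualifying term
#' it carries.
#'
#' @param genes list of \linkS4class{GeneRecord}
#' @param minYoung minimum number of young genes (strict inequality)
#' @param youngStrata integer vector of stratum indices considered young
#' @return named list: GO term -> list of genes
#' @export
groupByGO <- function(genes, minYoung, youngStrata) {
  if (!length(youngStrata)) return(list())
  byTerm <- list()
  for (g in genes) for (tm in g@goTerms)
    byTerm[[tm]] <- c(byTerm[[tm]], list(g))
  keep <- vapply(byTerm, function(gl) {
    sum(vapply(gl, function(g) g@stratum %in% youngStrata, logical(1))) > minYoung
  }, logical(1))
  byTerm[keep]
}

#' Pool genes into (age class x group) cells
#'
#' @param genes list of \linkS4class{GeneRecord}
#' @param ageScheme optional \code{\link{stratumScheme}} applied first
#' @param groups optional named character vector gene id -> group label
#'   (e.g. from \code{\link{splitHighLow}} membership), or NULL for a
#'   single group
#' @return data.frame with columns ageClass, group, nGenes and a list
#'   column \code{counts} of pooled \linkS4class{CategoryCounts}; empty
#'   cells are absent (reported via message)
#' @export
buildCells <- function(genes, ageScheme = NULL, groups = NULL) {
  if (!is.null(ageScheme)) genes <- mergeStrata(genes, ageScheme)
  age <- vapply(genes, function(g) g@stratum, integer(1))
  grp <- if (is.null(groups)) rep("all", length(genes))
         else unname(groups[vapply(genes, function(g) g@geneId, character(1))])
  keep <- !is.na(grp)
  genes <- genes[keep]; age <- age[keep]; grp <- grp[keep]
  cells <- list(); labels <- character(); ages <- integer(); grps <- character()
  ng <- integer()
  for (a in sort(unique(age))) for (g in sort(unique(grp))) {
    sel <- age == a & grp == g
    if (!any(sel)) next
    lab <- sprintf("age%d_%s", a, g)
    cells[[length(cells) + 1L]] <-
      poolCounts(lapply(genes[sel], function(x) x@counts), label = lab)
    labels <- c(labels, lab); ages <- c(ages, a); grps <- c(grps, g)
    ng <- c(ng, sum(sel))
  }
  full <- length(unique(age)) * length(unique(grp))
  if (length(cells) < full)
    message(sprintf("buildCells: %d of %d cells empty", full - length(cells), full))
  out <- data.frame(label = labels, ageClass = ages, group = grps,
                    nGenes = ng, stringsAsFactors = FALSE)
  out$counts <- cells
  out
}
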
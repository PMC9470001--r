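## Counts-level synthetic data with the statistical structure the
## analysis assumes: per-gene SFS and divergence drawn from the Poisson
## random field expectations under stratum-dependent DFEs, cofactors
## correlated with age, and amino-acid substitution identities with
## controllable Grantham-distance structure.

## one global seed fans out to per-task seeds via a counter scheme
.fanSeed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 69621) %% 2147483399) + 1L
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Configuration of a synthetic adaptive-walk study
#'
#' The defaults define the simulated study conditions: six merged age
#' classes of 50 genes each, 20 sampled haplotypes, a shared deleterious
#' DFE (Gamma shape 0.3, mean scaled effect -2000), and -- when the
#' adaptive-walk gradient is on -- a beneficial-mutation probability
#' rising monotonically from the oldest to the youngest stratum together
#' with a Grantham-distance exponent rising from 0 to its maximum, so
#' that young genes both adapt faster and take larger physicochemical
#' steps. Cofactors are drawn with the age correlations the analysis is
#' meant to control for: young genes are shorter, less expressed, more
#' exposed (higher RSA), more disordered and have shallower homology
#' hits (larger E-values).
#'
#' @param nStrata number of age classes (1 = oldest)
#' @param genesPerStratum genes per class
#' @param sampleSize haplotype number n of the SFS
#' @param shape,meanDel deleterious DFE shared by all strata
#' @param theta per-site mutation-scaled diversity
#' @param muT per-site divergence opportunity (expected synonymous
#'   substitutions per site)
#' @param gradient logical: adaptive-walk gradient on/off
#' @param pBenRange beneficial probability at the oldest and youngest
#'   stratum (log-interpolated across strata; collapsed to its first
#'   element when \code{gradient} is FALSE)
#' @param meanBen mean beneficial scaled effect
#' @param granthamEffect maximum Grantham exponent (youngest stratum);
#'   the exponent rises linearly from 0 at the oldest stratum
#' @param lengthRange,exprRange,rsaRange,disorderRange,log10EvalRange
#'   cofactor means at the oldest and youngest stratum
#' @param seed global RNG seed
#' @return list of class "SimConfig"
#' @export
simConfig <- function(nStrata = 6L, genesPerStratum = 50L, sampleSize = 20L,
                      shape = 0.3, meanDel = -2000, theta = 0.02,
                      muT = 0.1, gradient = TRUE,
                      pBenRange = c(5e-4, 0.02), meanBen = 10,
                      granthamEffect = 2,
                      lengthRange = c(450, 250), exprRange = c(8, 3),
                      rsaRange = c(0.30, 0.45), disorderRange = c(0.06, 0.20),
                      log10EvalRange = c(-180, -60), seed = 1L) {
  stopifnot(nStrata >= 2L, genesPerStratum >= 1L, sampleSize >= 4L,
            theta > 0, muT >= 0, meanBen > 0)
  if (gradient && diff(pBenRange) < 0)
    stop("gradient mode requires pBen nondecreasing toward the youngest stratum")
  pBen <- if (gradient)
    exp(seq(log(pBenRange[1]), log(pBenRange[2]), length.out = nStrata))
  else rep(pBenRange[1], nStrata)
  expo <- if (gradient) seq(0, granthamEffect, length.out = nStrata)
          else rep(0, nStrata)
  structure(list(
    nStrata = as.integer(nStrata), genesPerStratum = as.integer(genesPerStratum),
    sampleSize = as.integer(sampleSize), shape = shape, meanDel = meanDel,
    theta = theta, muT = muT, gradient = gradient, pBen = pBen,
    meanBen = meanBen, granthamExponent = expo,
    lengthRange = lengthRange, exprRange = exprRange, rsaRange = rsaRange,
    disorderRange = disorderRange, log10EvalRange = log10EvalRange,
    seed = as.integer(seed)), class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf("SimConfig: %d strata x %d genes, n = %d, gradient %s\n",
              x$nStrata, x$genesPerStratum, x$sampleSize,
              if (x$gradient) "on" else "off"))
  invisible(x)
}

#' Simulate one gene's counts under a DFE
#'
#' SFS class counts are independent Poisson draws around the PRF
#' expectations of \code{\link{expectedSfs}}; divergence counts are
#' Poisson with synonymous mean \code{lSyn muT} and nonsynonymous mean
#' \code{lNonsyn muT (omega_na + omega_a)}, the rates being the
#' fixation-integral values of the DFE itself. The true rates are
#' attached as attribute \code{truth}.
#'
#' @param params a \linkS4class{DFEParams}
#' @param lNonsyn,lSyn effective site numbers
#' @param n haplotype sample size
#' @param muT per-site divergence opportunity
#' @param seed RNG seed (draws are bit-reproducible)
#' @param label gene identifier
#' @param quad quadrature controls
#' @return a \linkS4class{CategoryCounts}
#' @export
simulateGene <- function(params, lNonsyn, lSyn, n, muT, seed,
                         label = "gene", quad = dfeQuadControl()) {
  lam <- expectedSfs(params, n, lSyn, lNonsyn, quad)
  oNa <- omegaNaExpected(params, quad)
  oA <- omegaAExpected(params, quad)
  .withSeed(seed, {
    sfsS <- stats::rpois(n - 1L, lam$lambdaSyn)
    sfsN <- stats::rpois(n - 1L, lam$lambdaNonsyn)
    dS <- stats::rpois(1L, lSyn * muT)
    dN <- stats::rpois(1L, lNonsyn * muT * (oNa + oA))
    cc <- CategoryCounts(
      SiteFrequencySpectrum(sfsS, nSites = lSyn, siteClass = "synonymous",
                            sampleSize = n),
      SiteFrequencySpectrum(sfsN, nSites = lNonsyn,
                            siteClass = "nonsynonymous", sampleSize = n),
      dSyn = dS, dNonsyn = dN, lSyn = lSyn, lNonsyn = lNonsyn, label = label)
    attr(cc, "truth") <- c(omegaNa = oNa, omegaA = oA)
    cc
  })
}

#' Sample amino-acid pairs for substitutions with Grantham structure
#'
#' Draws one-step amino-acid pairs with probability proportional to
#' mutational opportunity (number of codon interconversions) times
#' \code{distance^exponent} for adaptive substitutions, and times
#' \code{distance^-exponent} for nonadaptive ones, so a positive
#' exponent pushes adaptive substitutions toward physicochemically
#' distant pairs.
#'
#' @param count number of substitutions to draw
#' @param exponent Grantham exponent (0 = opportunity-weighted uniform)
#' @param class "adaptive" or "nonadaptive"
#' @param seed RNG seed
#' @param stepPairs result of \code{\link{enumerateStepPairs}}
#' @param distance Grantham matrix
#' @return data.frame with columns aa1, aa2, class (empty for count 0)
#' @export
simulateSubstitutionPairs <- function(count, exponent = 0,
                                      class = c("adaptive", "nonadaptive"),
                                      seed = 1L,
                                      stepPairs = enumerateStepPairs(),
                                      distance = granthamMatrix("table")) {
  class <- match.arg(class)
  pairs <- stepPairs$pairs
  key <- .pairKey(pairs$aa1, pairs$aa2)
  opp <- table(.pairKey(stepPairs$edges$aa1, stepPairs$edges$aa2))[key]
  d <- distance[cbind(pairs$aa1, pairs$aa2)]
  ex <- if (class == "adaptive") exponent else -exponent
  w <- as.numeric(opp) * d^ex
  if (count == 0)
    return(data.frame(aa1 = character(), aa2 = character(),
                      class = character(), stringsAsFactors = FALSE))
  idx <- .withSeed(seed,
                   sample.int(nrow(pairs), count, replace = TRUE, prob = w))
  data.frame(aa1 = pairs$aa1[idx], aa2 = pairs$aa2[idx], class = class,
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic study
#'
#' Generates everything the pipeline consumes: per-gene counts and
#' metadata across age strata, the stratum-level truth table, a
#' substitutions list with adaptive/nonadaptive amino-acid pair
#' identities, and the per-pair polymorphism data (nonsynonymous spectra
#' per one-step pair, fourfold synonymous spectra per mutation type,
#' codon frequencies) feeding the Grantham analysis. Optionally writes
#' the plain-text input files (metadata TSV, SFS-exchange files,
#' substitutions CSV) to a directory.
#'
#' @param cfg a \code{\link{simConfig}}
#' @param dir optional output directory for the text inputs
#' @param quad quadrature controls
#' @return list with elements \code{genes} (list of
#'   \linkS4class{GeneRecord}), \code{truth} (per-stratum data.frame with
#'   the true rates), \code{substitutions} (data.frame gene/stratum/aa1/
#'   aa2/class), \code{grantham} (per-stratum pair-level data) and
#'   \code{config}
#' @export
simulateStudy <- function(cfg = simConfig(), dir = NULL,
                          quad = dfeQuadControl()) {
  sp <- enumerateStepPairs()
  D <- granthamMatrix("table")
  n <- cfg$sampleSize
  lin <- function(range) seq(range[1], range[2], length.out = cfg$nStrata)
  lenMean <- lin(cfg$lengthRange); exprMean <- lin(cfg$exprRange)
  rsaMean <- lin(cfg$rsaRange); disMean <- lin(cfg$disorderRange)
  ev10Mean <- lin(cfg$log10EvalRange)

  genes <- list(); subsRows <- list(); granth <- list(); truthRows <- list()
  counter <- 0L
  for (s in seq_len(cfg$nStrata)) {
    params <- DFEParams(cfg$shape, cfg$meanDel, pBen = cfg$pBen[s],
                        meanBen = cfg$meanBen, theta = cfg$theta)
    oNa <- omegaNaExpected(params, quad)
    oA <- omegaAExpected(params, quad)
    truthRows[[s]] <- data.frame(
      stratum = s, pBen = cfg$pBen[s], meanBen = cfg$meanBen,
      granthamExponent = cfg$granthamExponent[s],
      omegaNa = oNa, omegaA = oA, omega = oNa + oA)
    ## ---- genes ----
    for (g in seq_len(cfg$genesPerStratum)) {
      counter <- counter + 1L
      sd1 <- .fanSeed(cfg$seed, counter)
      meta <- .withSeed(sd1 + 7L, {
        len <- max(50, round(stats::rlnorm(1, log(lenMean[s]), 0.4)))
        list(len = len,
             expression = stats::rlnorm(1, log(exprMean[s]), 0.6),
             rsa = min(0.95, max(0.05, stats::rnorm(1, rsaMean[s], 0.06))),
             disorder = min(0.95, max(0.01, stats::rnorm(1, disMean[s], 0.04))),
             evalue = 10^pmin(0, stats::rnorm(1, ev10Mean[s], 20)),
             chromosome = sample(c("A", "X"), 1, prob = c(0.85, 0.15)),
             go = sample(c("GO:0006950", "GO:0009605", "GO:0007165",
                           "GO:0008152", "GO:0016020"),
                         sample(0:3, 1), replace = FALSE))
      })
      lNonsyn <- meta$len * 3 * 0.7
      lSyn <- meta$len * 3 * 0.25
      cc <- simulateGene(params, lNonsyn, lSyn, n, cfg$muT, seed = sd1,
                         label = sprintf("g%04d", counter), quad = quad)
      pnps <- (sum(cc@sfsNonsyn@counts) / lNonsyn) /
        max(sum(cc@sfsSyn@counts) / lSyn, 1e-9)
      genes[[counter]] <- GeneRecord(
        geneId = cc@label, stratum = s, counts = cc, length = meta$len,
        expression = meta$expression, rsa = meta$rsa,
        disorder = meta$disorder, evalue = meta$evalue, pnps = pnps,
        chromosome = meta$chromosome, goTerms = meta$go)
    }
    ## ---- Grantham pair-level data ----
    strGenes <- genes[(counter - cfg$genesPerStratum + 1L):counter]
    lNtot <- sum(vapply(strGenes, function(g) g@counts@lNonsyn, numeric(1)))
    lStot <- sum(vapply(strGenes, function(g) g@counts@lSyn, numeric(1)))
    key <- .pairKey(sp$pairs$aa1, sp$pairs$aa2)
    opp <- as.numeric(table(.pairKey(sp$edges$aa1, sp$edges$aa2))[key])
    lPair <- lNtot * opp / sum(opp)
    ## substitution counts and pair identities
    sdS <- .fanSeed(cfg$seed, 100000L + s)
    counts2 <- .withSeed(sdS, c(
      adaptive = stats::rpois(1, lNtot * cfg$muT * oA),
      nonadaptive = stats::rpois(1, lNtot * cfg$muT * oNa)))
    ex <- cfg$granthamExponent[s]
    subsA <- simulateSubstitutionPairs(counts2["adaptive"], ex, "adaptive",
                                       seed = sdS + 1L, stepPairs = sp,
                                       distance = D)
    subsN <- simulateSubstitutionPairs(counts2["nonadaptive"], ex,
                                       "nonadaptive", seed = sdS + 2L,
                                       stepPairs = sp, distance = D)
    subs <- rbind(subsA, subsN)
    if (nrow(subs)) {
      subs$stratum <- s
      subs$gene <- .withSeed(sdS + 3L, sample(
        vapply(strGenes, function(g) g@geneId, character(1)),
        nrow(subs), replace = TRUE))
      subsRows[[s]] <- subs
    }
    ## per-pair nonsynonymous SFS + divergence
    pairD <- table(factor(.pairKey(subs$aa1, subs$aa2), levels = key))
    lamUnit <- expectedSfs(params, n, lSyn = 1, lNonsyn = 1, quad)$lambdaNonsyn
    pairData <- list()
    for (k in seq_along(key)) {
      sdP <- .fanSeed(cfg$seed, 200000L + s * 1000L + k)
      cnt <- .withSeed(sdP, stats::rpois(n - 1L, lamUnit * lPair[k]))
      pairData[[key[k]]] <- list(
        sfs = SiteFrequencySpectrum(cnt, nSites = lPair[k],
                                    siteClass = "nonsynonymous",
                                    sampleSize = n),
        d = as.numeric(pairD[key[k]]), l = lPair[k])
    }
    ## fourfold synonymous spectra per mutation type (neutral)
    mts <- sort(unique(sp$edges$mutType))
    lMt <- lStot / length(mts)
    sfsByMuttype <- list()
    for (k in seq_along(mts)) {
      sdM <- .fanSeed(cfg$seed, 300000L + s * 100L + k)
      drawn <- .withSeed(sdM, list(
        cnt = stats::rpois(n - 1L, lMt * cfg$theta / seq_len(n - 1L)),
        d = stats::rpois(1, lMt * cfg$muT)))
      sfsByMuttype[[mts[k]]] <- list(
        sfs = SiteFrequencySpectrum(drawn$cnt, nSites = lMt,
                                    siteClass = "fourfold_by_muttype",
                                    sampleSize = n),
        d = drawn$d, l = lMt)
    }
    codons <- names(.codonTable())[.codonTable() != "*"]
    granth[[s]] <- list(pairData = pairData, sfsByMuttype = sfsByMuttype,
                        codonFreqs = stats::setNames(
                          rep(1 / length(codons), length(codons)), codons))
  }
  substitutions <- if (length(subsRows)) do.call(rbind, subsRows) else
    data.frame(aa1 = character(), aa2 = character(), class = character(),
               stratum = integer(), gene = character())
  rownames(substitutions) <- NULL
  out <- list(genes = genes, truth = do.call(rbind, truthRows),
              substitutions = substitutions, grantham = granth,
              config = cfg)
  if (!is.null(dir)) .writeStudy(out, dir)
  out
}

.writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- do.call(rbind, lapply(study$genes, function(g) data.frame(
    gene = g@geneId, stratum = g@stratum, length = g@length,
    expression = g@expression, rsa = g@rsa, disorder = g@disorder,
    evalue = g@evalue, pnps = g@pnps, chromosome = g@chromosome,
    go = paste(g@goTerms, collapse = ";"), stringsAsFactors = FALSE)))
  utils::write.table(meta, file.path(dir, "gene_metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ccs <- lapply(study$genes, function(g) g@counts)
  names(ccs) <- vapply(study$genes, function(g) g@geneId, character(1))
  writeSfsExchange(ccs, file.path(dir, "gene_counts.sfsx"))
  utils::write.csv(study$substitutions,
                   file.path(dir, "substitutions.csv"), row.names = FALSE)
  invisible(dir)
}
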
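## Orchestration: per-stratum rate estimation, Grantham effect-size
## analysis, trend statistics, and report tables.

#' Per-stratum DFE fits with bootstrap confidence intervals
#'
#' Pools the genes of each age class, fits the DFE, and (optionally)
#' bootstraps genes within the class to obtain percentile intervals and
#' replicate vectors for pairwise comparisons.
#'
#' @param genes list of \linkS4class{GeneRecord}
#' @param B bootstrap replicates (0 disables the bootstrap)
#' @param seed RNG seed for the bootstrap
#' @param model,opts passed to \code{\link{fitDfe}}
#' @return list with \code{table} (one row per stratum: point estimates,
#'   bootstrap means and 95 percent CIs) and \code{boot} (per-stratum
#'   \linkS4class{BootstrapResult} or NULL)
#' @export
fitStratumRates <- function(genes, B = 100L, seed = 1L,
                            model = c("auto", "GammaExpo", "GammaZero"),
                            opts = dfeFitControl()) {
  model <- match.arg(model)
  strata <- sort(unique(vapply(genes, function(g) g@stratum, integer(1))))
  rows <- list(); boots <- list()
  for (s in strata) {
    gs <- genes[vapply(genes, function(g) g@stratum == s, logical(1))]
    pooled <- poolCounts(lapply(gs, function(g) g@counts),
                         label = sprintf("stratum%d", s))
    fit <- fitDfe(pooled, model = model, opts = opts)
    row <- data.frame(stratum = s, nGenes = length(gs),
                      omega = fit@omega, omegaNa = fit@omegaNa,
                      omegaA = fit@omegaA, alpha = fit@alpha,
                      loglik = fit@loglik, converged = fit@converged)
    bt <- NULL
    if (B > 0L) {
      bt <- bootstrapFit(gs, B = B, seed = .fanSeed(seed, s), model = model,
                         opts = opts, pointFit = fit)
      row$omegaAMean <- bt@mean["omegaA"]
      row$omegaALow <- bt@ciLow["omegaA"]; row$omegaAHigh <- bt@ciHigh["omegaA"]
      row$omegaNaMean <- bt@mean["omegaNa"]
      row$omegaNaLow <- bt@ciLow["omegaNa"]; row$omegaNaHigh <- bt@ciHigh["omegaNa"]
    }
    rows[[length(rows) + 1L]] <- row
    boots[[as.character(s)]] <- bt
  }
  list(table = do.call(rbind, rows), boot = boots)
}

#' Grantham effect-size analysis per stratum
#'
#' For each age class: pools the per-pair nonsynonymous data into
#' Grantham-distance bins with codon-frequency-weighted fourfold
#' synonymous references, fits the DFE per bin, and combines the per-bin
#' adaptive and nonadaptive rates into the site-weighted mean distances
#' gbarA and gbarNa.
#'
#' @param granthamData per-stratum list as produced by
#'   \code{\link{simulateStudy}} (elements pairData, sfsByMuttype,
#'   codonFreqs)
#' @param partition a \linkS4class{GranthamPartition}
#' @param opts fit controls; bins are many and small, so fewer starts
#'   than for stratum-level fits are the default
#' @param model DFE model for the per-bin fits
#' @return list with \code{table} (stratum, gbarA, gbarNa, nBinsUsed)
#'   and \code{bins} (per-stratum per-bin detail)
#' @export
granthamAnalysis <- function(granthamData, partition = granthamPartition(),
                             opts = dfeFitControl(
                               nStarts = 2L,
                               quad = dfeQuadControl(nDel = 60L, nBen = 24L)),
                             model = "auto") {
  sp <- enumerateStepPairs()
  rows <- list(); detail <- list()
  for (s in seq_along(granthamData)) {
    gd <- granthamData[[s]]
    bins <- perBinCounts(gd$pairData, partition, gd$sfsByMuttype,
                         gd$codonFreqs, stepPairs = sp)
    oA <- rep(NA_real_, nrow(bins)); oNa <- rep(NA_real_, nrow(bins))
    for (b in seq_len(nrow(bins))) {
      cc <- bins$counts[[b]]
      if (is.null(cc)) next
      vals <- tryCatch({
        fit <- fitDfe(cc, model = model, opts = opts)
        omegaValues(fit)
      }, error = function(e) NULL)
      if (is.null(vals)) next
      oA[b] <- vals["omegaA"]; oNa[b] <- vals["omegaNa"]
    }
    gb <- tryCatch(gbarStat(oA, oNa, bins$gbar, bins$nSites),
                   error = function(e) NULL)
    rows[[s]] <- data.frame(
      stratum = s,
      gbarA = if (is.null(gb)) NA_real_ else gb@gbarA,
      gbarNa = if (is.null(gb)) NA_real_ else gb@gbarNa,
      nBinsUsed = sum(is.finite(oA) & bins$nSites > 0))
    bins$omegaA <- oA; bins$omegaNa <- oNa
    detail[[s]] <- bins
  }
  list(table = do.call(rbind, rows), bins = detail)
}

#' Kendall trend of a per-stratum statistic against age rank
#'
#' @param table data.frame with a \code{stratum} column (1 = oldest)
#' @param stat name of the statistic column
#' @return list with tau and p, see \code{\link{kendallTau}}
#' @export
ageTrend <- function(table, stat) {
  ok <- is.finite(table[[stat]])
  kendallTau(table$stratum[ok], table[[stat]][ok])
}

#' Run the full synthetic-study pipeline
#'
#' Stages: simulate -> per-stratum fits (+ bootstrap) -> Grantham
#' effect-size analysis -> trend statistics -> report tables. When
#' \code{outdir} is given, writes the input files, all report tables
#' (CSV) and a plain-text run manifest sufficient to reproduce the run.
#'
#' @param cfg a \code{\link{simConfig}}
#' @param B bootstrap replicates per stratum (0 disables)
#' @param outdir optional output directory
#' @param fitOpts,binFitOpts fit controls for stratum-level and per-bin
#'   fits
#' @return list with \code{rates} (per-stratum rate table),
#'   \code{trends} (tau/p per statistic), \code{gbar} (per-stratum
#'   gbarA/gbarNa), \code{granthamMedians} (per-stratum substitution
#'   distance quartiles), \code{truth} and \code{study}
#' @export
runPipeline <- function(cfg = simConfig(), B = 0L, outdir = NULL,
                        fitOpts = dfeFitControl(
                          nStarts = 3L,
                          quad = dfeQuadControl(nDel = 60L, nBen = 24L,
                                                nodesPerPanel = 10L)),
                        binFitOpts = dfeFitControl(
                          nStarts = 1L,
                          quad = dfeQuadControl(nDel = 48L, nBen = 20L,
                                                nodesPerPanel = 8L))) {
  t0 <- Sys.time()
  study <- simulateStudy(cfg, dir = if (is.null(outdir)) NULL
                                    else file.path(outdir, "inputs"))
  rates <- fitStratumRates(study$genes, B = B, seed = cfg$seed,
                           opts = fitOpts)
  part <- granthamPartition()
  gb <- granthamAnalysis(study$grantham, part, opts = binFitOpts)
  med <- meanGranthamPerStratum(study$substitutions)
  trends <- data.frame(
    statistic = c("omegaA", "omegaNa", "gbarA", "gbarNa", "granthamMedian"),
    tau = NA_real_, p = NA_real_)
  tr <- list(ageTrend(rates$table, "omegaA"),
             ageTrend(rates$table, "omegaNa"),
             ageTrend(gb$table, "gbarA"),
             ageTrend(gb$table, "gbarNa"),
             ageTrend(med, "median"))
  trends$tau <- vapply(tr, function(x) x$tau, numeric(1))
  trends$p <- vapply(tr, function(x) x$p, numeric(1))
  out <- list(rates = rates$table, boot = rates$boot, trends = trends,
              gbar = gb$table, granthamMedians = med, truth = study$truth,
              study = study)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rates$table, file.path(outdir, "stratum_rates.csv"),
                     row.names = FALSE)
    utils::write.csv(trends, file.path(outdir, "age_trends.csv"),
                     row.names = FALSE)
    utils::write.csv(gb$table, file.path(outdir, "gbar_per_stratum.csv"),
                     row.names = FALSE)
    utils::write.csv(med, file.path(outdir, "grantham_medians.csv"),
                     row.names = FALSE)
    utils::write.csv(study$truth, file.path(outdir, "truth.csv"),
                     row.names = FALSE)
    manifest <- c(
      sprintf("adaptwalk_version: %s",
              as.character(utils::packageVersion("adaptwalk"))),
      sprintf("seed: %d", cfg$seed),
      sprintf("nStrata: %d", cfg$nStrata),
      sprintf("genesPerStratum: %d", cfg$genesPerStratum),
      sprintf("sampleSize: %d", cfg$sampleSize),
      sprintf("bootstrapB: %d", B),
      sprintf("gradient: %s", cfg$gradient),
      sprintf("elapsedSec: %.1f", as.numeric(Sys.time() - t0, units = "secs")))
    writeLines(manifest, file.path(outdir, "manifest.txt"))
  }
  out
}
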
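test_that("Grantham matrix agrees between table and formula", {
  Dt <- granthamMatrix("table")
  Df <- granthamMatrix("formula")
  expect_equal(dim(Dt), c(20, 20))
  expect_equal(Dt, t(Dt))
  expect_true(all(diag(Dt) == 0))
  # canonical values
  expect_equal(Dt["L", "I"], 5)
  expect_equal(max(Dt), 215)
  expect_setequal(unname(which(Dt == 215, arr.ind = TRUE)[1, ]),
                  match(c("C", "W"), rownames(Dt)))
  # the table is the integer rounding of the formula
  expect_true(max(abs(Dt - Df)) <= 0.5 + 1e-9)
  expect_equal(Df["L", "I"], 5, tolerance = 0.1)
})

test_that("one-step pairs match an all-codon-pairs brute force", {
  sp <- enumerateStepPairs()
  # independent oracle: test all 61 x 61 sense codon pairs for Hamming
  # distance 1 directly from the code table
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  got <- character()
  for (c1 in codons) for (c2 in codons) {
    if (c1 >= c2) next
    diff <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(diff) != 1L) next
    if (gc[c1] == gc[c2]) next
    got <- c(got, paste(sort(c(gc[[c1]], gc[[c2]])), collapse = "|"))
  }
  oracle <- sort(unique(got))
  mine <- sort(paste(sp$pairs$aa1, sp$pairs$aa2, sep = "|"))
  expect_identical(mine, oracle)

  # named examples
  sc <- sp$pairs[sp$pairs$aa1 == "C" & sp$pairs$aa2 == "S", ]
  expect_equal(strsplit(sc$mutTypes, ",")[[1]], c("A<>T", "C<>G"))
  expect_true(any(sp$pairs$aa1 == "I" & sp$pairs$aa2 == "M"))
  expect_true(any(sp$pairs$aa1 == "R" & sp$pairs$aa2 == "W"))
})

test_that("codon-frequency weighting of fourfold spectra follows the rule", {
  sp <- enumerateStepPairs()
  n <- 6
  mkSfs <- function(x, L) SiteFrequencySpectrum(x, L, "fourfold_by_muttype",
                                                sampleSize = n)
  sfsAT <- mkSfs(c(10, 6, 4, 2, 1), 100)
  sfsCG <- mkSfs(c(20, 8, 2, 2, 0), 80)
  byType <- list("A<>T" = sfsAT, "C<>G" = sfsCG)

  # arbitrary codon frequencies; hand evaluation of the stated weights
  codons <- names(Biostrings::GENETIC_CODE)
  f <- setNames(seq_along(codons) / sum(seq_along(codons)), codons)
  wAT <- f["AGT"] + f["TGT"] + f["AGC"] + f["TGC"]
  wCG <- f["TCT"] + f["TGT"] + f["TCC"] + f["TGC"]
  want <- (wAT * sfsCounts(sfsAT) + wCG * sfsCounts(sfsCG)) / (wAT + wCG)
  out <- weightedFourfoldSfs(c("S", "C"), byType, f, sp)
  expect_equal(sfsCounts(out), unname(want))
  expect_equal(nSites(out), unname((wAT * 100 + wCG * 80) / (wAT + wCG)))

  # equal codon frequencies: plain mean of the two spectra
  fEq <- setNames(rep(1 / 64, 64), codons)
  outEq <- weightedFourfoldSfs(c("S", "C"), byType, fEq, sp)
  expect_equal(sfsCounts(outEq), (sfsCounts(sfsAT) + sfsCounts(sfsCG)) / 2)

  # single mutation type: returned unchanged (weight 1)
  ad <- weightedFourfoldSfs(c("A", "D"), list("A<>C" = sfsAT), f, sp)
  expect_equal(sfsCounts(ad), sfsCounts(sfsAT))

  # convex combination: every class within the input range
  rng <- rbind(pmin(sfsCounts(sfsAT), sfsCounts(sfsCG)),
               pmax(sfsCounts(sfsAT), sfsCounts(sfsCG)))
  expect_true(all(sfsCounts(out) >= rng[1, ] & sfsCounts(out) <= rng[2, ]))

  expect_error(weightedFourfoldSfs(c("S", "C"), byType,
                                   setNames(rep(0, 64), codons), sp),
               "zero total")
  expect_error(weightedFourfoldSfs(c("S", "C"), list("A<>T" = sfsAT), f, sp),
               "C<>G")
})

test_that("equal-count partition covers all pairs with ordered bins", {
  part <- granthamPartition(10)
  expect_equal(sort(unique(part@bins)), 1:10)
  counts <- table(part@bins)
  expect_true(max(counts) - min(counts) <= 1)
  expect_true(all(diff(part@gbar) > 0))
  # bin assignment respects distance ordering
  for (b in 1:9)
    expect_true(max(part@pairs$distance[part@bins == b]) <=
                  min(part@pairs$distance[part@bins == b + 1]))
})

test_that("per-bin pooling conserves counts and sites", {
  sp <- enumerateStepPairs()
  part <- granthamPartition(10)
  n <- 6
  # synthetic per-pair data for three pairs in different bins
  key <- paste(part@pairs$aa1, part@pairs$aa2, sep = "|")
  pick <- key[c(which(part@bins == 1)[1], which(part@bins == 1)[2],
                which(part@bins == 7)[1])]
  mk <- function(seed) {
    set.seed(seed)
    list(sfs = SiteFrequencySpectrum(rpois(n - 1, 5), 200, "nonsynonymous",
                                     sampleSize = n),
         d = rpois(1, 10), l = 200)
  }
  pairData <- setNames(lapply(1:3, mk), pick)
  mts <- sort(unique(sp$edges$mutType))
  byType <- setNames(lapply(seq_along(mts), function(i) {
    set.seed(100 + i)
    list(sfs = SiteFrequencySpectrum(rpois(n - 1, 8), 150,
                                     "fourfold_by_muttype", sampleSize = n),
         d = rpois(1, 12), l = 150)
  }), mts)
  codons <- names(Biostrings::GENETIC_CODE)
  f <- setNames(rep(1 / 64, 64), codons)

  bins <- perBinCounts(pairData, part, byType, f, sp)
  expect_equal(nrow(bins), 10)
  # nonsynonymous divergence is conserved across bins
  dTot <- sum(sapply(bins$counts[!sapply(bins$counts, is.null)],
                     function(cc) divergence(cc)[["nonsyn"]]))
  expect_equal(dTot, sum(sapply(pairData, function(p) p$d)))
  # N_i additive over the pairs of the bin
  expect_equal(bins$nSites[1], 400)
  expect_equal(bins$nSites[7], 200)
  expect_equal(sum(bins$nSites), 600)
  # single-pair bin equals that pair's counts
  cc7 <- bins$counts[[7]]
  expect_equal(sfsCounts(cc7@sfsNonsyn), sfsCounts(pairData[[3]]$sfs))
  expect_equal(divergence(cc7)[["nonsyn"]], pairData[[3]]$d)
})

test_that("gbar statistics reproduce the weighted-sum definition", {
  # two-bin hand example
  g <- gbarStat(omegaA = c(0.1, 0.3), omegaNa = c(0.05, 0.02),
                gbarBin = c(10, 100), nSites = c(1000, 500))
  expect_equal(g@gbarA, (0.1 * 10 * 1000 + 0.3 * 100 * 500) / 1500)
  expect_equal(g@gbarA, 10.667, tolerance = 1e-3)
  # single bin collapses to omegaA * gbar
  g1 <- gbarStat(0.2, 0.1, 50, 800)
  expect_equal(g1@gbarA, 0.2 * 50)
  # constant rates factor out
  gc <- gbarStat(rep(0.07, 3), rep(0.01, 3), c(10, 50, 90), c(5, 10, 20))
  expect_equal(gc@gbarA, 0.07 * sum(c(10, 50, 90) * c(5, 10, 20)) / 35)
  # invariant to splitting a bin with identical rate and distance
  gSplit <- gbarStat(c(0.1, 0.3, 0.3), c(0.05, 0.02, 0.02),
                     c(10, 100, 100), c(1000, 250, 250))
  expect_equal(gSplit@gbarA, g@gbarA)
  # negative adaptive rates propagate
  gNeg <- gbarStat(c(-0.1, 0.2), c(0.1, 0.1), c(10, 20), c(100, 100))
  expect_equal(gNeg@gbarA, (-0.1 * 10 + 0.2 * 20) * 100 / 200)
  expect_error(gbarStat(0.1, 0.1, 10, 0), "no nonsynonymous sites")
})

test_that("per-stratum distance medians summarise fixed differences", {
  subs <- data.frame(stratum = c(1, 2, 2, 2),
                     aa1 = c("L", "L", "L", "K"),
                     aa2 = c("I", "I", "I", "L"))
  # K|L needs two mutational steps and is ignored
  out <- meanGranthamPerStratum(subs)
  expect_equal(out$median[out$stratum == 1], 5)
  expect_equal(out$median[out$stratum == 2], 5)
  expect_equal(out$n[out$stratum == 2], 2)
  expect_true(all(out$q1 <= out$median & out$median <= out$q3))
  # duplicated substitutions do not move the median
  dup <- rbind(subs, subs[1, ])
  expect_equal(meanGranthamPerStratum(dup)$median,
               out$median)
})
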
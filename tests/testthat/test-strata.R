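test_that("stratum schemes merge contiguous clades in age order", {
  # 12 strata merged to 6 classes (3-4, 5-6, 7-10, 11-12 combined)
  sch <- stratumScheme(c(1, 2, 3, 3, 4, 4, 5, 5, 5, 5, 6, 6))
  expect_equal(max(sch$mapping), 6)

  par <- DFEParams(0.3, -500, theta = 0.02)
  genes <- makeGenes(2, 1:12, replicate(12, par, simplify = FALSE))
  merged <- mergeStrata(genes, sch)
  expect_equal(sort(unique(sapply(merged, function(g) g@stratum))), 1:6)
  # age order preserved: merged class is nondecreasing in original stratum
  orig <- sapply(genes, function(g) g@stratum)
  expect_true(all(diff(sch$mapping[sort(unique(orig))]) >= 0))

  # identity scheme leaves genes untouched
  ident <- stratumScheme(1:12)
  expect_equal(sapply(mergeStrata(genes, ident), function(g) g@stratum), orig)

  # non-contiguous merges violate monotonicity
  expect_error(stratumScheme(c(1, 2, 1)), "monotone|contiguous")
  expect_error(stratumScheme(c(1, 2, 2, 1)), "monotone|contiguous")
  # uncovered stratum
  expect_error(mergeStrata(genes, stratumScheme(1:5)), "cover")
})

test_that("median split sends ties to the low group", {
  par <- DFEParams(0.3, -500, theta = 0.02)
  genes <- makeGenes(4, 1, list(par))
  vals <- list(c(1, 2, 3, 4), c(1, 2, 2, 3))
  lows <- list(c(1, 2), c(1, 2, 2))
  for (k in 1:2) {
    for (i in 1:4) genes[[i]]@length <- vals[[k]][i]
    sp <- splitHighLow(genes, "length")
    expect_equal(sort(sapply(sp$low, function(g) g@length)), lows[[k]])
    expect_equal(sp$threshold, median(vals[[k]]))
    expect_true(all(sapply(sp$high, function(g) g@length) > sp$threshold))
  }
  for (i in 1:4) genes[[i]]@length <- 7
  expect_error(splitHighLow(genes, "length"), "identical")
})

test_that("E-value filter retains by strict inequality", {
  par <- DFEParams(0.3, -500, theta = 0.02)
  genes <- makeGenes(3, 1, list(par))
  genes[[1]]@evalue <- 1e-200
  genes[[2]]@evalue <- 1e-100
  genes[[3]]@evalue <- NA_real_
  kept <- suppressMessages(filterByEvalue(genes, 1e-150))
  expect_equal(sapply(kept, function(g) g@geneId), genes[[1]]@geneId)
  # infinite cutoff keeps everything with a defined E-value
  expect_length(suppressMessages(filterByEvalue(genes, Inf)), 2)
})

test_that("pn/ps mode filter matches a brute-force window", {
  par <- DFEParams(0.3, -500, theta = 0.02)
  genes <- makeGenes(60, 1, list(par))
  set.seed(11)
  pn <- rnorm(60, mean = 0.2, sd = 0.05)
  for (i in 1:60) genes[[i]]@pnps <- pn[i]
  kSd <- 0.5
  kept <- suppressMessages(filterByPnpsMode(genes, kSd))
  # brute force: same estimator, direct window count
  mode <- halfSampleMode(pn)
  expect_equal(length(kept), sum(abs(pn - mode) <= kSd * sd(pn)))
  # infinite window is the identity on defined values
  expect_length(suppressMessages(filterByPnpsMode(genes, Inf)), 60)
  # all-equal pn/ps: everything is at the mode
  for (i in 1:60) genes[[i]]@pnps <- 0.1
  expect_length(suppressMessages(filterByPnpsMode(genes, 0)), 60)
})

test_that("GO grouping keeps young-rich terms with strict threshold", {
  par <- DFEParams(0.3, -500, theta = 0.02)
  genes <- makeGenes(6, c(1, 5), replicate(5, par, simplify = FALSE))
  # 6 old (stratum 1), 6 young (stratum 5)
  for (i in 1:12) genes[[i]]@goTerms <- character()
  for (i in 7:9) genes[[i]]@goTerms <- "GO:A"          # 3 young
  for (i in 10:12) genes[[i]]@goTerms <- c("GO:A", "GO:B")  # 3 more young
  gb <- groupByGO(genes, minYoung = 5, youngStrata = 5)
  expect_identical(names(gb), "GO:A")   # 6 > 5 qualifies, GO:B has 3
  expect_length(gb[["GO:A"]], 6)
  # threshold is strict: exactly minYoung young genes is excluded
  expect_length(groupByGO(genes, minYoung = 6, youngStrata = 5), 0)
  # a gene with two qualifying terms appears under both
  gb2 <- groupByGO(genes, minYoung = 2, youngStrata = 5)
  inBoth <- intersect(sapply(gb2[["GO:A"]], function(g) g@geneId),
                      sapply(gb2[["GO:B"]], function(g) g@geneId))
  expect_length(inBoth, 3)
  expect_length(groupByGO(genes, 1, integer()), 0)
})

test_that("cells pool additively and ignore gene order", {
  par <- DFEParams(0.3, -500, theta = 0.02)
  genes <- makeGenes(4, 1:2, list(par, par))
  groups <- setNames(rep(c("low", "high"), 4),
                     sapply(genes, function(g) g@geneId))
  cells <- suppressMessages(buildCells(genes, groups = groups))
  expect_equal(nrow(cells), 4)
  # pooled divergence equals the sum over member genes
  for (r in seq_len(nrow(cells))) {
    sel <- sapply(genes, function(g)
      g@stratum == cells$ageClass[r] & groups[g@geneId] == cells$group[r])
    want <- sum(sapply(genes[sel], function(g) divergence(g@counts)[["nonsyn"]]))
    expect_equal(divergence(cells$counts[[r]])[["nonsyn"]], want)
  }
  cells2 <- suppressMessages(buildCells(rev(genes), groups = groups))
  expect_equal(cells$nGenes, cells2$nGenes)
  expect_equal(sfsCounts(cells$counts[[1]]@sfsSyn),
               sfsCounts(cells2$counts[[1]]@sfsSyn))
  # single gene: one nonempty cell carrying that gene's counts
  one <- suppressMessages(buildCells(genes[1]))
  expect_equal(nrow(one), 1)
  expect_equal(divergence(one$counts[[1]]), divergence(genes[[1]]@counts))
})
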
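test_that("degeneracy classes match genetic-code enumeration", {
  expect_identical(classifyDegeneracy("GGA", 3), "four")
  expect_identical(classifyDegeneracy("TGG", 2), "zero")
  expect_identical(classifyDegeneracy("ATG", 1), "zero")

  # independent oracle: enumerate all sense codons x positions directly
  # from the code table and compare the counts of synonymous alternatives
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  for (cd in sample(codons, 15)) {
    for (p in 1:3) {
      nts <- strsplit(cd, "")[[1]]
      aas <- sapply(setdiff(c("A", "C", "G", "T"), nts[p]), function(nt) {
        nts2 <- nts; nts2[p] <- nt
        gc[paste(nts2, collapse = "")]
      })
      nsyn <- sum(aas == gc[cd] & aas != "*")
      want <- c("zero", "two", "other", "four")[
        match(nsyn, c(0, 1, 2, 3))]
      expect_identical(classifyDegeneracy(cd, p), want,
                       label = paste(cd, p))
    }
  }

  # ambiguous nucleotide: missing, not an error
  expect_true(is.na(classifyDegeneracy("GNA", 1)))
  expect_true(is.na(classifyDegeneracy("TAA", 1)))  # stop codon context
})

test_that("site table classifies polymorphism, divergence and skips", {
  toy <- makeToyAlignment()
  st <- buildSiteTable(toy$ingroup, toy$outgroup)

  # fourfold polymorphic site: derived count 3 of 10, synonymous
  s1 <- st[st$site == 2, ]
  expect_identical(s1$type, "poly")
  expect_identical(s1$class, "synonymous")
  expect_identical(s1$d, 3L)
  expect_identical(s1$m, 10L)

  # fixed difference M/I at codon 2 is nonsynonymous divergence
  s2 <- st[st$site == 5, ]
  expect_identical(s2$type, "div")
  expect_identical(s2$class, "nonsynonymous")

  # outgroup matching neither ingroup allele: discarded
  s3 <- st[st$site == 6, ]
  expect_identical(s3$type, "skipped")

  # degeneracy-apportioned site totals
  expect_equal(attr(st, "lSyn"), 11 / 3)
  expect_equal(attr(st, "lNonsyn"), 34 / 3)

  # frame error
  expect_error(buildSiteTable(substr(toy$ingroup, 1, 14),
                              substr(toy$outgroup, 1, 14)),
               "multiple of 3")
})

test_that("unfolded SFS and divergence counts assemble per gene", {
  toy <- makeToyAlignment()
  cc <- buildUnfoldedSfs(toy$ingroup, toy$outgroup, label = "toy")
  expect_equal(unname(divergence(cc)), c(1, 1))
  expect_equal(sfsCounts(cc@sfsSyn), c(0, 0, 1, rep(0, 6)))
  expect_equal(sum(sfsCounts(cc@sfsNonsyn)), 0)
  expect_equal(unname(siteTotals(cc)), c(11 / 3, 34 / 3))

  # permuting haplotypes leaves the SFS unchanged
  cc2 <- buildUnfoldedSfs(rev(toy$ingroup), toy$outgroup)
  expect_equal(sfsCounts(cc2@sfsSyn), sfsCounts(cc@sfsSyn))
  expect_equal(sfsCounts(cc2@sfsNonsyn), sfsCounts(cc@sfsNonsyn))
})

test_that("expected-mode down-sampling equals subset enumeration", {
  # one site, 2 derived of 4, projected to n = 2: enumerate all C(4,2)
  # subsets directly
  combos <- combn(4, 2)
  derivedIn <- function(cols) sum(cols <= 2)  # haplotypes 1,2 carry derived
  tab <- table(apply(combos, 2, derivedIn)) / ncol(combos)
  sites <- data.frame(d = 2, m = 4)
  sfs <- downsampleSfs(sites, 2, mode = "expected")
  expect_equal(sfsCounts(sfs), unname(tab["1"]))           # 2/3
  expect_equal(attr(sfs, "nDroppedMono"),
               unname(tab["0"] + tab["2"]))                # 1/6 + 1/6
  # mass conservation: retained + dropped = 1 per site
  expect_equal(sum(sfsCounts(sfs)) + attr(sfs, "nDroppedMono"), 1)

  # identity projection
  sfsId <- downsampleSfs(data.frame(d = 2, m = 4), 4, mode = "expected")
  expect_equal(sfsCounts(sfsId), c(0, 1, 0))
})

test_that("random-mode down-sampling is seed-reproducible and unbiased", {
  sites <- data.frame(d = c(2, 5, 1, 7), m = c(8, 10, 9, 12))
  a <- downsampleSfs(sites, 6, mode = "random", seed = 42)
  b <- downsampleSfs(sites, 6, mode = "random", seed = 42)
  expect_identical(sfsCounts(a), sfsCounts(b))

  # Monte-Carlo: mean of random draws approaches the expected-mode SFS
  exp_sfs <- sfsCounts(downsampleSfs(sites, 6, mode = "expected"))
  draws <- sapply(1:600, function(s)
    sfsCounts(downsampleSfs(sites, 6, mode = "random", seed = s)))
  mc <- rowMeans(draws)
  se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(mc - exp_sfs) <= 3 * pmax(se, 1e-3)))

  # coverage rule: sites with fewer than nTarget genotypes are discarded
  low <- downsampleSfs(data.frame(d = c(2, 3), m = c(4, 20)), 10)
  expect_equal(attr(low, "nDroppedCoverage"), 1L)

  expect_error(downsampleSfs(sites, 1), "at least 2")
})

test_that("SFS-exchange round-trips and rejects malformed input", {
  n <- 4
  cc <- CategoryCounts(
    SiteFrequencySpectrum(c(5, 2, 1), 120.5, "synonymous"),
    SiteFrequencySpectrum(c(9, 3, 0), 410.25, "nonsynonymous"),
    dSyn = 7, dNonsyn = 13, label = "catA")
  path <- tempfile(fileext = ".sfsx")
  writeSfsExchange(cc, path)
  back <- readSfsExchange(path)[["catA"]]
  expect_equal(sfsCounts(back@sfsSyn), sfsCounts(cc@sfsSyn))
  expect_equal(sfsCounts(back@sfsNonsyn), sfsCounts(cc@sfsNonsyn))
  expect_equal(divergence(back), divergence(cc))
  expect_equal(siteTotals(back), siteTotals(cc))

  # layout: n = 4 serialises 3 + 3 classes + 2 divergence fields
  line <- grep("^[^#]", readLines(path), value = TRUE)
  expect_length(strsplit(line, "\t")[[1]], 2 + 1 + 3 + 1 + 3 + 2)

  # negative count and short lines are parse errors naming the line
  writeLines(c("bad\t4\t10\t-1\t0\t0\t5\t1\t1\t1\t2\t1"), path)
  expect_error(readSfsExchange(path), "line 1")
  writeLines("only\t4\t10", path)
  expect_error(readSfsExchange(path), "line 1")
})

test_that("pooling categories is additive and order-invariant", {
  set.seed(7)
  ccs <- lapply(1:5, function(i) CategoryCounts(
    SiteFrequencySpectrum(rpois(5, 4), 100, "synonymous"),
    SiteFrequencySpectrum(rpois(5, 8), 300, "nonsynonymous"),
    dSyn = rpois(1, 10), dNonsyn = rpois(1, 5), label = paste0("g", i)))
  pooled <- poolCounts(ccs)
  expect_equal(divergence(pooled)[["nonsyn"]],
               sum(sapply(ccs, function(x) divergence(x)[["nonsyn"]])))
  shuffled <- poolCounts(ccs[c(3, 1, 5, 2, 4)])
  expect_equal(sfsCounts(pooled@sfsSyn), sfsCounts(shuffled@sfsSyn))
  expect_equal(divergence(pooled), divergence(shuffled))
  expect_error(poolCounts(list(ccs[[1]], CategoryCounts(
    SiteFrequencySpectrum(c(1, 1), 10, "synonymous"),
    SiteFrequencySpectrum(c(1, 1), 10, "nonsynonymous"), 1, 1))),
    "sample size")
})

test_that("fourfold spectra split by mutation type", {
  toy <- makeToyAlignment()
  st <- buildSiteTable(toy$ingroup, toy$outgroup)
  ff <- fourfoldSfsByMuttype(st, nTarget = 10)
  # the GGA codon's A/T polymorphism at a fourfold site is an A<>T type
  expect_true("A<>T" %in% names(ff))
  expect_equal(sum(sfsCounts(ff[["A<>T"]]$sfs)), 1)
  # the GCC/GCT fixed difference is a C<>T fourfold divergence
  expect_true("C<>T" %in% names(ff))
  expect_equal(ff[["C<>T"]]$d, 1)
})
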
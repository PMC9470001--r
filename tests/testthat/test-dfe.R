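test_that("relative fixation rate matches the closed form", {
  expect_equal(fixationRateRelative(0), 1)
  expect_equal(fixationRateRelative(2), 2 / (1 - exp(-2)), tolerance = 1e-4)
  expect_equal(fixationRateRelative(-2), -2 / (1 - exp(2)), tolerance = 1e-4)
  expect_equal(fixationRateRelative(2), 2.3130, tolerance = 2e-4)
  expect_equal(fixationRateRelative(-2), 0.3130, tolerance = 2e-4)
  # strictly increasing and positive over a wide range
  s <- seq(-50, 50, by = 0.5)
  r <- fixationRateRelative(s)
  expect_true(all(r > 0))
  expect_true(all(diff(r) > 0))
  # stable in the far tails
  expect_equal(fixationRateRelative(-1e5), 0)
  expect_equal(fixationRateRelative(1e5), 1e5)
})

test_that("expected SFS reduces to theta L / i in the neutral limit", {
  n <- 12
  par <- DFEParams(shape = 1, meanDel = -1e-7, pBen = 0, meanBen = 10,
                   theta = 0.02)
  lam <- expectedSfs(par, n, lSyn = 1000, lNonsyn = 1000)
  ii <- seq_len(n - 1)
  expect_equal(lam$lambdaSyn, 1000 * 0.02 / ii)
  expect_true(max(abs(lam$lambdaNonsyn / (1000 * 0.02 / ii) - 1)) < 1e-3)
})

test_that("strong purifying selection suppresses the nonsynonymous SFS", {
  n <- 10
  par <- DFEParams(shape = 1, meanDel = -1e4, pBen = 0, meanBen = 10,
                   theta = 0.02)
  lam <- expectedSfs(par, n, lSyn = 1000, lNonsyn = 1000)
  expect_true(all(lam$lambdaNonsyn > 0))
  expect_true(all(is.finite(lam$lambdaNonsyn)))
  expect_true(all(lam$lambdaNonsyn < 0.05 * lam$lambdaSyn))
  # and the deficit grows with derived-allele frequency
  ratio <- lam$lambdaNonsyn / lam$lambdaSyn
  expect_true(all(diff(ratio) < 0))
})

test_that("Poisson likelihood behaves as a PRF likelihood should", {
  n <- 8
  par <- DFEParams(0.4, -300, pBen = 0, meanBen = 10, theta = 0.02)
  lam <- expectedSfs(par, n, 500, 1500)
  mk <- function(sfsS, sfsN) CategoryCounts(
    SiteFrequencySpectrum(sfsS, 500, "synonymous"),
    SiteFrequencySpectrum(sfsN, 1500, "nonsynonymous"),
    dSyn = 1, dNonsyn = 1)

  # counts equal to the expectation: maximal over theta rescalings
  cc <- mk(lam$lambdaSyn, lam$lambdaNonsyn)
  ll0 <- loglikPoisson(cc, par)
  for (f in c(0.7, 0.9, 1.1, 1.5)) {
    parF <- DFEParams(0.4, -300, pBen = 0, meanBen = 10, theta = 0.02 * f)
    expect_lt(loglikPoisson(cc, parF), ll0)
  }

  # all-zero counts: loglik is -sum(lambda)
  zero <- mk(rep(0, n - 1), rep(0, n - 1))
  expect_equal(loglikPoisson(zero, par),
               -sum(lam$lambdaSyn) - sum(lam$lambdaNonsyn))
})

test_that("omega_na decreases as deleterious effects strengthen", {
  vals <- sapply(c(-10, -100, -1000, -10000), function(sd)
    omegaNaExpected(DFEParams(0.3, sd, pBen = 0, meanBen = 10, theta = 0.01)))
  expect_true(all(diff(vals) < 0))
  # and is bounded by neutrality
  expect_true(all(vals < 1 & vals > 0))
})

test_that("DFE fit recovers rates and keeps the identity omega = omega_a + omega_na", {
  par <- DFEParams(0.3, -800, pBen = 0.02, meanBen = 10, theta = 0.02)
  ccs <- lapply(1:60, function(i)
    simulateGene(par, 2500, 900, 12, 0.1, seed = 7000 + i))
  pooled <- poolCounts(ccs)
  fit <- fitDfe(pooled, model = "auto",
                opts = dfeFitControl(nStarts = 4))
  v <- omegaValues(fit)
  expect_equal(v[["omegaA"]], v[["omega"]] - v[["omegaNa"]])
  expect_equal(v[["alpha"]], v[["omegaA"]] / v[["omega"]])
  # likelihood at the optimum beats the perturbed truth
  parPerturb <- DFEParams(0.6, -80, pBen = 0.02, meanBen = 10,
                          theta = dfeParams(fit)@theta)
  expect_gt(fit@loglik, loglikPoisson(pooled, parPerturb))
  # recovery within a loose band at this scale
  trueNa <- omegaNaExpected(par)
  expect_lt(abs(v[["omegaNa"]] - trueNa), 0.35 * trueNa)
})

test_that("degenerate divergence counts are handled as defined", {
  par <- DFEParams(0.3, -500, pBen = 0, meanBen = 10, theta = 0.02)
  cc <- simulateGene(par, 2000, 700, 10, 0.1, seed = 3)
  ccNoDn <- CategoryCounts(cc@sfsSyn, cc@sfsNonsyn, dSyn = cc@dSyn,
                           dNonsyn = 0, label = "noDn")
  fit <- fitDfe(ccNoDn, model = "GammaZero",
                opts = dfeFitControl(nStarts = 2))
  expect_equal(fit@omega, 0)
  expect_equal(fit@omegaA, -fit@omegaNa)
  expect_true(is.na(fit@alpha))

  ccNoDs <- CategoryCounts(cc@sfsSyn, cc@sfsNonsyn, dSyn = 0,
                           dNonsyn = cc@dNonsyn, label = "noDs")
  expect_error(fitDfe(ccNoDs, model = "GammaZero",
                      opts = dfeFitControl(nStarts = 1)),
               "omega undefined")
})

test_that("gene bootstrap is deterministic and degenerates correctly", {
  par <- DFEParams(0.3, -500, pBen = 0, meanBen = 10, theta = 0.02)
  genes <- lapply(1:12, function(i)
    simulateGene(par, 1500, 500, 10, 0.1, seed = 100 + i))
  opts <- dfeFitControl(nStarts = 2,
                        quad = dfeQuadControl(nDel = 48, nBen = 20))

  b1 <- bootstrapFit(genes, B = 1, seed = 5, model = "GammaZero", opts = opts)
  b2 <- bootstrapFit(genes, B = 1, seed = 5, model = "GammaZero", opts = opts)
  expect_identical(b1@replicates, b2@replicates)

  # identical genes duplicated: every resample pools the same data
  same <- rep(genes[1], 8)
  bs <- bootstrapFit(same, B = 5, seed = 2, model = "GammaZero", opts = opts)
  expect_equal(unname(bs@ciHigh["omegaA"] - bs@ciLow["omegaA"]), 0,
               tolerance = 1e-6)
})
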
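# Shared fixtures, built in code.

# A tiny in-frame alignment with known features, 10 ingroup haplotypes,
# 5 codons:
#   codon 1 GGA: pos 3 fourfold; ingroup polymorphic A/T at pos 3
#     (7 A, 3 T), outgroup A -> synonymous? GGA/GGT both Gly -> syn,
#     derived count 3
#   codon 2 ATG: monomorphic, outgroup ATA -> fixed difference (M vs I,
#     nonsynonymous divergence)
#   codon 3 CTG: ingroup polymorphic C/T at pos 1 (5/5), outgroup G
#     (matches neither) -> skipped
#   codon 4 AAA: monomorphic, equals outgroup -> mono
#   codon 5 GCC: pos 3 fourfold, monomorphic, outgroup GCT -> synonymous
#     divergence
makeToyAlignment <- function() {
  base <- c("GGA", "ATG", "CTG", "AAA", "GCC")
  seqs <- character(10)
  for (h in 1:10) {
    cods <- base
    if (h <= 3) substr(cods[1], 3, 3) <- "T"   # derived T in 3 haplotypes
    if (h <= 5) substr(cods[3], 1, 1) <- "T"   # CTG -> TTG in 5 haplotypes
    seqs[h] <- paste(cods, collapse = "")
  }
  list(ingroup = seqs,
       outgroup = paste(c("GGA", "ATA", "GTG", "AAA", "GCT"), collapse = ""))
}

# quick gene list with given per-stratum DFE truth
makeGenes <- function(nPerStratum, strata, params, lNonsyn = 600, lSyn = 210,
                      n = 10, muT = 0.1, seed = 1) {
  genes <- list(); k <- 0
  for (s in strata) {
    for (i in seq_len(nPerStratum)) {
      k <- k + 1
      cc <- simulateGene(params[[s]], lNonsyn, lSyn, n, muT,
                         seed = seed * 10000 + k, label = sprintf("g%03d", k))
      genes[[k]] <- GeneRecord(sprintf("g%03d", k), stratum = s, counts = cc,
                               length = 200, evalue = 1e-120, pnps = 0.2)
    }
  }
  genes
}

# brute-force Kendall tau-b for the oracle comparisons
bruteKendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}
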
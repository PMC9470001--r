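---
title: "Methods: estimating adaptive rates and substitution effect sizes across gene ages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive rates across gene ages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

`adaptwalk` decomposes the protein substitution rate of a set of genes
into an adaptive and a nonadaptive component, and asks how both — and
the physicochemical size of the underlying amino-acid changes — vary
with gene age. The data for one analysis cell are four quantities: the
unfolded synonymous and nonsynonymous site frequency spectra (SFS) of a
sample of *n* haplotypes, polarized by a single outgroup, and the
synonymous and nonsynonymous fixed-difference counts against that
outgroup, with the effective numbers of sites of both classes.

The method is an extension of the McDonald–Kreitman contrast. The naive
contrast is biased by segregating slightly deleterious and advantageous
mutations, so the package models them explicitly through a distribution
of fitness effects (DFE) over scaled selection coefficients
$S = 4 N_e s$:

$$\phi(S) = (1-p_b)\,\Gamma_{\text{reflected}}(S; \beta, \bar S_d)
          + p_b\,\text{Exp}(S; \bar S_b),$$

a reflected Gamma (shape $\beta$, mean $\bar S_d < 0$) of deleterious
effects plus an Exponential (mean $\bar S_b > 0$) of beneficial ones
with mixture weight $p_b$ — the Gamma-Exponential family.

Under the Poisson random field, the expected count in derived-allele
class $i$ is

$$\lambda_i^{\text{syn}} = L_s\,\theta\, r_i / i, \qquad
  \lambda_i^{\text{nonsyn}} = L_n\,\theta\, r_i
  \int \phi(S)\, H(i, n, S)\, dS,$$

with the diffusion sojourn kernel

$$H(i,n,S) = \int_0^1 \binom{n}{i} x^i (1-x)^{n-i}
  \frac{1 - e^{-S(1-x)}}{(1-e^{-S})\,x(1-x)}\, dx .$$

$\theta$ is the per-site mutation-scaled diversity, shared between site
classes; $r_i$ is an optional vector of per-class distortion multipliers
($r_1 = 1$, off by default) that can absorb demography or ascertainment,
exposed as configuration because nothing in the estimation requires it.
The counts are treated as independent Poisson observations and the DFE
parameters are estimated by maximum likelihood from the SFS alone.

Divergence never enters the likelihood. It is used afterwards:

$$\omega = \frac{D_n/L_n}{D_s/L_s}, \qquad
  \omega_{na} = (1-p_b)\int_{S<0} \phi_{\text{del}}(S)
  \frac{S}{1-e^{-S}}\,dS, \qquad
  \omega_a = \omega - \omega_{na}, \qquad
  \alpha = \omega_a/\omega .$$

This "model-based alpha" convention keeps the divergence counts — which
carry the adaptive signal — out of the DFE fit that estimates the
nonadaptive background. $\omega_a$ may legitimately be negative when
sampling noise puts $\omega$ below the fitted $\omega_{na}$;
downstream statistics propagate such values rather than truncating them.

## Numerical choices

**Quadrature.** The $S$-integral is discretized by equal-probability-mass
quantile nodes of each mixture component (default 100 deleterious, 40
beneficial; hard truncation of deleterious effects at $|S| = 10^5$,
beyond which neither polymorphism nor fixation is affected at double
precision). The $x$-integral uses composite Gauss–Legendre panels
refined toward both endpoints (break points at $10^{-5} \dots 0.9999$),
because for large $|S|$ the kernel develops boundary layers of width
$1/|S|$. The implementation evaluates
$(1-e^{-S(1-x)})/(1-e^{-S})$ in log space via `expm1` so that
$S = -10^5$ is exact rather than overflowing. Two checks pin the
accuracy: the neutral limit reproduces $\theta L / i$ to $10^{-3}$
relative, and the deleterious fixation integral matches adaptive
quadrature (`integrate`) to eight digits at the default node counts.

**Optimization.** $\theta$ is profiled out analytically (the
expectations are linear in $\theta$, so its conditional MLE is
$\sum k_i / \sum \lambda_i(\theta{=}1)$), leaving 2 (GammaZero) or 4
(GammaExpo) free parameters, optimized by L-BFGS-B on log/logit scales
with box constraints ($\beta \in [0.05, 5]$, $|\bar S_d| \in [0.5, 10^5]$,
$p_b \in [10^{-8}, 0.5]$, $\bar S_b \in [0.05, 500]$), relative
log-likelihood tolerance $10^{-8}$, and 8 multi-starts: one central plus
Latin-hypercube draws under a fixed seed. Replicate (bootstrap) fits
warm-start at the point estimate with a single start.

**Model reduction.** The beneficial component of the Gamma-Exponential
family is weakly identified from the SFS: a small $p_b$ with
$\bar S_b \to 0$ is indistinguishable from neutrality yet counts toward
$\omega_a$, so under a true null the unconstrained fit inflates
$\hat\alpha$. `fitDfe(model = "auto")` therefore fits both families and
keeps the Exponential component only when it improves the likelihood
beyond $\chi^2_2$ at the 5% level — the same fit-based family choice by
which the Gamma-Exponential model is preferred over alternatives in the
first place. The pipeline defaults to `auto`; the pure families remain
available.

**Degenerate inputs.** $D_s = 0$ makes $\omega$ undefined and is an
error; $D_n = 0$ gives $\omega = 0$, $\omega_a = -\omega_{na}$ and a
flagged (NA) $\alpha$. A frequency class with zero expectation but a
positive count yields $-\infty$ log-likelihood, flagged rather than
masked. Bootstrap replicates whose fit errors are dropped; more than 20%
failures aborts with an error rather than reporting a biased interval.

## From alignments to spectra

`buildSiteTable()` walks an in-frame codon alignment (ingroup haplotypes
plus one aligned outgroup). Rules, each of which is a deliberate choice:

* **Polarization**: at a biallelic ingroup site the allele not carried
  by the outgroup is derived. If the outgroup matches *neither* allele
  the site is discarded entirely (neither SFS nor divergence): it cannot
  be polarized, and assigning it to divergence would inflate $D$.
  Sites with more than two ingroup alleles are likewise skipped.
* **Missing data**: a missing or ambiguous outgroup base makes the site
  missing (it still counts toward $L$, which is computed from
  degeneracy, below); missing ingroup bases reduce that site's
  genotype count.
* **Site totals**: $L_s$ and $L_n$ are tallied per consensus codon by
  degeneracy — fourfold positions contribute 1 synonymous site,
  zerofold 1 nonsynonymous site, twofold and intermediate positions are
  split 1/3 : 2/3 by mutational opportunity. Site-counting conventions
  differ between tools and rarely survive re-implementation unchanged,
  so the package states its rule explicitly and applies it everywhere,
  including inside the synthetic generator.
* **Multi-position codon divergence** is counted one position at a time
  with the ingroup codon as context; such codons stay in $D$ but are
  excluded from the one-step pair analysis.
* **Down-sampling** to a common haplotype number (typical genome-scale
  data sets project to n near 100-110; nothing is hard-coded) offers a
  `random` mode (one hypergeometric draw per site, seeded,
  bit-reproducible) and an `expected` mode (exact hypergeometric mass
  per class). In both, sites monomorphic after projection are dropped
  and the dropped mass is reported, so retained + dropped mass is
  exactly 1 per site.

## Stratification and cofactor controls

Phylostrata (1 = oldest) are merged by order-preserving contiguous
schemes (`stratumScheme`); non-contiguous merges are rejected because
they would break the age ordering that the trend tests rank against.
Cofactor controls split genes at the median with ties assigned to the
low group — a deterministic reading of "two roughly equal-sized groups".
The E-value filter retains genes strictly below the cutoff (the shipped
example profiles use 1e-150 and 1e-100). The $p_n/p_s$ control retains
genes within $k$ SD of the modal $p_n/p_s$; the mode uses the
half-sample estimator because it is deterministic and robust for the
skewed, unimodal distributions involved. The window width `kSd` is a
free argument (the shipped example profiles use 0.02 and 0.05 SD), and
because an absolute-width reading of such windows is also defensible,
the filter can be driven either way by rescaling the argument.

## Grantham effect sizes

`enumerateStepPairs()` derives, by brute force over all sense codons and
their nine single-nucleotide neighbours, the amino-acid pairs reachable
in one mutational step, together with their mutation types (unordered
nucleotide pairs) and participating codons. The canonical distance
matrix ships as an integer table reconstructed from the published
side-chain composition, polarity and volume values with the published
weighting constants and mean-100 normalization; `granthamMatrix("formula")`
recomputes it from those properties as a cross-check (the two agree to
integer rounding).

Each pair's synonymous reference is the fourfold-degenerate SFS of its
mutation types, weighted by the frequencies of the pair's codons that
interconvert through each type. Pairs are assigned to 10 equal-count
distance bins. With the bin number fixed at 10 the boundaries are still
a free choice; the package uses equal pair counts over the observed
one-step distances and reports the resulting boundaries in the
partition object. Within a bin, nonsynonymous counts pool additively
across pairs and each pair's weighted fourfold reference is summed
once. Per-bin DFE fits then give
$\omega_{a,i}$, $\omega_{na,i}$, and

$$\bar G_a = \frac{\sum_i \omega_{a,i}\,\bar g_i\,N_i}{\sum_i N_i}$$

(and likewise $\bar G_{na}$), with $N_i$ the nonsynonymous site count of
bin $i$. The per-stratum distance summaries (median and quartiles of
one-step fixed differences) pool all substitutions within a stratum
rather than weighting per gene; per-gene weighting is a defensible
alternative and would be a one-line change, but pooling keeps the
summary interpretable as a property of the stratum's substitutions.

## The synthetic-data generator

`simulateStudy()` draws counts-level data from the estimator's own
sampling model: SFS class counts are Poisson around the PRF
expectations, divergence is Poisson with synonymous mean $L_s \mu T$ and
nonsynonymous mean $L_n \mu T (\omega_{na} + \omega_a)$, with the rates
computed from the generating DFE. This is deliberate: recovery tests
then measure estimation error, not model misspecification. One global
seed fans out to per-gene seeds through a counter scheme, so studies are
bit-reproducible and insensitive to evaluation order.

Default study conditions (chosen once, as a desk-scale portrait of a
Drosophila-like data set): 6 age classes of 50 genes, $n = 20$
haplotypes, $\theta = 0.02$, $\mu T = 0.1$, deleterious DFE
$\beta = 0.3$, $\bar S_d = -2000$; under the adaptive-walk gradient
$p_b$ rises log-linearly from $5\times10^{-4}$ (oldest) to $0.02$
(youngest) at $\bar S_b = 10$, and the Grantham exponent rises linearly
from 0 to 2, so adaptive substitutions in young strata are drawn
preferentially between distant residues (nonadaptive draws are weighted
inversely). Cofactors are drawn with the age correlations the analysis
must control for: young genes shorter, less expressed, more exposed,
more disordered, with shallower homology hits. Calibration-style runs
use 2000 nonsynonymous and 700 synonymous sites per gene so that a
500-gene null study totals $10^6$ nonsynonymous sites.

What the generator does *not* emulate — and hence what passing recovery
tests do not show about real data: linkage and Hill–Robertson
interference, demography and nonequilibrium spectra (no distortion is
simulated), ancestral-state misidentification, variation of $\theta$ or
$\mu T$ across genes beyond length, GC-biased gene conversion, and real
codon usage (codon frequencies are uniform by default and configurable).

## Problem sizes and runtime

The shipped validation uses sizes chosen to keep a full run on one CPU
within minutes while leaving the statistical conclusions stable: null
calibration on 500 pooled genes ($10^6$ nonsynonymous sites, one fit,
about half a minute); bootstrap coverage on 10 independent studies of
1000 genes with 100 replicates each (about six minutes); trend recovery
on 20 seeded studies at the default scale above, each fitting 6 strata
and 10 distance bins per stratum (about half a minute per seed).
Pipeline-level fits use slightly coarsened quadrature (60/24 DFE nodes)
whose relative effect on the expectations is below $10^{-3}$.

## Known limitations

* The likelihood treats frequency classes as independent Poisson
  fields; linked selection violates this on real data, and intervals
  from the gene bootstrap absorb only between-gene variation.
* Polarization by a single outgroup ignores ancestral-state
  misidentification; no probabilistic polarization is attempted.
* The distortion vector $r_i$ is exposed but not estimated by default;
  strongly nonequilibrium samples need it or will bias
  $\hat\omega_{na}$.
* $\bar G_a$ inherits the per-bin fit noise of small bins; bins without
  synonymous divergence drop out of the weighted sums and are flagged.
* The Gamma-Exponential beneficial parameters ($p_b$, $\bar S_b$) are
  only jointly identified; their individual values should not be
  over-interpreted even when the LRT retains the component.
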
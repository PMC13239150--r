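---
title: "Latent components of cross-disorder GWAS: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent components of cross-disorder GWAS: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiopc)
```

## The model

Psychiatric disorders share much of their common-variant genetic signal.
`pleiopc` works entirely from GWAS summary statistics: for each disorder a
table of per-SNP effects (beta or OR), standard errors, p-values, allele
frequencies and sample sizes. After harmonising every table onto one
reference panel, each association is summarised by its signed Z-score
`z = beta / se`, oriented to the panel's first allele.

The SNP-by-disorder matrix **Z** is built in a fixed order:

1. **Thresholding.** Entries with `p >= alpha` (default `1e-3`) are set to
   zero, so only reasonably reliable associations contribute. A boolean
   mask records which entries survived.
2. **Retention.** Only SNPs with sub-threshold associations in at least
   `min_traits = 2` disorders are kept — a SNP informative for a single
   disorder says nothing about shared structure.
3. **Clumping.** Greedy index-SNP selection within 500 kb / r-squared 0.2,
   prioritising SNPs associated with more disorders, reduces the rows to
   approximately independent signals.
4. **Standardisation.** Each disorder's column is scaled to mean 0, SD 1,
   so that differently powered GWAS contribute comparably.

The standardised matrix is decomposed by SVD, `Z = U D V'`, keeping all
`K = n_traits` components: `U` holds unit-norm SNP singular vectors, `V`
phenotype singular vectors, `D` the singular values. Derived statistics:

- **Variance explained** of component *k*: `d_k^2 / sum_j d_j^2`.
- **Contribution** of a SNP or phenotype to a component: the squared entry
  of the corresponding unit-norm singular-vector column (columns sum to 1).
- **Squared cosines**: the share of one phenotype carried by each
  component, computed on singular-value-scaled loadings,
  `(v_tk d_k)^2 / sum_j (v_tj d_j)^2`. With *unscaled* loadings every row
  of the orthonormal square matrix `V` would trivially sum to 1 entry-wise
  and carry no information; the scaled convention is the informative one,
  and is what the factor-decomposition literature computes.

Components are characterised three ways: gene-set over-representation of
the SNPs cumulatively carrying 50% of a component's variance (hypergeometric
upper tail, enrichment ratio observed/expected, BH FDR, sets of 20–500
genes); Pearson correlation of standardised SNP loadings with external GWAS
Z-scores over the shared SNPs; and component polygenic scores evaluated
against target GWAS from summary statistics alone.

## Summary-statistics polygenic scores

A component's PGS weights are its **signed** SNP singular-vector entries.
The alternative reading — squared contributions — is rejected as the
default because squaring destroys direction of effect: a score built from
squared weights cannot distinguish a risk-increasing from a risk-decreasing
allele, so case/control score differences would be uninterpretable. The
squared variant remains available (`pc_pgs_weights(..., squared = TRUE)`)
for comparison.

Group-wise evaluation reconstructs the 2x2 allelic count table of each
target-GWAS SNP from (OR, allele frequency, sample sizes). If the reported
frequency is the control frequency, the case frequency follows directly
from the OR; if it is the pooled frequency (biobank-style output), the
control frequency solves a quadratic, taking the root with both
frequencies in (0, 1). Under Hardy–Weinberg sampling and post-clumping
independence, the per-individual score `(1/M) sum_i w_i g_i` has analytic
group moments

- `mean_g = (1/M) sum_i 2 f_gi w_i`
- `sd_g   = (1/M) sqrt(sum_i w_i^2 2 f_gi (1 - f_gi))`

The division by the number of SNPs `M` is cosmetic — it cancels in the t
statistic and R² — but keeps reported means at the magnitude a per-SNP
average produces. Cases and controls are compared by a Welch
(unequal-variance) two-sample t-test with Welch–Satterthwaite degrees of
freedom; the source method states only "two-sample t-test", and Welch is
the safer default when group variances differ. `R² = t² / (t² + df)` uses
the same df.

Two further summary-statistics operations support the evaluation design:

- **Overlap subtraction**: removing a cohort from fixed-effect
  inverse-variance meta statistics,
  `beta = (w_m b_m − w_c b_c) / (w_m − w_c)`, `se = (w_m − w_c)^{-1/2}`.
  This inverts the meta-analysis exactly (tested to 1e-10); SNPs where the
  cohort's weight is not smaller than the meta's are degenerate and dropped.
- **Case–case GWAS**: both disorders' case allele frequencies are
  reconstructed, and the case-case OR is the ratio of case-allele odds with
  the Woolf SE on the reconstructed case counts. The shared-control
  covariance adjustment that a full overlapping-samples treatment would add
  is **not** implemented; with distinct control panels the Woolf SE is the
  appropriate first-order error, and this simplification is a documented
  limitation.

## The synthetic study

Real inputs at this scale are multi-gigabyte consortium downloads, so the
generator plants the structure the pipeline is meant to find and everything
is validated against that truth. A `planted_model` holds orthonormal
phenotype factors, sparse standard-normal SNP factors and per-component
scales; the observed matrix is `signal + noise` with
`signal = F_snp diag(scales) F_pheno'` and i.i.d. normal noise on the **Z
scale** — the pipeline consumes Z-scores, so that is where the noise model
must live; betas and SEs are back-derived (`se = 1/sqrt(2 f (1-f) n_eff)`)
for file realism. LD comes in blocks: within-block pairs share one
r-squared, blocks are independent, block spans are well under the clumping
window and blocks are separated by more than it.

Default study conditions, chosen once: 8 traits, 2000 SNPs, 3 components
at scales (10, 7, 5) over unit noise, SNP-factor sparsity 0.15, MAF
uniform in (0.05, 0.5), 20,000 cases / 30,000 controls per trait, LD
blocks of 5 at r-squared 0.8. The scales-over-noise ratio matches the
regime in which recovery is asserted (mean Tucker congruence above 0.95
across seeds); sparsity and MAF are desk-scale stand-ins for a clumped
GWAS panel. Target cohorts shift case allele frequencies along the sign of
each weight and draw binomial(2, f) genotypes, so analytic group moments
can be checked against individual-level scores and reconstruction against
realised counts.

What the generator does **not** emulate — realistic LD from population
panels, realistic MAF spectra, ascertainment bias, sample overlap between
discovery GWAS, population stratification — bounds what passing tests
show: they validate the algebra and the pipeline's contracts, not
robustness to the messiness of real consortium data.

## Numerical conventions and edge cases

- **SD denominator.** All standardisations (matrix columns, loading
  Z-scores) use the population convention (divide by *n*). The constant
  cancels in SVD directions and in Pearson correlations; determinism
  matters more than the choice.
- **Sign canonicalisation.** SVD leaves each component's sign arbitrary.
  Each component is oriented so its largest-magnitude phenotype loading is
  positive; SNP and phenotype columns flip together, so the reconstruction
  is unchanged. Downstream direction checks are orientation-aware, and a
  recovered component may still be the negative of a planted factor —
  congruence is therefore scored in absolute value.
- **Clumping tie-breaks.** The stated priority is the number of disorders
  with non-zero Z. Beyond that the order is unspecified; ties break by
  maximum |z| descending, then SNP id ascending, making the greedy
  selection fully deterministic (and testable against a brute-force
  oracle).
- **Structural vs thresholded zeros.** A SNP absent from one GWAS and a
  SNP zeroed by the p-value rule enter standardisation identically; the
  mask preserves the distinction for diagnostics only.
- **Window semantics.** Pairwise distance `|pos_a − pos_b| <= window_bp`,
  same chromosome, inclusive; region exclusion uses inclusive bounds and
  runs before clumping.
- **Strand handling.** A/T and C/G SNPs cannot be disambiguated between
  strands and are dropped by default (configurable); records matching the
  panel only after complementation are complemented, then aligned or
  flipped. OR-vs-beta is declared in the column map, never auto-detected —
  silently misreading the effect scale is the worst failure mode.
- **Cumulative SNP selection.** SNPs are ranked by contribution with ties
  broken by id; the shortest prefix reaching the fraction is returned, with
  a 1e-12 slack on the comparison so exact-boundary prefixes are not
  extended by floating-point noise.
- **Degenerate inputs** are fatal, named errors where silence would bias
  results: zero-variance columns, empty post-filter matrices, missing
  clumping positions, all-zero singular values, empty enrichment queries,
  fewer than 3 shared SNPs in a correlation.

## Open choices resolved here

- "SNP loadings transformed into Z-scores" for external correlation is read
  as simple standardisation of the loading column. The alternative —
  rescaling to the original GWAS Z units — is an affine transform, and
  Pearson correlation is invariant to it, so the choice cannot change any
  downstream result.
- External GWAS Z-scores are left unstandardised before correlation, for
  the same invariance reason.
- SNPs missing from an external GWAS are dropped from that correlation,
  not zero-filled; zero-filling would shrink r towards zero by an amount
  depending on coverage.
- The hypergeometric FDR universe is all sets surviving the size filter,
  per collection. The background is always an explicit input, never
  inferred from the mapping.
- No additional QC (MAF or imputation-quality filters) is applied during
  harmonisation beyond allele reconciliation; any such filtering belongs
  upstream.

## Problem sizes

The test suite and the analysis drivers run the study conditions at
2000 SNPs x 8 traits (recovery, identities, the end-to-end run), 200
random instances of up to 100 SNPs for the clumping oracle, 1000 random
SNPs for subtraction and reconstruction round trips, 50,000 individuals
per group for the one individual-level simulation, and 20 replicate null
cohorts for calibration — sizes at which every guarantee is checked
exactly or within stated Monte-Carlo bounds while the whole suite stays
desk-scale.

## Limitations

Residual LD below the clumping threshold is ignored in the analytic PGS
SD; the case-case SE omits shared-control covariance; the decomposition is
linear and orthogonal by construction and cannot represent correlated
latent factors; and all validation is against planted structure, not
external data.
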
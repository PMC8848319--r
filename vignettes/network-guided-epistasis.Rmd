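---
title: "Network-guided epistasis detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-guided epistasis detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netepi)
```

## The problem

Genome-wide interaction scans test enormous numbers of SNP pairs, pay a
crushing multiple-testing price, and return hits that are hard to interpret
biologically. `netepi` implements a protocol that restricts the scan to SNP
pairs spanning *gene models* — gene pairs with prior co-function evidence in
a knowledge network — and then aggregates SNP-pair statistics into
gene-pair significance. The result is a much smaller hypothesis space,
interpretable gene-level findings, and (as the package's own calibration
experiments verify) a controlled type I error.

The pipeline has six statistical stages:

1. **Hypothesis space.** Network edges supported by at least
   `min_evidence = 2` sources become gene models; self-interactions are
   removed (within-gene epistasis needs different machinery). Each gene
   model is expanded into SNP pairs via one or more SNP-gene mappings
   (positional, eQTL, chromatin-contact), and the pairs pass quality
   control: minor allele frequency at least 5%, exact Hardy–Weinberg
   p-value at least $10^{-3}$, no pair fully inside the HLA region, dosage
   $r^2 \le 0.75$. A whitelist exempts known risk SNPs from the MAF/HWE
   rules (only those two; the LD and HLA rules still apply, since they
   protect the interaction model itself).
2. **Phenotype adjustment.** The binary status is regressed on covariates
   (ancestry principal components) by logistic IRLS, and the *response
   residuals* $y - \hat p$ become the working phenotype. This mirrors the
   common workaround for interaction engines that cannot carry covariates;
   the residual scale makes every downstream test a linear model.
3. **Interaction scan.** For each candidate pair, ordinary least squares of
   $Y = \beta_0 + \beta_1 g_A + \beta_2 g_B + \beta_3 g_A g_B$, with a
   two-sided Student-t test of $\beta_3 = 0$ on residual degrees of
   freedom. We use the t reference rather than a normal approximation so
   the small fixtures in the test suite are exact; at cohort scale the two
   are indistinguishable.
4. **Family-wise error control.** The number of tested pairs differs
   between analyses, so the significance threshold is dataset-dependent:
   the adjusted phenotype is permuted `n_perm = 400` times, the full scan
   is re-run per permutation, and the threshold is the
   $\lfloor 0.05\,n_\text{perm}\rfloor$-th smallest of the per-permutation
   minimum p-values. "5% percentile" does not pin an interpolation rule;
   the order-statistic definition keeps the threshold an actually observed
   value and its coverage exactly $k/(n_\text{perm}+1)$.
5. **Gene-level aggregation (ATPM).** For a gene pair with $N$ SNP pairs,
   the truncated product $W(\tau)=\prod_i p_i^{I(p_i\le\tau)}$ is computed
   for $\tau \in \{0.001, 0.01, 0.05\}$ over the observed data ($b=0$) and
   $B = 999$ phenotype permutations. Empirical p-values
   $\pi_b(\tau)=\sum_l I(W_b \ge W_l)/(B+1)$ include the observed statistic
   in its own null (Becker–Knapp convention), the adaptive statistic is
   $\pi^*_b=\min_\tau \pi_b(\tau)$, and the gene-level p-value is
   $P_0=\sum_l I(\pi^*_0 \ge \pi^*_l)/(B+1)$, significant at
   $P_0 \le 0.05$. Only gene models parenting at least one
   threshold-passing SNP pair are tested; this preselection is what keeps
   the protocol-wide type I error near the nominal level without a further
   gene-level correction.
6. **Interpretation aids.** Significant pairs are re-tested with a
   clumping-and-averaging polygenic score as an extra covariate to flag
   signals inflated by nearby main effects (phantom epistasis); significant
   gene pairs get a shortest-path network neighborhood and a
   hypergeometric gene-set enrichment with a Bonferroni threshold of
   $0.05/(\#\text{pathways}\times\#\text{tested neighborhoods})$.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_evidence` | 2 | evidence sources required for a gene model |
| `maf_min` | 0.05 | minimum minor allele frequency (fraction) |
| `hwe_alpha` | 0.001 | exact HWE p-value below which a SNP is dropped |
| `ld_r2_max` | 0.75 | dosage r² above which a pair is dropped |
| `hla_region` | chr6:25–34 Mb | closed interval; both SNPs inside → pair dropped |
| `n_perm_threshold` | 400 | permutations for the SNP-level threshold |
| `fwer` | 0.05 | target family-wise error rate |
| `taus` | 0.001, 0.01, 0.05 | ATPM truncation points |
| `B` | 999 | ATPM permutations |
| `alpha` | 0.05 | gene-level cutoff on `P0` |
| `store_threshold` | 0.05 | scan storage cutoff (see below) |
| clumping | 250 kb, p ≤ 1, r² > 0.1 | polygenic-score construction |

All boundary conventions are explicit: MAF strictly below the threshold
drops, HWE strictly below drops, r² strictly above drops, selection at the
permutation threshold is inclusive (`p <= threshold`), the truncation
indicator is inclusive (`p <= tau`), and both ATPM rank comparisons are
inclusive (`>=`). Tie-breaking in clumping is by ascending p, then
position, then SNP id, which makes the kept set independent of row order.

**Storage threshold.** Scan engines typically store only pairs below a
reporting cutoff (often $10^{-4}$). Storing at $10^{-4}$ would make
$W(0.01)$ and $W(0.05)$ depend only on the stored tail, so `netepi` stores
at `max(taus) = 0.05` instead: every truncated product is then exact. The
sparse-storage convention is explicit in the API: an absent entry of a
permuted p-value store is known to lie in `(store_threshold, 1]` and
contributes no factor at any `tau`.

## What the synthetic-data generator emulates

`simulate_dataset()` produces genotypes in LD blocks: per block, a latent
Gaussian with exchangeable correlation is thresholded at the
allele-frequency quantile, twice per sample, and summed. Each SNP is
therefore marginally in Hardy–Weinberg proportions (verified by a χ²
goodness-of-fit property test) while within-block dosage correlation is
tunable and across-block correlation is zero. The phenotype follows a
logistic model with optional planted SNP main effects, planted gene-pair
interactions (one representative SNP pair each — matching the observation
that real gene-level signals are typically carried by few SNP pairs), and
a latent standard-normal ancestry axis exposed directly as covariate
column 1.

The generator deliberately does **not** emulate realistic recombination
maps, allele-frequency spectra, haplotype-block irregularity, genotyping
error, or missingness patterns of real arrays. Passing calibration tests
on this generator therefore demonstrates that the statistical machinery is
correct under its stated assumptions — not that power or error rates on a
particular real cohort will match. One targeted exception: the
phantom-epistasis test fixture couples a causal allele onto the
double-minor haplotype of two flanking SNPs, which is the configuration in
which a pure main effect masquerades as an interaction and which the
polygenic-score adjustment is designed to deflate.

## Numerical choices

* p-values are clamped to the smallest positive double, never 0.
* Truncated products are computed and stored in log space; a test asserts
  agreement with the direct product to $10^{-10}$ on non-underflowing
  cases, and the empty product is exactly 1.
* The exact HWE test runs its recurrence in log space (the unnormalized
  conditional mass spans hundreds of orders of magnitude at large n) and
  includes tables whose probability is within a $1+10^{-7}$ relative
  factor of the observed table's, so mathematically tied tables enter the
  tail regardless of floating-point rounding.
* Rank-deficient interaction designs (e.g. a SNP with no heterozygotes
  among minor-allele carriers) are flagged degenerate and recorded with
  p = 1 rather than dropped silently.
* Per-pair complete-case handling: samples missing either genotype are
  excluded for that pair only.
* Every stage derives its own RNG stream from the master seed by a counter
  scheme, so threshold permutations, ATPM permutations and outer
  permutations are mutually independent and any stage can be reproduced in
  isolation.

## Design choices where the design was open

* **Permutation target.** Permutations shuffle the *adjusted* phenotype
  rather than re-adjusting a permuted binary phenotype: this breaks all
  genotype–phenotype association while preserving the residual
  distribution, and makes the scan's null exactly exchangeable.
* **Shared ATPM permutations.** The B = 999 permutations are generated
  once and shared across all candidate gene models, preserving the
  dependence structure between gene models at a total cost of B scans.
  The threshold stage uses an independent stream.
* **Duplicate network edges** are merged keeping the maximum evidence
  count — the conservative-inclusion choice for a filter whose only use is
  `evidence >= min_evidence`.
* **MAF/HWE on the pooled cohort** (cases plus controls), the usual
  choice when the QC's purpose is pair-level model stability rather than
  disease association.
* **Bonferroni scope in the pathway stage** is global by default (the
  union of gene sets touched by any tested neighborhood times the number
  of tested neighborhoods); a `per_neighborhood` scope is available since
  the counting rule is genuinely ambiguous.
* **Type-I-error harness.** The SNP-level threshold is computed once from
  the observed data and reused across outer permutations: under the global
  null the threshold's distribution is identical for every permutation,
  and nesting 400 permutations inside each of 1000 outer permutations
  would be computationally prohibitive for no statistical gain.
* **Standard mode** (no network) scans all pairs and assigns gene pairs
  post hoc through the positional mapping only, so its gene-level results
  are comparable with the network-guided modes.

## Problem sizes used by the shipped experiments

The package's calibration experiments are sized for a single CPU: the
full-protocol type-I-error run uses 500 samples × 200 SNPs (60 gene
models), a threshold from 200 permutations and 200 outer permutations with
B = 199; the threshold-FWER run uses 500 × 150 (50 SNP pairs) with 400
permutations and 400 fresh null draws; the ATPM grid-calibration run uses
1000 replicates of a 300-sample, 4-SNP-pair null with B = 999. The test
suite re-runs reduced versions of the same experiments. At these sizes the
full acceptance computation completes in about a minute.

## Known limitations

* The interaction model is linear on the response-residual scale; a
  logistic interaction model with covariates would be the natural
  alternative where the tooling allows it.
* Dosage (imputed) genotypes, phased data and X-chromosome coding are out
  of scope; genotypes are additive 0/1/2 with an explicit missing state.
* The polygenic-score re-test is descriptive: adjusted p-values are
  reported alongside the originals, not re-thresholded, because the
  appropriate multiple-testing correction after conditioning is unclear.
* Gene models with SNP pairs that all fail QC (or genes with no mapped
  SNPs) are carried as a side list but can never reach significance.
* The empirical p-value floor is $1/(B+1)$; at B = 999 no gene pair can
  report `P0` below 0.001.
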
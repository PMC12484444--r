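---
title: "Cell-weighted polygenic risk scores: model, assumptions and design choices"
author: "cellprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-weighted polygenic risk scores: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellprs)
```

## The model

A polygenic risk score aggregates per-variant GWAS effects into one
per-individual liability. `cellprs` decomposes that liability by brain
cell type: every variant is mapped positionally to its nearest gene,
the gene's fractional expression across six cell types is estimated
from labelled single-cell counts, and the variant's effect size is
multiplied by 100 times that fraction before scoring. A gene expressed
almost exclusively in microglia therefore pushes its variants' weight
into the microglial score and out of the neuronal ones. The unweighted
("full") score is carried alongside as the reference.

The weight for gene $g$ in cell type $c$ is

$$w_{gc} = \frac{\bar e_{gc}}{\sum_{c'} \bar e_{gc'}},$$

where $\bar e_{gc}$ is the mean, over cells of type $c$, of
`expm1(log1p(count/total * 10^6))`. Rows sum to one by construction;
genes with zero expression everywhere are flagged absent rather than
emitted as `NaN`, and variants mapping to them stay in the full score
only.

Scores follow the clumping-and-thresholding tradition: variants are
QC-filtered, harmonized against the counted genotype allele, greedily
clumped at $r^2 < 0.1$ within 1000 kb (most significant variant kept
per window), subset at seven strict thresholds
$P < 0.05, 5\times10^{-3}, \ldots, 5\times10^{-8}$ (PRS1–PRS7, nested
by construction), scored as $\sum_v d_{iv} \beta_v$, and standardized.
Scoring and inference are repeated with the APOE region
(chr19:44905796–44909393 $\pm$ 1 Mb, boundaries inclusive) removed, to
separate the APOE locus' outsized contribution from the polygenic
remainder.

## Statistical stages and their assumptions

* **Amyloid status** (CSF ratio below 0.091) is modelled by logistic
  regression; **pTau217** and cognitive outcomes are rank-based
  inverse-normal transformed (Blom offset 3/8, average ranks for ties)
  and modelled by OLS. Covariates: age, sex, ten genotype PCs; models
  on APOE-excluded scores additionally adjust for APOE ε4 and ε2
  counts. The transform makes the linear model's error assumption
  innocuous but changes the outcome scale: coefficients are per SD of
  PRS on the normal-scores scale.
* **Families and FDR.** The default plan per outcome is 7 score types
  × 7 thresholds × 2 APOE modes = 98 models, corrected together by
  Benjamini–Hochberg. The family is the unit of error control;
  cognition analyses can be planned as their own families.
* **Attenuation.** Whether excluding APOE attenuates a score type's
  associations is tested by a paired t-test on the per-threshold t
  statistics (differences across the seven thresholds). The paired
  form is the default because the seven PRS are nested and strongly
  dependent; an unpaired Welch mode exists for sensitivity.
* **Mediation.** The amyloid-mediated share of a score's pTau217
  effect is the difference of coefficients $c - c'$ (total minus
  amyloid-adjusted), with a percentile bootstrap CI over resampled
  individuals and significance read off the CI excluding zero. The
  proportion mediated $(c - c')/c$ is reported as a percentage and is
  undefined (flagged, not fabricated) when $|c| < 10^{-10}$. A
  product-of-coefficients mode ($a\cdot b$) is provided as a
  cross-check for continuous mediators; for a binary mediator the
  difference form on the linear pTau217 scale is the estimator of
  record. Both regressions share the same QR fitting core as the
  association stage, so $c'$ is bit-identical to the adjusted
  association coefficient.
* **Longitudinal decline.** Nested mixed models
  `outcome ~ covariates + PRS + time + PRS:time + (1 + time | id)`
  versus the model without `PRS:time`, both fit by maximum likelihood
  (not REML, since the fixed effects differ), compared by a 1-df
  likelihood-ratio chi-square. Non-convergence is warned and surfaced
  as `NA`, never silently dropped.

## What the synthetic generator emulates

`simulate_cohort()` provides the statistical structure the analysis
assumes, at desk scale, with one seed determining every byte:

* **Genotypes** — Gaussian-copula haplotypes: within an LD block the
  latent normals share a factor with loading $\sqrt{\rho}$
  (`ld_rho`, default 0.7), thresholded at the $(1-\mathrm{MAF})$
  quantile and summed into diploid dosages. This is the simplest model
  with tunable $r^2$, which is all clumping exercises. It does not
  reproduce human LD decay, allele-frequency spectra or imputation
  dosage uncertainty. Note a property of any threshold-copula model:
  two variants with very different MAFs cannot reach high $r^2$ even
  at latent correlation 0.99, because thresholding at different
  quantiles caps the phi coefficient.
* **Gene map** — 120 genes spaced 2.5 Mb apart over six chromosomes,
  so each gene's ±1 Mb variant neighbourhood is disjoint; the last
  chromosome is labelled chr19 with one gene centred in the APOE
  region so the mask has work to do. Each gene's neighbourhood
  receives an equal share of the 400-variant panel.
* **Single-cell counts** — negative binomial with gene-level
  log-normal baselines; each of the six types has 3 marker genes whose
  mean is elevated 20-fold in its own type, giving expected own-type
  weights of $20/25 = 0.8$. Two percent of cells are labelled "None"
  to exercise the documented filter. No doublets, batch effects or
  ambient RNA.
* **Discovery GWAS** — an independent cohort (default n = 5000) is
  simulated from the same variant panel; variants near causal genes
  get true effects $N(0, 0.15^2)$, a phenotype is generated, and
  per-variant marginal regressions give $(\hat\beta, p)$. The paper's
  source GWAS does not state a sample size or effect scale, so these
  are free parameters chosen to make genome-wide-significant variants
  (PRS7 non-empty) attainable at desk scale.
* **Phenotypes** — amyloid liability is
  `gamma_amyloid × score + 0.02·(age−71) + 0.1·sex + noise`; the CSF
  ratio is an affine decreasing map of liability calibrated so that
  `status == (ratio < 0.091)` holds exactly at ~35% positivity;
  pTau217 is `alpha_tau × amyloid + Σ_c delta_direct[c] × score_c +
  noise`, exponentiated to a positive skewed scale (the analysis INTs
  it anyway); cognition has per-subject random intercepts and slopes
  with an optional score-by-time term, five visits two years apart.
  Defaults (γ = 0.4, α = 0.6, δ = 0.2) inject partial mediation.
  MMSE is not ceiling-truncated at 30 — truncation would create rank
  ties without changing what the tests exercise.

Passing tests on this generator show the pipeline's operations are
correct and calibrated under the stated structure; they do not show
robustness to real-data pathologies (population stratification,
assay batch effects, genotyping artefacts, real LD).

## Numerical and design choices

* **Averaging semantics.** The toolkit convention this package
  follows averages back-transformed (`expm1`) normalized values;
  a `mean_of_log` alternative is selectable and the choice is recorded
  in the weight matrix metadata, because the two differ whenever
  expression varies across cells of a type.
* **Percent scale.** Scaled effects use the 0–100 percent scale
  (β × 100 × fraction), matching the field's reporting convention for
  the single-variant example (−0.0603 × 88.4 → −5.3); standardization
  makes the factor immaterial to inference.
* **Clump once.** Clumping runs on unweighted p-values and the index
  set is shared across score types: reweighting does not change
  p-values. Ties in the p-ordering break by chromosome then position
  for reproducibility.
* **Sum vs average scoring**: sum, recorded in metadata;
  standardization removes the difference. Missing dosages are
  mean-imputed at twice the effect-allele frequency, the common
  scoring default.
* **Strict thresholds** (`p < t`), per the "P < …" convention.
* **HWE**: 1-df chi-square against expected genotype frequencies;
  monomorphic variants return p = 1. An exact test adds nothing at
  MAF ≥ 5%.
* **Harmonization**: no strand inference; A/T and C/G pairs are kept
  only on literal allele match, with a `drop_ambiguous` switch.
  Imputed panels are normally pre-aligned, and guessing strands
  silently is worse than dropping.
* **Logistic fits**: IRLS to |Δ| < 1e−8, max 100 iterations; apparent
  separation (non-convergence or |coef| > 15) is an error, not a
  result.
* **Zero-variance guards**: standardization and the paired attenuation
  test raise named errors; `ld_r2` defines r² = 0 with a warning for a
  monomorphic variant (it cannot clump others).
* **Restricted PRS**: "strictly cell-specific" is externalized as a
  weight threshold τ (default 0.5) because no canonical value exists;
  variants within 1 Mb of the selected genes are clumped, thresholded
  and scored with unweighted effects.
* **Bootstrap**: resamples whole individuals, preserving covariate
  structure; degenerate draws are redrawn and counted; the seed is
  stored in the result.

## Problem sizes used by the test suite

Chosen as the package's own desk-scale study conditions: unit tests
run on 300-individual cohorts with 120 variants; calibration uses 100
seeds at n = 1000 with 40 null phenotype replicates per seed per
fitting stage (the longitudinal LRT contributes one p-value per seed,
pooled, since its within-seed replication would multiply mixed-model
fits without changing the question); cell-type recovery uses 50 seeds
at n = 1000; mediation recovery uses n = 2000 with 200 bootstrap
resamples and a 100-seed null-coverage run. Within-seed replicates are
used for the calibration KS tests rather than the 98-model family
because the nested thresholds make family p-values strongly dependent,
which would invalidate the KS reference distribution.

## Known limitations

* The nearest-gene assignment ignores multi-gene loci and
  trans-effects; an external SNP→gene table (e.g. eQTL-based) can be
  substituted via `apply_snp_gene_table()`.
* The Allen-style class/subclass labels must be collapsed to the six
  analysis types by the user-supplied `label_map`; no canonical
  mapping ships with the package.
* LD is reference-free: r² always comes from the supplied genotypes.
* The mediation estimator assumes no unmeasured mediator-outcome
  confounding and no exposure–mediator interaction; sensitivity
  analysis for those assumptions is out of scope.
* APOE allele counts are simulated as covariates independent of the
  genotype panel; APOE haplotype genetics are not modelled.
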
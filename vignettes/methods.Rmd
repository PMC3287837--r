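---
title: "Gene-based rare-variant collapsing tests: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based rare-variant collapsing tests: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-variant regression has essentially no power against rare variants:
with a minor allele frequency (MAF) of a few per mille, almost no carriers
are observed and the per-variant test is hopeless. The standard remedy is
to *collapse* all rare variants of a gene region into one per-subject
burden score and test that score against the trait. `rvcollapse`
implements this programme for quantitative traits, together with two ways
of letting the region's *common* variants into the same test, and an
evaluation layer that measures how well-calibrated and how powerful the
resulting tests are on synthetic data.

## Models

### Collapsing scores

For the rare variants of a gene (MAF strictly below a cutoff $c \in
\{0.005, 0.01, 0.05\}$; a variant with MAF exactly $c$ counts as common,
and monomorphic variants are excluded everywhere), with $g_{ij} \in
\{0,1,2\}$ the minor-allele dosage of subject $i$ at rare variant $j$:

* **indicator**: $s_i = \mathbf 1\{\sum_j g_{ij} > 0\}$ — does the subject
  carry any rare minor allele;
* **count**: $s_i = \sum_j g_{ij}$ — the total number of rare minor
  alleles. With complete genotypes this equals $2m$ times the per-subject
  proportion of rare minor alleles over the $m$ rare variants, so the
  proportion parameterisation is the same test;
* **data-adaptive sum**: each rare variant is first screened with a linear
  regression of the trait on the covariates plus that variant's dosage.
  If the dosage coefficient is negative with a two-sided p-value at or
  below 0.1 (inclusive), the variant's coding is flipped to major-allele
  counting ($2 - g$); the score is then the row sum of the recoded
  columns. Because the outcome itself drives the coding, testing the score
  against the same trait replicate is biased toward association; the
  package preserves this deliberately and calibrates it downstream (see
  *Inference for the data-adaptive score*).

### Association test

Association is measured by a nested-model F statistic. With $Z$ the
covariate design (intercept, sex, age, smoking status and population
group as six treatment-coded dummies for seven groups) and $G$ the
genetic terms,

$$F = \frac{(\mathrm{RSS}_Z - \mathrm{RSS}_{Z+G})/q}{\mathrm{RSS}_{Z+G}/(n - p)},$$

where $q$ is the rank added by $G$ over $Z$ and $p$ the rank of the full
design. Genetic columns that add no rank (constant, duplicated, or
collinear with the covariates) are dropped and logged; $q$ always equals
the retained rank, so the reference distribution $F(q, n-p)$ is exact
under the Gaussian null. A gene with no testable genetic term (no rare
variants at the cutoff, or a constant score and no common variants) is
reported as *skipped*, never as a p-value.

The three common-variant strategies differ only in $G$:

* **none**: $G = [s]$, the burden score alone;
* **CMC** (combined multivariate and collapsing): $G = [s \mid X_C]$ with
  $X_C$ all common-variant dosages of the region;
* **LASSO**: an L1-penalised path is fit with zero penalty on the
  covariates and the score (they are always retained) and unit penalty on
  the common variants; 10-fold cross-validation with squared-error loss
  picks $\lambda_{1se}$, the largest $\lambda$ whose mean CV error is
  within one standard error of the minimum; the selected common variants
  are refit by ordinary least squares and tested with the same F
  statistic. The selection uses the same trait replicate as the test, so
  these p-values are anti-conservative by construction — that
  post-selection inflation is a *finding* this package is designed to
  exhibit, not a bug it tries to hide.

### Evaluation: empirical null, type I error, power

Null-trait results for one method × strategy × cutoff are pooled across
genes and replicates into an empirical null distribution of p-values
(p-values, not F statistics, because genes differ in numerator degrees of
freedom and raw F values are not exchangeable across them). From the pool:

* **type I error** at a nominal level $\alpha$ is the fraction of pooled
  null p-values below $\alpha$ — this is the quantity a calibration table
  at the "5% significance level" reports, and the only reading under
  which an inflated method can show type I error above 5%;
* the **empirical threshold** is the order statistic at rank
  $\lceil \alpha n \rceil + 1$, with the strict rejection rule
  $p < \hat q$, which guarantees the rejection fraction on the pool
  itself never exceeds $\alpha$;
* **power** per gene is the fraction of associated-trait replicates below
  the empirical threshold of the *matching* method × strategy × cutoff
  pool, so each method is judged against its own attained null.

### Inference for the data-adaptive score

The data-adaptive method needs either an empirical null (above) or
permutation. `permutation_null()` re-runs the *entire* procedure — flip
decisions and F-test — on each permuted trait and returns the add-one
estimate $(1 + \#\{F^* \ge F\})/(1 + B)$. Permuting the raw trait would
destroy the covariate–trait relationship, so the default scheme permutes
residuals of the covariate-only fit and adds them back to the fitted
values (Freedman–Lane style); raw-trait permutation remains available.
`adaptive_permutation_test()` is an algebraically identical vectorised
implementation (one covariate QR, all permutations by matrix algebra)
that draws the same permutations under the same seed and is tested for
exact agreement with the closure route; it exists so that
calibration studies with thousands of permutation tests stay feasible.

## The synthetic data generator

The generator emulates the design of a well-known simulated exome panel:
697 unrelated subjects from 7 populations, one fixed genotype panel, and
200 phenotype replicates in which only the noise (and nothing genetic) is
redrawn. Defaults:

* **genotypes**: per gene, specification frequencies are drawn from the
  architecture's MAF ranges; each population perturbs them on the logit
  scale (jitter SD 0.25), which induces real confounding by ancestry and
  justifies the population covariate. Two haplotypes per subject are
  generated by a first-order Markov copying process (adjacent-variant
  copying probability `ld_rho`) and summed to dosages, so rare–common
  linkage disequilibrium exists and common variants can tag causal rare
  ones. Realised sample MAFs are recomputed afterwards: a variant
  specified near a cutoff may drift across it, exactly the behaviour that
  makes power sensitive to cutoffs near a risk variant's MAF.
* **null genes** (`null_gene_specs()`): 13 variants with MAF drawn
  log-uniformly on $(5\times10^{-4}, 0.05)$ — the $1/f$ shape of a
  neutral site-frequency spectrum, so the region is mostly rare and
  variants reclassify from common to rare as the cutoff rises — plus 5
  clearly common variants log-uniform on $(0.05, 0.35)$, `ld_rho = 0.2`.
  An earlier draft used disjoint uniform blocks with a spectrum hole
  between 0.01 and 0.06; that hole froze the common-variant pool across
  cutoffs and thereby suppressed the cutoff dependence of LASSO's
  post-selection inflation, whose mechanism (fewer candidates undergoing
  selection at higher cutoffs) requires a continuous spectrum. The
  continuous spectrum is also simply the more faithful model of exome
  data.
* **associated genes** (`gaw17_gene_presets()`): the nine risk-gene
  architectures (causal/total counts of rare and common variants at each
  cutoff) are shipped as presets. The underlying per-variant effect sizes
  were never published, so the preset betas (default 0.5 per causal rare
  minor allele, 0.3 per causal common, in units of the residual SD 1) are
  free parameters chosen to land in a moderate-power regime; published
  per-gene power values are therefore *not* reproduction targets, only
  the directional contrasts between methods are.
* **covariates**: sex ~ Bernoulli(0.5); age ~ Normal(50, 10) truncated to
  [18, 90]; smoking ~ Bernoulli(0.3); population from the configured
  weights (uniform by default). Covariate effects on the trait default to
  0.5 (sex), 0.02 per year (age), 0.5 (smoking) and per-population shifts
  spanning ±0.5 — large enough that failing to adjust is visibly wrong.
* **effect direction**: all causal betas are non-negative by default
  (every causal minor allele increases the trait), matching the design
  whose central caveat is exactly that same-direction assumption; a
  mixed-direction world is available via `allow_negative_beta` but is not
  part of any acceptance property.

What the generator does **not** model: coalescent/demographic realism,
related subjects, sex chromosomes, genotyping error or missingness
(readers impute, the analysis path requires completeness), and dosage
uncertainty. A green test on this world therefore establishes the
statistical machinery — calibration of the F-test, the direction and
mechanism of adaptive and post-selection inflation, the benefit of
common variants — not population-genetic realism.

## Numerical choices

* Rank decisions use R's pivoted QR; dropped genetic columns are reported
  and the F numerator df equals the retained rank.
* A full-model residual sum of squares below $10^{-10}\,\max(\mathrm{RSS}_{reduced},1)$
  is treated as a perfect fit ($F = \infty$, $p = 0$).
* The marginal flip regressions use Frisch–Waugh residualisation against
  one shared covariate QR; variants whose residualised dosage has
  (near-)zero variance are never flipped and contribute their column
  unchanged.
* For trait-independent designs (indicator/count scores with the none and
  CMC strategies) the driver batches all replicates through one QR per
  design; the batch is tested for agreement with the per-test route at
  $10^{-12}$.
* Cross-validation folds are a seeded random partition; per-test fold
  seeds derive deterministically from one base seed, so whole studies are
  bit-reproducible.
* Boundary conventions: rare means MAF $<$ cutoff (strict); the flip rule
  is $p \le 0.1$ (inclusive); empirical-threshold rejection is $p <
  \hat q$ (strict).

## Design choices that were genuinely open

* **One- vs two-sided flip p-value**: the flip rule pairs a sign condition
  with a p-value condition, which implies an unsigned (two-sided) test;
  two-sided is used.
* **λ within one standard error**: read as the standard `lambda.1se`
  convention (largest λ with CV error within one SE of the minimum
  error), the convention of the software the procedure is defined
  against, rather than a literal window on the λ axis.
* **Pooling p-values, not F statistics**, across genes with unequal df
  (see above).
* **Type I error at the nominal threshold, power at the empirical
  threshold**: the calibration table can only exhibit inflation if type I
  error is measured against the nominal 5% F quantile; power, by
  contrast, is defined against each method's own empirical null.
* **Permutation scheme**: residual (Freedman–Lane) permutation by
  default, because raw-trait permutation is only valid when covariates
  carry no signal.
* **MAF computed on the pooled analysis sample**, not per population, as
  a single MAF per variant is assumed throughout.
* **Subject alignment is by identifier**, never by row order across
  files.

## Known limitations

* **The one-standard-error rule gates LASSO power.** At n = 697 a common
  variant survives `lambda.1se` selection only when it cuts the CV error
  by about one CV standard error (roughly 5% of residual variance), an
  order of magnitude above what the F-test needs for near-certain
  rejection. Selection probability is therefore a sharp sigmoid in the
  effect size, and the LASSO test's power is a mixture of "selected, and
  then saturated" and "nothing selected, fall back to the collapse-only
  test". Consequently LASSO power can only match CMC power at full
  saturation in this Gaussian world; reports of LASSO slightly beating
  CMC on architectures with one causal common variant among few are not
  reproducible here and plausibly reflect data-specific LD or Monte Carlo
  error. The corresponding acceptance assertion is deliberately left
  failing rather than weakened.

* LASSO inflation magnitudes (and to a lesser degree the adaptive
  method's) depend on the variant pool and LD structure, so only their
  direction and ordering are asserted — the published magnitudes came
  from a restricted genotype panel this package cannot redistribute or
  reconstruct.
* The permutation test is exact only under exchangeability of residuals;
  with heteroscedastic noise it is approximate.
* `cv.glmnet` dominates the runtime of LASSO studies (~0.1 s per
  gene-replicate at n = 697); the shipped studies are sized accordingly.
* The VCF reader handles biallelic SNVs with plain GT fields only; the
  tab-delimited dosage matrix is the primary interchange format.
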
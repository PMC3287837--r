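# rvcollapse

Gene-based rare-variant association testing for quantitative traits.

## What problem this solves

Rare variants (minor allele frequency below 0.005–0.05) carry too few
carriers for single-variant regression to detect anything. `rvcollapse`
tests a whole gene region at once by collapsing its rare variants into one
per-subject burden score and comparing nested linear models. It is aimed at
statistical geneticists who want to run, compare, or stress-test
region-based tests for quantitative traits with covariate adjustment —
including the failure modes (data-adaptive recoding and post-selection
inference) that silently inflate type I error.

## The methods

Three collapsing scores for the rare variants of a gene (dosage
`g_ij ∈ {0,1,2}`):

| score | definition |
|---|---|
| indicator | `s_i = 1{Σ_j g_ij > 0}` (carries any rare minor allele) |
| count | `s_i = Σ_j g_ij` (total rare minor alleles; ≡ the proportion method × 2m) |
| data-adaptive | count after flipping variant `j` to `2 − g_ij` when its covariate-adjusted marginal coefficient is negative with p ≤ 0.1 |

crossed with three common-variant strategies: **none** (score alone),
**CMC** (score plus *all* common variants of the region), and **LASSO**
(score plus the common variants selected by an L1 path with covariates and
score unpenalised, 10-fold CV, one-standard-error rule). Every combination
is tested with the nested-model F statistic

    F = [(RSS_reduced − RSS_full)/q] / [RSS_full/(n − p_full)],

reduced model = intercept + sex + age + smoking + population dummies, full
model = reduced + genetic terms, `q` = rank added by the genetic terms.

The evaluation layer pools null-trait p-values across genes and replicates
into an empirical null, reports type I error at the nominal level, derives
empirical significance thresholds, and measures per-gene power at those
thresholds. A Freedman–Lane permutation test (`permutation_null()`, with a
vectorised fast path `adaptive_permutation_test()`) restores calibration
for the data-adaptive score. A synthetic-data module generates exome-like
genotype panels (mostly-rare 1/f MAF spectrum, 7-population stratification,
haplotype LD), covariates and replicated traits, so the full study design
runs with no external data.

## Worked example

Simulate a small study (nine risk-gene architectures shipped as presets,
plus a null trait), run all nine method × strategy combinations at one
cutoff, and evaluate:

```r
library(rvcollapse)

cfg   <- sim_config(gaw17_gene_presets(0.01)[c("ARNT", "KDR", "VEGFC")],
                    n_replicates = 40)
study <- simulate_study(cfg, seed = 1)

null_res <- run_gene_tests(study$genotypes, study$info, study$covariates,
                           study$traits$null, cutoffs = 0.01)
alt_res  <- run_gene_tests(study$genotypes, study$info, study$covariates,
                           study$traits$associated, cutoffs = 0.01)
ev <- evaluate_study(null_res, alt_res, alpha = 0.05)
subset(ev$power, gene == "ARNT")
```

```
   gene cutoff    method strategy power
1  ARNT   0.01 indicator     none 0.400
4  ARNT   0.01 indicator      cmc 1.000
7  ARNT   0.01     count     none 0.450
10 ARNT   0.01     count      cmc 1.000
13 ARNT   0.01 indicator    lasso 0.575
16 ARNT   0.01     count    lasso 0.575
19 ARNT   0.01  adaptive     none 0.525
22 ARNT   0.01  adaptive      cmc 1.000
25 ARNT   0.01  adaptive    lasso 0.625
```

Read: for a gene whose association is partly carried by one causal common
variant (an ARNT-like architecture: 4 of 15 rare and 1 of 3 common
variants causal), the collapse-only tests find it in 40–53% of replicates;
including the common variants (CMC) saturates power, and LASSO sits in
between because its one-standard-error selection rule only retains the
causal common variant in some replicates (see the vignette's limitations
section). `power` is the fraction of trait replicates rejected at the
empirical threshold derived from the matching null-trait pool; the three
collapsing scores perform similarly because all simulated effects share
one direction.

The same pipeline is scriptable:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/rvcollapse.R", package = "rvcollapse"))')
Rscript $CLI simulate --config cfg.json --out study/ --seed 1
Rscript $CLI test --data study/ --trait null --out null.tsv
Rscript $CLI test --data study/ --trait associated --out alt.tsv
Rscript $CLI evaluate --null null.tsv --alt alt.tsv --alpha 0.05 --out report
```

## Further reading

`vignettes/methods.Rmd` documents the models, the empirical-null
machinery, the simulator's stated world and its limits, and every
numerical/design choice (boundary conventions, rank handling, permutation
scheme, λ rule).
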
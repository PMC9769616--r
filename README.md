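# qpcohort

Quasi-paired cohort construction and paired multi-omic analysis for
case–control microbiome studies.

## The problem

In case–control gut-microbiome cohorts, inter-individual variation driven by
host factors (age, glycaemia, lipids, ...) routinely swamps disease-associated
signal: conventional unpaired tests of taxon abundances can come up empty even
when real effects exist. qpcohort implements an analysis strategy that matches
each disease sample to metabolically similar controls and then differences the
shared background away with paired statistics.

The matching substrate is the **metabolic background**: the per-sample profile
of microbial metabolic-pathway relative abundances, summarized by principal
components. Because core community metabolism is functionally redundant and
comparatively stable across individuals, two samples with similar pathway
profiles share the host context that shapes their microbiomes. The pipeline:

1. **PCA** of the pathway table; retain components to cumulative explained
   variance > 0.85.
2. **Propensity score** `e(x) = P(disease | PCs)` by logistic regression.
3. **Nearest-neighbour matching** with caliper 0.25 (in SD units of the
   score) and ratio 1:2, with replacement, yielding the quasi-paired cohort.
4. **Balance diagnostics** by standardized mean difference
   `SMD = (m_d − m_c) / sqrt((s²_d + s²_c)/2)` per covariate and per PC,
   before/after matching; a caliper × ratio scan selects parameters by the
   count of variables with |SMD| < 0.1.
5. **Paired differential abundance**: prevalence filter (> 10% of samples),
   Wilcoxon signed-rank per feature over pairs, Benjamini–Hochberg FDR.
6. **Signed-NMI trend association**: per-pair change signs
   `s_i = sgn(x_disease − x_control)`; association between two features is the
   normalized mutual information `NMI = I(a; b) / sqrt(H(a) H(b))` of their
   sign vectors, in [0, 1], given a ± direction by majority trend concordance,
   with a permutation p-value (1000 permutations).
7. **Ecology**: Chao1, species-accumulation curves, Bray–Curtis, unweighted
   UniFrac, PCoA, PERMANOVA, rank-sum comparisons.
8. **Diagnosis model**: 5-fold cross-validated random forest, grid-searched
   hyperparameters, recursive feature elimination with a cumulative-AUC curve
   and ROC report.

A first-class synthetic-cohort generator plants group effects, confounding
(covariates transmitted to the pathway background, optionally masking the
planted effects from unpaired tests) and signed feature–feature trend
couplings, with a truth sheet, so every stage is testable end to end with no
external data.

## Worked example

```r
library(qpcohort)

sim <- generate_cohort(sim_config(seed = 1))   # 42 disease / 46 control
fit <- quasi_pair(sim$pathways, sim$design, caliper = 0.25, ratio = 2)
fit
#> Quasi-paired cohort
#> metabolic_background: 4 PCs retained (cumulative EV 0.858 > 0.85) of 88
#> propensity_model on 4 background PCs; score range [0.034, 0.960]
#> pair_set: 62 pairs (31 unique disease / 30 unique control); 11 disease dropped
#> caliper 0.25 (sd scale, width 0.06246), ratio 2, replacement TRUE

summary(fit)
#> Quasi-paired cohort: covariate balance
#>   variable smd_before smd_after
#> 1      age     0.7832    0.1221
#> 2      FBG     0.5896    0.1049
#> 3       TG    -0.1064    0.1009
#> 4      HDL     0.0993    0.0135
#> 5      PC1     0.2188   -0.0408
#> 6      PC2     1.0619    0.0296
#> ...
```

The cohort is confounded by design: age and fasting blood glucose differ
between groups (SMD 0.78 and 0.59) and drive the pathway background; matching
on the background brings every covariate near balance (|SMD| ≈ 0.1). The
paired test then recovers the planted taxa that unpaired testing misses:

```r
filt <- prevalence_filter(sim$taxa, min_fraction = 0.10)
diff <- differential_table(filt, fit$pairs, alpha = 0.05)
head(as.data.frame(diff)[, c(1, 2, 4, 5, 6)], 5)
#>   feature_id n_effective_pairs      p_value      q_value    direction
#> 1      sp017                61 6.435640e-07 0.0000965346   disease-up
#> 2      sp004                60 2.790588e-06 0.0002092941 disease-down
#> 3      sp002                62 5.728656e-06 0.0002864328 disease-down
#> 4      sp012                61 8.455223e-06 0.0003170709 disease-down
#> 5      sp018                61 5.256874e-05 0.0015770623 disease-down
sum(diff$significant)
#> [1] 16    # of 150 taxa; the generator planted 20
```

A planted negative taxon–metabolite trend coupling is recovered by the
signed-NMI statistic with the right sign:

```r
assoc <- associate_trends(sim$taxa[, "sp021"], sim$metabolites[, "met011"],
                          fit$pairs, n_permutations = 999, seed = 1)
as.data.frame(assoc)[, c("feature_a", "feature_b", "signed_score", "p_value")]
#>   feature_a feature_b signed_score p_value
#> 1     sp021    met011    0.1669746   0.001
```

The whole analysis — simulate, match, diversity, differential tables, trend
associations, RF-RFE classifier — runs from one call (or the thin wrapper in
`inst/scripts/pipeline.R`):

```r
run_pipeline(default_run_config(seed = 1), "results/")
```

writing plain-TSV stage outputs and a `manifest.json` with per-stage file
hashes, seeds and timings.

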
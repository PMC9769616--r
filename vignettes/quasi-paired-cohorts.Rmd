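---
title: "Quasi-paired cohorts: matching on the metabolic background and paired multi-omic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-paired cohorts: matching on the metabolic background and paired multi-omic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Case–control gut-microbiome studies are chronically confounded: inter-individual
variation driven by age, glycaemia, diet or medication can exceed the
disease-associated signal, so a conventional unpaired comparison of taxon
abundances may find nothing even when real effects exist. Matching on measured
clinical covariates helps, but covariates are incomplete summaries of the
forces that shape a microbiome.

qpcohort implements an alternative: match samples on their **metabolic
background** — the profile of microbial metabolic-pathway relative abundances.
The premise is functional redundancy: the community's core metabolic capacity
is comparatively stable across individuals and integrates the host factors
that constrain community composition, so two samples with similar pathway
profiles are "the same kind of gut" even if their taxon lists differ. Pairing
disease samples with metabolically similar controls yields a *quasi-paired
cohort* in which paired tests difference away the shared background.

## The matching model

`quasi_pair(pathways, design)` runs four steps:

1. **Background extraction.** PCA of the samples × pathways table
   (centre-only by default). The retained component count is the smallest k
   whose cumulative explained variance exceeds `ev_threshold` (default 0.85).
   Centre-only versus unit-variance scaling is exposed as `scale.`; on
   simulated cohorts the choice did not change balance outcomes measurably,
   so the simpler default stands.
2. **Propensity model.** Maximum-likelihood logistic regression of disease
   status on the retained components; each sample gets a propensity score in
   (0, 1). Under (quasi-)separation the fit falls back to a lightly
   ridge-penalised IRLS solution with a warning — scores must stay strictly
   inside (0, 1) for matching to be meaningful.
3. **Matching.** Nearest-neighbour matching with a caliper. Disease samples
   are processed in descending score order; each receives up to `ratio`
   (default 2) nearest controls whose score distance is at most
   `caliper × SD(scores)` (default caliper 0.25, the convention of standard
   matching software, which expresses calipers in SD units of the distance
   measure). Matching is **with replacement** by default: a quasi-paired
   cohort of 78 pairs containing only 28 unique controls — the arithmetic of
   the study design this package targets — is impossible without replacement.
   A logit-scale caliper (`score_transform = "logit"`) is available; the
   probability scale is the default. Ties (equal distances) break by sample
   id, so the pair list is fully deterministic.
4. **Balance diagnostics.** Standardized mean differences
   `SMD = (mean_d − mean_c)/sqrt((var_d + var_c)/2)` per clinical covariate
   and per retained PC, before matching and on the pair-weighted matched
   sample. Post-matching differences are standardized by the *unmatched*
   pooled SD (the convention of balance-assessment tooling): the matched
   sample's own variance shrinks under restriction, and standardizing by it
   would inflate the ratio and make before/after incomparable.
   `scan_match_parameters()` grids caliper × ratio and picks the candidate
   with the most variables at |SMD| < 0.1, breaking ties by smaller mean
   |SMD|, larger pair count, then smaller caliper.

## Paired differential analysis

Features are first prevalence-filtered: a feature is kept only when detected
in *strictly more than* `min_fraction` (default 0.10) of samples, so presence
in exactly 10% of samples is removal. Percentages are not renormalized after
filtering by default (`renormalize = FALSE`); renormalization is available but
changes the meaning of the remaining values.

Per feature, the paired Wilcoxon signed-rank test is applied to
disease-minus-control differences over the pair list. Zero differences are
discarded (classic Wilcoxon); Pratt's zero-rank method is available via
`zero_policy = "pratt"`. The p-value is exact (enumeration over sign
assignments) when the effective n is ≤ 12 with untied |differences|, and a
tie- and continuity-corrected normal approximation otherwise; the cutoff
balances runtime against precision and is configurable. Benjamini–Hochberg
q-values are computed per table (taxa and metabolites form separate families).
The reported effect size is the median paired log2 ratio with a pseudo-count
of half the smallest nonzero table value, which is defined in the presence of
zeros without dominating nonzero values.

**The reused-control caveat.** With-replacement matching places the same
control in several pairs. The paired tests treat pairs as independent
observations — the convention of the quasi-paired design — and
`differential_table()` surfaces the caveat via a `reused_controls` attribute.
This is not innocuous: on null simulations, ratio-2 with-replacement matching
(single controls reused up to ~8×) produced spurious BH discoveries in every
run, whereas 1:1 matching without replacement gave exact error control
(0/50 null runs with any q < 0.05). When error control matters more than pair
count, match with `ratio = 1, replacement = FALSE`.

## The signed-NMI trend association

For two features measured over the same pair list, each pair contributes a
trend sign per feature: sign(disease − control), with |difference| ≤
`tie_epsilon` (default 0) mapped to 0. The association between two sign
vectors is their normalized mutual information:

* MI is computed from the empirical joint contingency of sign categories,
  with natural-log entropies; zeros form a genuine third category by default
  (no tie rule is imposed on the data; a drop-zeros variant exists).
* Normalization is MI / sqrt(H(a)·H(b)) (geometric-mean normalization, the
  common "NMI" convention); an arithmetic-mean variant is available and the
  choice is recorded in the output. Both bound the score to [0, 1].
* A constant vector has zero entropy; its score is defined as 0 and flagged
  degenerate rather than producing 0/0.

NMI is sign-blind, so direction is reported separately: +1 if at least as
many pairs move concordantly as discordantly (zero-containing pairs do not
vote), −1 otherwise, and the signed score is direction × NMI. At an exact
concordance tie both orientations report +1; the sign is then arbitrary and
the NMI itself is typically near 0.

The p-value permutes the entries of one vector (breaking the pair
correspondence), recomputing NMI each time, with the add-one estimator
`(#{NMI_perm ≥ NMI_obs} + 1)/(B + 1)` and B = 1000 by default. The test is
one-sided in NMI — large NMI means association, direction is not part of the
statistic. Which vector is permuted and the tail convention are recorded in
output metadata. Under the null this p-value is uniform for three-category
sign vectors and super-uniform (conservative, never anti-conservative) for
the more discrete purely-binary case. Heatmap significance marks use raw p
at 0.05/0.01 by default, matching association-heatmap practice; a BH layer
across the matrix is available (`fdr = TRUE`) but off by default.

## Diversity statistics

* **Chao1** requires count-like input; `to_pseudocounts()` makes the
  conversion from relative abundances explicit (scale to a depth, default
  1e5, then round) rather than silent. Bias-corrected
  `S + F1(F1−1)/(2(F2+1))` is the default; the classic `S + F1²/(2F2)` form
  falls back to `F1(F1−1)/2` when F2 = 0.
* **Bray–Curtis** distances; a pair of all-zero samples is defined as
  distance 0 with a warning.
* **Unweighted UniFrac**: unique / union branch length over the edges leading
  to either community's leaves; a root edge above a degree-2 root is ignored.
* **PCoA** by classical scaling; negative eigenvalues are clamped to zero in
  the explained-proportion denominator and their count reported.
* **PERMANOVA**: one-way pseudo-F from total versus within-group sums of
  squared distances; p by label permutation with the add-one formula, or
  exact enumeration of all distinct assignments in exhaustive mode.
* **Rank-sum test** (two-sided Wilcoxon) for alpha-diversity and
  distance-distribution comparisons: exact by enumeration when n ≤ 12 without
  ties, otherwise normal approximation with tie and continuity corrections.
  Both the axis-coordinate and the distance-distribution uses are supported;
  neither is asserted as canonical.

## Random-forest discrimination

`cv_auc()` evaluates stratified 5-fold cross-validated AUC;
`grid_search()` exhaustively evaluates a small hyperparameter grid (trees
{100, 500} × depth {unlimited, 5} × min leaf {1, 5} by default; small by
design so desk-scale runs are deterministic and fast), breaking ties toward
the simpler model. `rfe_select()` drops the least-important feature
(impurity importance averaged over folds) one at a time, records mean CV AUC
at each feature count, and selects the count maximizing AUC with ties toward
fewer features.

Classification always uses unique samples with their group labels, never the
pair-expanded cohort: duplicated controls would leak across CV folds and
inflate AUC. All stochastic components (fold split, forests) derive from one
run seed through named substreams.

## What the simulator emulates — and what it does not

`generate_cohort()` produces a cohort of 42 disease / 46 control samples
with taxon, pathway and metabolite tables plus clinical covariates, and a
truth sheet recording everything planted. Design choices:

* **Latent scale.** Log-normal latent abundances (not Dirichlet), so planted
  multiplicative effects have interpretable log-fold sizes; compositional
  closure to percent rows is applied last. Zero inflation (default 0.1 for
  taxa) is applied before closure; an all-zero row is redrawn up to 100
  times. Pathways get near-zero dropout (0.02) and a small residual log-SD
  (0.2 versus 1.0 for taxa) — the functional-redundancy premise that pathway
  profiles are stable across individuals is exactly what makes them usable
  as a matching substrate, and the simulator encodes it.
* **Confounding.** Covariates (age and FBG imbalanced by default, TG and HDL
  balanced) drive latent factors that load on blocks of pathways. A factor
  loading on *every* pathway would be annihilated by closure — only
  between-block contrasts survive — so each factor loads on its own block
  with the remainder unloaded.
* **Masking.** By default (`taxa_confounding = "mask"`), every planted taxon
  effect is coupled to the pathway-coupled covariates, in the proportions in
  which those covariates drive the background, scaled so that the expected
  between-group contribution exactly cancels the planted effect. Unpaired
  tests then see no group difference, while matching on the background
  aligns exactly this covariate combination within pairs and the paired test
  recovers the effect — the computational restatement of "no significant
  differences by conventional analysis, clear differences after matching".
* **Trend couplings.** A shared per-sample standard-normal latent enters
  both coupled features' log-abundances with weight `strength`, with each
  feature's own noise scaled by sqrt(1 − strength²). This variance-preserving
  parameterisation makes `strength` behave like a correlation weight; a
  purely additive shared term (same strength added on top of full noise)
  yields trend-sign agreement too weak to be detectable at the default
  strength (0.9) and cohort size, which would make the statistic look worse
  than it is.
* **Effect sizes** (default |log2 FC| = 1.5 on 20 taxa and 10 metabolites)
  are chosen for testability, not biological realism, and should be treated
  as such.

Not emulated: read-level sequencing noise, phylogenetic signal in abundances
(the random tree is an independent fixture), gene-level functional tables,
mass-spectral artefacts, covariate measurement error. Passing the simulated
recovery suites therefore demonstrates that the statistical machinery behaves
as designed under its own assumptions — not that those assumptions hold in
any particular real cohort.

## Numerical conventions

* All permutation p-values use the add-one estimator, which cannot return 0
  and is never anti-conservative in expectation.
* Exact-test cutoffs (n ≤ 12, no ties) for signed-rank and rank-sum are
  configurable; above them the normal approximation with tie/continuity
  corrections is used.
* Deterministic orderings everywhere: matching processes disease samples in
  descending score order with lexicographic tie-breaks; differential tables
  sort by (q, feature id); grid search and RFE break ties toward the simpler
  model / fewer features.
* Degenerate inputs are defined, flagged outcomes, not errors: zero-entropy
  sign vectors (NMI 0, p 1), zero margins in 2×2 tables (p 1), zero pooled
  variance with nonzero mean difference (SMD ±Inf with warning), zero
  effective pairs (p 1, flagged).
* Every stochastic component flows from a single seed through named
  substreams (`stream_seed`), so adding a stage or table does not perturb
  the draws of the others.

## Problem sizes used by the test suite

The packaged tests run the full chain at the cohort's native size (88
samples, 150 taxa, 120 pathways, 80 metabolites) for single-fit checks, and
scale the replicated studies to what a laptop runs in minutes: 20-seed
recovery ladders, 50-seed null-FDR studies at 500 taxa, 200-replicate
calibration studies with 99–199 permutations, and the end-to-end pipeline at
full default settings. These sizes are the package's own choices for a
routine-verification suite; all of them can be raised by editing one
constant in the corresponding test.

## Limitations

* PSM balances covariates in expectation, per-pair alignment is approximate;
  a noisy propensity model can leave residual imbalance, and the balance
  report — not the pair count — is the arbiter of matching quality.
* With-replacement pairs are not independent; see the reused-control caveat
  above. No correction for control reuse is invented, because none is
  established for this design; the caveat is surfaced instead.
* NMI on sign vectors discards magnitude information by construction; it
  detects trend-direction association, not dose-response.
* The enrichment module runs only against user-supplied annotation maps; no
  database connectivity is provided, by design.
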
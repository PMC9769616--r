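Package: qpcohort
Title: Quasi-Paired Cohort Construction and Paired Multi-Omic Analysis for
    Case-Control Microbiome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs quasi-paired case-control cohorts by propensity-score
    matching on the microbial metabolic background (principal components of
    functional-pathway profiles), with calipered ratio-k nearest-neighbour
    matching and standardized-mean-difference balance diagnostics. Provides
    paired differential-abundance testing (Wilcoxon signed-rank with
    Benjamini-Hochberg FDR), a signed normalized-mutual-information statistic
    for paired change-trend association with a permutation null, annotation-set
    enrichment (hypergeometric and one-sided Fisher tests), ecological
    diversity statistics (Chao1, species accumulation, Bray-Curtis, unweighted
    UniFrac, PCoA, PERMANOVA), cross-validated random-forest discrimination
    with recursive feature elimination, and a compositional synthetic-cohort
    simulator with planted effects, confounding and trend couplings for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    ape,
    vegan,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
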
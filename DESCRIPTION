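Package: micromet
Title: Microbiome-Metabolome Multi-Omics Association Analysis for Staged
    Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for cohorts stratified into
    ordered disease stages (e.g. healthy control, stable coronary artery
    disease, myocardial infarction) profiled by shotgun metagenomics and
    untargeted serum metabolomics. Provides differential-abundance screening
    of microbial species with fold-change gates, KEGG-module reporter scoring
    from per-KO rank tests with a size-matched random background, alpha
    diversity and Bray-Curtis ordination (PCoA, dbRDA, perMANOVA),
    co-abundance metabotype clustering (soft-threshold signed adjacency,
    topological overlap, average-linkage dendrogram with a dynamic height
    cut), tiered-FDR multi-omics Spearman association grids against clinical
    phenotypes, automated baseline-characteristics tables, and a synthetic
    cohort generator with planted, recoverable ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
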
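Package: kinscape
Title: Nested-Scale Biogeography of Genetic and Social Relatedness in
    Social Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the spatial structure of genetic and
    social (kin-discrimination) relatedness in hierarchically sampled
    microbial populations. Parses nested isolate identifiers
    (site/transect/core/fruiting-body/clone), builds multilocus sequence
    concatemers and sequence types from per-locus alignments, computes
    nucleotide diversity and pairwise genetic distances, draws fully
    independent isolate pairs per spatial scale by constrained
    resampling, scores colony-interface kin-discrimination assays by
    observer majority, estimates identity-decay curves with one-way
    ANOVA and Tukey HSD contrasts, and runs spatial-structure tests
    (Mantel permutation, exact binomial clade-distribution tests,
    nearest-sequence-type site concordance, within- versus among-site
    Wilcoxon comparisons). A hierarchical landscape simulator generates
    complete synthetic inputs with the statistical structure the
    analysis assumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
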
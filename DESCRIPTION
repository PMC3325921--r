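Package: gtxscore
Title: Weighted Scoring of Genotoxic Stress Responsive Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering genotoxin-specific responsive
    genes from multi-chemical, multi-timepoint liver expression studies. The
    core is a weighted multi-parameter score that combines, per gene, the
    specificity of its up-regulation for genotoxins, its average induction
    ratio, the number of positive conditions and chemicals, a genotoxin versus
    non-genotoxin t-test, basal expression, directional consistency and the
    coefficient of variation among control animals. The package also provides
    intensity-dependent up/down regulation calling, average-linkage
    hierarchical clustering of top-ranked genes, a seedable synthetic-data
    generator emulating the pooled-sample study design, and the closed-form
    assay statistics used to validate candidate biomarkers (2^-ddCt relative
    quantification, comet-assay olive tail moment, dose-response regression,
    micronucleus frequency).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
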
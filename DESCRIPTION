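Package: tissuemod
Title: Tissue-Specific Co-Expression Modules and Gene Prioritisation for
    Multi-Tissue Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative workflow for locating tissue-specific gene
    expression programmes in multi-cohort case/control transcriptomics, as
    used in mood-disorder studies spanning brain regions and blood. Provides
    per-dataset linear-model differential expression with demographic
    confounder screening, empirical-Bayes location/scale batch harmonisation
    of same-tissue datasets, weighted gene co-expression networks
    (soft-threshold scan, topological overlap, module detection, eigengenes,
    kME and gene significance), cross-disease consensus via quantile-scaled
    topological overlap and sign-consistent module-tissue correlation
    merging, robust rank aggregation of differential-expression rankings
    with beta order statistics, window-based variant-to-gene mapping, and
    the final tissue-specific gene calls with hypergeometric
    over-representation analysis. A seeded synthetic-data generator with
    planted modules, batch effects and confounder genes makes every stage
    verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    sva
Config/testthat/edition: 3
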
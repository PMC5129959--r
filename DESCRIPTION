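Package: ceRNAspread
Title: Small RNA and ceRNA Network Analysis of Peritoneal Tumor Spread Types
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for comparing miliary and non-miliary
    peritoneal tumor spread types in high grade serous ovarian cancer from
    matched small RNA and rRNA-depleted RNA sequencing data. Implements
    count normalization (log-CPM and cyclic loess), confounder-adjusted
    per-feature differential expression, a combined gene-miR set analysis
    that assigns miRNA regulators to gene sets by one-sided Fisher's exact
    tests and scores joint deregulation with a competitive permutation
    test, global competing endogenous RNA (ceRNA) network statistics
    including a circRNA back-splice index, a 13 small RNA spread-type
    predictor based on a difference of median expressions, and Cox
    proportional-hazards transfer validation of prognostic risk models.
    A synthetic cohort generator with planted effects makes every stage
    testable without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    survival,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneSetEnrichment, Normalization, Survival
RoxygenNote: 7.3.3
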
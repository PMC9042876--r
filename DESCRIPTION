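Package: mirdrugscreen
Title: Drug-Specific miRNA Survival Biomarker Screening
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Discovery and validation of miRNA survival biomarkers that are
    specific to a cancer type and a drug treatment. Stratifies a pan-cancer
    cohort into cancer-drug groups, binarizes log-scale expression with a
    global least-squares step-function fit, screens features by Kaplan-Meier
    / log-rank testing with Benjamini-Hochberg false-discovery control,
    contrasts group-level against cancer-wide significance to flag
    drug-specific markers, screens miRNA target genes, classifies
    miRNA-target survival-direction concordance, and validates markers in
    external cohorts by median split. Ships a synthetic cohort generator
    with planted markers so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    survival,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
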
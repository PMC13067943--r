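Package: ctcDLL3
Title: CTC-Based DLL3 Scoring and Response Stratification for Small Cell
    Lung Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for scoring DLL3 expression on circulating tumor cells
    (CTCs) in small cell lung cancer and relating it to treatment response.
    Implements per-cell immunofluorescence gating of CTC-enriched feature
    tables into CTC classes, leukocytes and tumor fragments; enumeration
    normalized to a reference blood volume; patient-level DLL3-fraction
    stratification with exact (Clopper-Pearson) binomial predictive metrics;
    rank-based single-cell subtype signature scoring; simplified
    genome-ordered copy-number inference for tumor-cell calling; epitope
    positivity and coexpression accounting; and synthetic-data generators
    with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
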
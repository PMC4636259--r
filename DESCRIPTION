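Package: methoutlier
Title: Outlier-Based DNA Methylation Biomarker Discovery and Diagnostic
    Evaluation
Version: 0.1.0
Authors@R:
    person("Methoutlier", "Developers", email = "methoutlier@example.org",
           role = c("aut", "cre"))
Description: Rank-sum outlier screening of tumor versus normal DNA
    methylation beta-values with a minimum-change floor, integration
    filtering by methylation-expression anti-correlation, and diagnostic
    evaluation of quantitative methylation-specific PCR (QMSP) biomarker
    panels: sensitivity and specificity with exact binomial confidence
    intervals, two-sided Fisher exact tests, Cohen's kappa concordance and
    percent agreement. Includes a seeded synthetic cohort generator that
    emulates the heterogeneous-outlier structure of head and neck squamous
    cell carcinoma methylation data, and a pipeline driver that runs
    simulate, screen, integrate and evaluate stages end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
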
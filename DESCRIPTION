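Package: teloscore
Title: Weighted Genetic Telomere-Length Score and Case-Control Association Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the weighted 11-SNP genetic score for leukocyte telomere
    length (the "teloscore") and runs the accompanying case-control analysis
    pipeline: genotype quality control (call-rate filtering, exact
    Hardy-Weinberg testing in controls, minor allele frequencies, duplicate
    concordance), raw and call-rate-scaled score computation, control-derived
    quintile binning, covariate-adjusted logistic regression under quintile,
    allelic, codominant, dominant and recessive genetic models with Bonferroni
    thresholding and strata, and a seeded cohort simulator with injectable
    quintile-level or per-SNP effects so every stage is verifiable without
    individual-level study data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
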
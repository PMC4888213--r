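Package: oncointerp
Title: Integrative Interpretation of Tumor Genomic Profiles for Personalized Cancer Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns per-patient somatic and germline variant calls, copy-number
    segments, and gene-expression tables into tiered mutation lists,
    evidence-ranked drug response, toxicity and prognosis predictions,
    actionable-alteration counts, in-silico cancer-panel comparisons, cohort
    mutation statistics, and structured per-patient findings documents. Ships a
    synthetic mini knowledge base and seeded cohort generators so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
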
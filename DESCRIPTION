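Package: patentscape
Title: Disease Coverage, Research Opportunity Indices, and Topic Dynamics in Patent Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis pipeline for mining biomedical patent corpora across
    the disease landscape. Filters patent documents to biomedicine by grant
    date and USPC/CPC classification codes, recognizes disease concepts with
    a dictionary longest-match recognizer and rolls them up to root PheCodes
    through CUI to ICD-9-CM mapping tables, computes per-year disease
    coverage, derives the Research Opportunity Index (ROI) and Public Health
    Index (PHI) from normalized disease-level measures of burden and research
    resources, audits multicollinearity with variance inflation factors, and
    fits a dynamic topic model with Gaussian-chained topic parameters and
    UMass-coherence topic-number selection. Ships a synthetic-data generator
    with planted ground truth so every stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    Matrix,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
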
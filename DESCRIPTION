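Package: druglabel
Title: Multi-Source Drug Labeling Extraction and Food-Effect Paragraph
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating FDA drug product labeling from
    heterogeneous public sources: parsers for HL7 Structured Product
    Labeling (SPL) XML keyed by LOINC section codes, DrugBank-style XML
    datafiles, and plain-text labels converted from PDF; identifier
    unification to six-digit FDA application numbers; latest-version
    filtering against an Orange Book reference list; per-source coverage
    and overlap statistics; and a food-effect paragraph classification
    workbench with regex annotation rules, rule-based baselines, TF-IDF
    features, classical classifiers, cross-source evaluation grids and
    learning curves. A deterministic synthetic-corpus generator emulates
    all source formats so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    ranger,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
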
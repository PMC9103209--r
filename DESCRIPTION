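Package: oncomir
Title: Circulating OncomiR Index Analysis for CNS Lymphoma Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for circulating oncogenic microRNAs (oncomiRs)
    measured by qPCR in cerebrospinal fluid and plasma of aggressive B-cell
    non-Hodgkin lymphoma patients. Converts raw Ct values to let-7a-normalized,
    control-equalized relative expression (2^-dCt), combines the five-oncomiR
    panel (miR-21, miR-19a, miR-20a, miR-92a, miR-155) into a weighted logistic
    "oncomiR index" for detecting secondary CNS involvement, selects decision
    thresholds on ROC curves (closest-to-corner and Youden rules), compares
    groups nonparametrically (Mann-Whitney, Kruskal-Wallis with Dunn post hoc),
    and stratifies CNS-relapse and overall-survival risk (Kaplan-Meier,
    log-rank, Cox). Includes a synthetic-cohort generator emulating the
    statistical structure of such liquid-biopsy studies, so the full pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0),
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
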
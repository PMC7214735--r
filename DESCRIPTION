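Package: eparmeta
Title: Meta-Assessment of the Evidence Base Behind Drug Approval Dossiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for appraising the clinical evidence summarised in drug
    approval dossiers such as the European Public Assessment Reports (EPARs).
    Heterogeneously reported trial results are converted to standardized mean
    differences (Cohen's d) through a three-tier derivation cascade (full arm
    statistics, arm contrasts, p-values with group sizes), pooled per drug and
    daily dose with a DerSimonian-Laird random-effects meta-analysis, and each
    approval's evidence is graded against an explicit rubric (robust, single,
    none, not required) per comparator class. Includes a synthetic
    trial-corpus generator with configurable between-trial heterogeneity and
    stochastic censoring of reporting completeness, corpus readers/writers
    (CSV bundle and JSON), descriptive summaries, heatmap and
    effect-size-versus-p scatter exports, and a small command-line interface.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
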
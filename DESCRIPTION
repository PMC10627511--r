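Package: ctdnamark
Title: Circulating Tumor DNA Biomarkers and Survival Stratification for
    Liquid-Biopsy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-sample circulating tumor DNA (ctDNA) biomarkers
    from gene-level somatic variant call tables (maximum variant allele
    frequency, ctDNA fraction, mutant-allele tumor heterogeneity score,
    tumor mutational burden, gene-level copy-number state), screens mutated
    genes for prognostic relevance by univariate Cox regression, classifies
    samples as ctDNA-positive or -negative against the resulting panel,
    dichotomizes continuous markers at maximally selected log-rank
    cut-points, and runs the downstream Kaplan-Meier, multivariable Cox,
    response-group and longitudinal-monitoring analyses. A synthetic-cohort
    generator reproduces the statistical structure these analyses assume
    (proportional-hazards gene effects, ordinal treatment response coupled
    to ctDNA burden, three-timepoint plasma sampling, paired tumor-tissue
    profiles), so the full pipeline is testable without access to patient
    data.
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
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
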
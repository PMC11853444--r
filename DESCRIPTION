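Package: cfmrd
Title: Cell-Free DNA Residual Disease and Donor Chimerism Monitoring
    After Allogeneic Transplant
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal surveillance of myeloid malignancies
    after allogeneic stem-cell transplantation using plasma cell-free DNA
    (cfDNA) panel sequencing. Implements geometric-mean variant-allele-
    frequency (VAF) tracking of measurable residual disease, donor
    chimerism estimation from informative SNP allele fractions via a
    median mixture-deconvolution rule, clearance/persistence
    classification of adverse-risk somatic mutations with relapse
    contingency summaries, the accompanying nonparametric cohort
    statistics, a fully seeded synthetic-cohort simulator with ground
    truth for recovery testing, and a packaged 20-subject transplant
    cohort so every analysis runs without external data.
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
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
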
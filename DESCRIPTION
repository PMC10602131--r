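Package: mrgxe
Title: Gene-Environment Interaction Screening from GWAS and GWIS Summary
    Statistics via Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens the genome for gene-environment (GxE) interaction and
    mediation using only summary statistics. Marginal effects from a
    genome-wide association study (GWAS) and main/interaction effects from a
    genome-wide interaction study (GWIS) are harmonized, a bridging
    coefficient between main and marginal effects is estimated by
    inverse-variance-weighted Mendelian randomization with iterative
    pleiotropy removal, and each variant is tested for departure from the
    bridging line (a chi-square screen for combined interaction and
    mediation). A two-step procedure follows the screen with the direct
    interaction test under a reduced multiple-testing burden. Includes
    summary-statistics quality control, LD-score regression for the
    heritability contributed by interaction and mediation, and simulators
    for calibration, power, and estimator-bias studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
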
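Package: gpsim
Title: Simulating Genomic Prediction Accuracy in Doubled-Haploid Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of barley-like doubled-haploid (DH) breeding
    populations and their evaluation in virtual field trials. Builds synthetic
    genetic maps and founder panels, simulates meiosis under the Haldane model
    for factorial and diallel mating designs, assigns additive marker effects
    calibrated to a target genetic variance, masks genotypic values with
    cross-by-environment, line-by-environment and residual noise scaled by the
    trial design, and estimates genome-wide marker effects from the simulated
    phenotypes by RR-BLUP (ridge-regression BLUP) with REML variance
    components. The central question the package addresses is whether genomic
    predictions y of field-tested lines recover true genotypic values g better
    than the phenotypes p themselves, quantified by replicated Monte-Carlo
    estimates of the correlations r(p,g), r(y,p) and r(y,g), plus a
    Pearson-Filon z-test for comparing two dependent overlapping correlations.
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
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
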
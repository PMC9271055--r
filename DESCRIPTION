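Package: vqtlewis
Title: Two-Stage Discovery of Gene-Environment Interactions via
    Variance-QTL Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a two-stage screening strategy for discovering
    gene-environment interactions (GEI) affecting quantitative traits.
    Stage one scans the genome for variance-quantitative trait loci
    (vQTLs) with the median-based Levene (Brown-Forsythe) test, meta-
    analyses ancestry strata with Stouffer's sample-size-weighted method,
    and collapses signals to index variants by distance-based pruning.
    Stage two tests prioritized variant-biomarker pairs against a panel
    of exposures with robust (sandwich) interaction regression, inverse-
    variance-weighted meta-analysis, conditional scans to count
    independent interaction signals, and enrichment statistics. Includes
    biomarker and exposure pre-processing (log transform, statin
    adjustment, residualization, outlier masking, rank-based inverse
    normal transformation, effective-test counting), PLINK1 and VCF
    genotype input with hard-calling and MAF filtering, and a synthetic
    study generator with retained ground truth for power and calibration
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
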
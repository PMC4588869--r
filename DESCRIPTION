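Package: dmrscreen
Title: Differentially Methylated Region Screening for Methylation-Enrichment Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline from promoter tiling-array methylation-enrichment
    signals to differentially methylated regions of interest (DMROIs) and to
    covariate-adjusted associations between CpG methylation and
    neurodevelopmental outcomes. Includes a grid-posterior estimator of
    per-100-nt percent methylation from probe log2 ratios and CpG density
    (a simplified BATMAN-style step), a four-part composite DMR screen across
    ordinal phenotype groups (heteroscedasticity-robust trend test, exact
    Mann-Whitney cascade, methylation odds ratio, absolute-difference filter),
    hypergeometric region-of-interest enrichment with gene-set analysis
    against the array background, Fisher-Yates normal-score association
    models reporting effect per SD methylation, and a synthetic-cohort
    generator with planted truth for calibration and power testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    fgsea,
    sandwich,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
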
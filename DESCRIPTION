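Package: prstail
Title: Simulating False-Positive Inflation in GWAS of Polygenic-Score-Derived Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of case-control cohorts under the liability
    threshold model, a pruning-and-thresholding polygenic risk score (PRS)
    pipeline, and a replicated experiment quantifying type-I error inflation
    when a genome-wide association study is run on an extreme-tail phenotype
    derived from the PRS itself. Includes a Dudbridge-style analytic model of
    expected PRS accuracy used to solve discovery-cohort sample sizes, a
    block-streamed allele-dosage trend-test association engine, stratified
    false-positive-rate metrics across discovery/target sample-overlap designs,
    and plain-text writers for all results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
Config/testthat/edition: 3
RoxygenNote: 7.3.3
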
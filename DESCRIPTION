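Package: slicequant
Title: Quantitative Drug-Response Analysis for Organotypic Tumor Tissue Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies drug response in ex vivo organotypic tissue-slice
    experiments from whole-slide annotation measurements. Computes per-slice
    histomorphological readouts (percentage of viable versus damaged cancer
    cell outgrowth, outgrowth length as a fraction of the slice perimeter,
    and a weighted tumor viability index), averages duplicate slices,
    assembles culture-by-condition cohort matrices, maps damage to Evans
    tumor regression grades, and performs paired small-sample nonparametric
    inference (exact Wilcoxon signed-rank by full enumeration,
    Benjamini-Hochberg adjustment, Friedman test with Kendall's W effect
    size). Includes a two-stage significance filter for differential
    expression result tables and a synthetic-cohort generator with an
    Emax/Hill dose-response model for testing the full pipeline without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
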
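Package: reprogR
Title: Fold-Change Distribution Thresholding and Immune Gene Panel
    Reprogramming for Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies genes from bulk RNA-seq contrasts as increased,
    decreased or unchanged by fitting a Gaussian or Lorentzian peak to the
    floor-binned histogram of log2 fold changes and thresholding at the fitted
    center plus or minus the fitted width. Includes a self-contained
    negative-binomial differential-expression core (median-of-ratios size
    factors, method-of-moments dispersion, Wald test with small-sample
    calibration, Benjamini-Hochberg adjustment), mapping of a human
    immunodeficiency (inborn errors of immunity) gene panel to mouse ortholog
    symbols, quantification of treatment-induced reprogramming (enhanced or
    suppressed) between a sepsis contrast and a sepsis-plus-treatment contrast,
    and a negative-binomial count simulator with known truth for end-to-end
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
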
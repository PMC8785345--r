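Package: basalopt
Title: Model-Based Titration of Long-Acting Insulin from CGM and Smart-Pen Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for run-to-run titration of long-acting (basal) insulin in
    type 1 diabetes managed with multiple daily injections. Implements a
    linearized subcutaneous oral glucose minimal model augmented with a
    long-acting insulin absorption channel, maximum-a-posteriori
    individualization of insulin sensitivity and meal-absorption parameters
    from continuous glucose monitoring (CGM) and smart-pen dose logs,
    regularized deconvolution of the residual metabolic signal,
    risk-weighted grid-search optimization of the basal dose with a night
    hypoglycemia penalty, and a saturated/dead-zoned dose update rule. Two
    SMBG-based comparator algorithms (control-to-range and iterative
    learning control-to-reference) and an in-silico trial framework with a
    synthetic virtual cohort, behavioural scenarios and glycemic outcome
    reporting are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
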
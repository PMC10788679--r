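Package: hapdose
Title: Decomposition of Genotype Imputation Quality Metrics with a
    Li-Stephens Imputation Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study why the model-based genotype imputation quality
    metric Rsq (the ratio of imputed-dosage variance to the binomial variance
    p(1-p)) deviates from the empirical dosage r-squared (squared correlation
    between imputed dosage and true genotype).  Implements the exact variance
    decomposition Rsq = EmpRsq * Rsq + MARE with beta_imp = sqrt(EmpRsq * Rsq),
    a minimal Li-Stephens haplotype-copying hidden Markov model with explicit
    template switching rates (theta) and error rates (epsilon), leave-one-out
    dosage evaluation, EM estimation of the HMM parameters from a reference
    panel, conversion of genetic-map distances to switching rates, a
    Balding-Nichols multi-ancestry reference-panel simulator, and experiment
    drivers reproducing the theta-scaling and panel-composition analyses on
    simulated data.  Phased reference panels, targets and imputed dosages are
    exchanged as VCF with GT, DS and HDS fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    vcfR,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
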
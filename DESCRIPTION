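Package: cephsal
Title: Saliency-Based Quantification of Craniofacial Growth from
    Cephalogram Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An annotation-free framework for quantifying craniofacial
    growth patterns and sexual dimorphism from lateral-cephalogram-like
    images. Convolutional networks are trained on the proxy tasks of age
    estimation (L1 loss) and sex classification (softmax cross-entropy);
    gradient-weighted class activation mapping extracts per-subject
    saliency, which is aggregated into population-average maps and
    summarized by two regional statistics, the age-related and sex-related
    saliency indices (mean supra-threshold saliency within consensus
    anatomical region masks at the group 75th percentile). A synthetic
    cephalogram phantom generator with planted, recoverable growth and
    dimorphism structure provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
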
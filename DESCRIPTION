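Package: mmgp
Title: Multi-Modal Genomic Prediction for Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction for multi-environment plant-breeding trials with
    two model families sharing one data pipeline: a Bayesian GBLUP linear mixed
    model (environment fixed effects, line and line-by-environment random effects
    with covariances proportional to the genomic relationship matrix G and to
    I x G, fitted by Gibbs sampling with scaled-inverse-chi-squared variance
    priors) and a multi-modal deep-learning regressor whose modalities are the
    environment design, the Cholesky-encoded genomic features Z_L L_G and the
    interaction features Z_EL L_EG, each passed through its own residual MLP
    before late fusion. Includes the genotype QC pipeline (MAF and missingness
    filters, TASSEL numeric recoding, mean imputation), Gaussian-process
    Bayesian hyperparameter optimization, k-fold and leave-one-environment-out
    evaluation protocols with NRMSE and Pearson correlation, model-comparison
    reporting, and a synthetic multi-environment-trial generator so the whole
    stack is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
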
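Package: ehrmisclass
Title: Misclassification-Adjusted Bayesian Logistic Regression for EHR Diagnosis Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying and correcting the attenuation of association
    estimates caused by under-recorded diagnoses in electronic health record
    (EHR) data. Provides exact conditional-probability algebra for two- and
    three-condition misclassification scenarios, a synthetic EHR cohort
    simulator with a hidden true-status layer and a recorded-diagnosis layer,
    naive maximum-likelihood logistic regression, and a Bayesian logistic
    regression in which recording sensitivity and false-positive rates enter
    as priors and the latent true statuses are marginalized analytically.
    Includes a simulation-grid harness for parameter-recovery studies, a
    Gibbs-within-Metropolis sampler for multivariable case-control analyses,
    AUROC scoring, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    rjags
Config/testthat/edition: 3
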
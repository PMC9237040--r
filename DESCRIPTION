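Package: cryptophen
Title: Cryptic Phenotype Analysis for Binary Symptom Matrices
Version: 0.1.0
Authors@R:
    person("CPA", "Maintainers", email = "maintainers@cryptophen.org",
           role = c("aut", "cre"))
Description: Infers quantitative latent traits ("cryptic phenotypes") that
    summarize the severity of Mendelian-disease-related symptom spectra from
    sparse binary patient-by-diagnosis-code matrices. Provides utilities to
    build, translate and split binary symptom matrices from coded clinical
    records; a Bernoulli latent-factor generative model with exact quadrature
    oracles at low rank; an amortized variational inference engine with
    automatic-relevance column pruning and effective-rank estimation;
    cryptic-component selection with average-precision ranking and
    bootstrap severity testing; regression-based genetic validation
    (carrier effects, annotation-flag decomposition, polygenic-score
    interactions); and a fully synthetic cohort simulator with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
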
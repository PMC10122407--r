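Package: twinliab
Title: Liability-Threshold Twin Models for Binary Comorbid Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classical twin-design analysis of binary phenotypes under the
    liability-threshold model: tetrachoric correlations estimated by maximum
    likelihood, univariate ACE/AE/E variance-component fits with
    likelihood-ratio comparison and profile-likelihood intervals, bivariate
    Cholesky/correlated-factors models yielding genetic and environmental
    correlations and bivariate heritability, cluster-robust logistic
    association tables, proband-wise cross-concordances, and a reproducible
    synthetic-cohort generator for monozygotic and same-sex dizygotic twin
    pairs with parent-interview (A-TAC) item emission for subclinical
    autism and ADHD phenotyping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm,
    sandwich,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
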
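Package: mfclass
Title: Multifactorial Likelihood Classification of BRCA1/2 Sequence Variants
Version: 0.1.0
Authors@R:
    person("mfclass", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative classification of BRCA1 and BRCA2 sequence variants
    with the multifactorial likelihood model: a bioinformatic prior probability
    of pathogenicity is combined with multiplicative likelihood ratios from
    co-segregation, breast tumour pathology, co-occurrence in trans with a
    pathogenic variant, reported family history and case-control data, and the
    Bayes posterior is mapped to the IARC five-tier class. Includes an
    Elston-Stewart pedigree likelihood for the co-segregation Bayes factor
    under an age-bracket penetrance hazard model, calibration of qualitative
    evidence types from classified-variant cross-tabulations (likelihood
    ratios with log-scale Wald confidence intervals mapped to ACMG/AMP
    evidence strengths), gnomAD-style population-frequency categorisation,
    and seed-deterministic synthetic-data generators so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
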
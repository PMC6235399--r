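Package: SAME
Title: Somatic Mutation Association Tests with Measurement Errors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Likelihood-ratio association tests between continuous or binary
    outcomes and somatic mutations that account for mutation-calling errors.
    True mutation status is treated as a latent variable; allele-specific read
    counts are modeled with beta-binomial distributions and mutation calls with
    a Bernoulli error model indexed by per-mutation sensitivity and
    specificity. Provides mutation-level (mSAME) and gene-level collapsed
    (gSAME) tests fitted by an EM algorithm, a naive generalized-linear-model
    comparator, plug-in estimation of the read-count model components, and a
    synthetic-data generator with a type-I-error/power experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
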
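Package: dyadsignal
Title: Multi-Component Signal Integration Analysis for Staged Dyadic Contests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-component signalling in staged
    male-male contests of colour-changing lizards. Computes
    receptor-noise-limited (RNL) chromatic contrasts in just-noticeable
    differences (JND) against a grey reference, assembles per-individual
    trait matrices under explicit exclusion rules, runs normality-gated
    univariate comparisons, extracts composite signalling traits by
    principal component analysis with a dyad-aware one-individual-per-pair
    bootstrap, fits hormone-signal regressions with subsampled confidence
    intervals, and tests opponent trait-matching against a permutation
    null of random re-pairings. Includes a fully seeded synthetic
    dyadic-study generator with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
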
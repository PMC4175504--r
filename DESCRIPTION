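Package: domdiff
Title: Length Variation and Membership Tracking Across Protein Domain
    Superfamily Database Updates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify domain-length variation within protein domain
    superfamilies, classify superfamilies as length-deviant, length-rigid or
    length-normal under an old majority scheme and an improved
    sparse-population-aware scheme, diff two releases of a superfamily
    alignment database at superfamily and member level (splits, merges,
    supersession by better-resolution structures, and a staged rescue cascade
    for missing members based on global sequence identity), and score
    structure-based multiple alignments via gapless-column equivalences and
    Kabsch superposition RMSD.  Includes a synthetic database generator with
    ground-truth records so every analysis step can be exercised and validated
    without access to the original releases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
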
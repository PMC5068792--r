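Package: nestgrad
Title: Nestedness of Microbial Communities Along Environmental Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for detecting nestedness of arbuscular
    mycorrhizal fungal communities along a soil-pH gradient. Builds
    phylotype-by-site community matrices from sample-level occurrence
    records, computes NODF and weighted NODF nestedness indices under a
    hypothesis-imposed row/column ordering, tests them against fixed-fixed
    (both-margins-preserving) Monte-Carlo null models with Z-scores,
    decomposes pairwise community comparisons into similarity, richness
    difference and replacement components, performs analytic (hypergeometric)
    rarefaction with variance, runs PERMANOVA and Mantel permutation tests,
    and profiles the pH generality of individual phylotypes. Includes a
    synthetic community generator with known tolerance-limit structure so
    every stage can be exercised and calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
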
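Package: numsize
Title: Value-Based and Statistics-Based Components of Numerosity Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for decomposing performance in
    nonsymbolic numerosity comparison into a psychophysical (ratio-driven)
    component and stimulus-statistics components (value-"larger" association
    and stimulus frequency). Provides stimulus-design constructors (omitted-
    range and frequency-manipulated designs, dot-array geometry), trial-level
    generators (a drift-diffusion process with optional frequency coupling of
    threshold, nondecision time or drift, and an association/frequency-driven
    generator), distance- and size-effect regressions, study-level contrasts
    (paired Wilcoxon model comparison, ANOVA / Kruskal-Wallis with Dunn post
    hoc, block-wise mixed ANOVA), EZ-diffusion parameter recovery, and a
    qualitative diffusion-signature classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    emmeans,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
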
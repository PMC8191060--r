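Package: permatch
Title: Matched-Set Microbiome Association Tests by Set-Indicator
    Projection and Within-Set Permutation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community-level and OTU-level association tests for matched-set
    (paired or 1:m matched) microbiome data. Implements a PERMANOVA pseudo-F
    test on Gower-centered distance matrices and a linear decomposition model
    (LDM) style test on frequency and arcsin-root scales, both using per-set
    indicator variables in the design matrix to project off between-set
    nuisance variation and restricted permutation of traits within matched
    sets. Includes a Dirichlet-multinomial simulator for matched-set count
    data with causal-OTU, covariate, confounder and interaction effects, and
    a replicate-level harness for type I error, power, sensitivity and
    empirical FDR evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan
Suggests:
    biomformat,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
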
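Package: comre
Title: Covariability-Based Multiple Regression for Modulated Gene Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers how candidate modulator genes jointly determine the
    regulation strength between gene pairs from expression data.  Regulation
    strength is measured per sample by the "covariability" statistic (the
    per-sample product of the two genes' expression z-scores, i.e. the
    per-sample contribution to their Pearson correlation) and modelled as a
    multiple linear regression on the z-transformed expression of the
    modulators.  Provides batched all-pairs fitting with a shared design
    matrix, grouping of gene pairs by co-modulation pattern, hub-gene and
    modulator co-occurrence analysis, cross-cohort validation of
    co-modulation patterns, expression-matrix preprocessing (probe collapsing
    by coefficient of variation, noise filters), and a synthetic-data
    generator with planted modulation effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
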
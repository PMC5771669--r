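Package: nucbarrier
Title: Quantification of the Yeast Nuclear Diffusion Barrier and DNA Circle Segregation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis pipeline for asymmetric inheritance of DNA circles in
    budding yeast. Computes the circle-weighted propagation-frequency statistic
    from per-cell segregation counts, the FLIP (fluorescence loss in
    photobleaching) Barrier Index from a constrained one-phase-decay fit with
    delta-method error propagation, stage-resolved circle-passage flux during
    early and late anaphase, nuclear-rim intensity-profile alignment for
    NPC-circle colocalization, and a stochastic simulator of extrachromosomal
    rDNA circle (ERC) accumulation and replicative lifespan. Includes
    synthetic-data generators that emulate the statistical structure of the
    underlying microscopy assays so every stage is testable without raw images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
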
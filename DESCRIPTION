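Package: gutvar
Title: Technical Versus Biological Variability in Defined Gut Bacterial
    Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for replicated bioreactor time series of a
    defined human gut bacterial community. Classifies flow-cytometry events
    into species with random-forest ensembles trained on gated monocultures
    (vote-threshold rule with an explicit unknown class), converts 16S rRNA
    gene counts to copy-number-corrected relative and absolute abundances
    using volumetric cell counts, computes coefficient-of-variation tables
    across replicate vessels with paired Wilcoxon signed-rank comparisons of
    methods, quantifies population heterogeneity from channel ranges, and
    performs Bray-Curtis principal coordinates analysis with permutation-based
    environmental vector fitting. A synthetic-data generator emulates the
    study design (batch-then-chemostat vessels, triplicate sequencing with
    technical noise, species washout, two-phase metabolite trajectories) so
    that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ranger,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
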
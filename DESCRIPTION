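Package: fdSim
Title: Event-Driven Simulation of Transcription Factor Target Search on
    Crowded DNA
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic, event-driven simulation of facilitated diffusion:
    transcription factor molecules bind a genome segment from a free pool,
    reside with sequence-dependent exponential waiting times, slide, hop or
    unbind, and exclude each other sterically. The package models cognate
    (lac repressor-like) and non-cognate (mobile or immobile) DNA-binding
    species, rescales whole-genome abundances to simulated subsegments with
    a copy-number model, and computes first-passage (target search) times,
    target-site occupancy, DNA coverage and reach probabilities together
    with their population statistics (ANOVA with Tukey's range test,
    correlation with crowding, notched-boxplot summaries). Synthetic genome,
    motif and parameter-grid generators make every analysis reproducible
    from seeds alone.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    Biostrings,
    jsonlite,
    rlang
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'ensemble.R'
    'fdSim-package.R'
    'genome.R'
    'observables.R'
    'pwm.R'
    'reduction.R'
    'simulate.R'
    'species.R'
    'synthetic.R'
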
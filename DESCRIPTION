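Package: crisprDerep
Title: Competitive dCas9 Binding Models for CRISPRi Repression and
    Derepression Circuits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Steady-state and dynamic models of transcriptional control by
    competitive dCas9 binding in bacteria. A repressing sgRNA (sgR) directs
    dCas9 to block transcription and a derepressing sgRNA (sgD) directs dCas9
    to an adjacent, mutually exclusive site that restores expression. The
    package provides the competitive-occupancy steady-state model on both the
    mechanistic (mRNA) and observable (fluorescence) scales, the two-stage
    nonlinear least-squares procedure that fits single-sgRNA induction curves
    and then dual-sgRNA response grids with the single-sgRNA parameters
    frozen, ratio-of-means estimators with propagated uncertainty, Hill-form
    inducer-to-promoter-activity transfer functions, sequence-level guide-pair
    design rules (PAM discovery, distance to the transcription start site,
    footprint-based competition classification), ODE time-course simulation of
    repression and derepression dynamics, ratiometric collapse of
    two-dimensional response grids, and seed-deterministic synthetic data
    generators emulating flow-cytometry geometric-mean measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    deSolve,
    Biostrings,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
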
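Package: fluorobind
Title: Fluorescence and Infrared Analysis of Ligand Interactions with
    Membranes, Albumin and DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of ligand interactions with lipid
    membranes, serum albumin and plasmid DNA from fluorescence and
    ATR-FTIR measurements. Provides steady-state tools (fluorescence
    anisotropy, membrane partition constants from double-reciprocal
    quenching titrations, Stern-Volmer and double-logarithmic binding
    fits with inner-filter correction), single-molecule tools
    (Brownian-dynamics photon-stream simulation, multi-tau and direct
    intensity autocorrelation, one-component three-dimensional
    diffusion fits, maximum-likelihood fluorescence lifetime
    estimation), infrared band-peak extraction with parabolic
    refinement and band-shift reporting, and one-way ANOVA with
    Duncan's multiple range test for control-versus-treatment
    significance flags. A synthetic-data generator with known ground
    truth makes every stage of the pipeline testable without
    instrument output.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
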
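Package: msapkit
Title: Methylation-Sensitive Amplified Polymorphism Scoring and Simulation
Version: 0.1.0
Authors@R: person("Hua", "Lin", email = "hua.lin@example.org",
    role = c("aut", "cre"))
Description: Tools for methylation-sensitive amplified polymorphism (MSAP)
    analysis of CCGG cytosine methylation. Implements the HpaII/MspI
    isoschizomer sensitivity model, classification of presence/absence band
    pairs into the four canonical methylation band types, group-level
    methylation ratio statistics, and classification of control-versus-treated
    band-pattern changes into the fourteen standard transition classes with
    no-change, demethylation and methylation rates. Includes an in silico
    EcoRI + HpaII/MspI double-digestion engine that turns a genome plus a
    CCGG methylome track into virtual band matrices, a synthetic methylome
    generator with a categorical state prior and a treatment transition
    kernel for parameter-recovery studies, and the 2^-ddCt relative
    expression calculation for qPCR readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
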
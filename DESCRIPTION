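Package: teckinetics
Title: Pre-Steady-State Kinetic Analysis of Transcription Elongation Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action kinetic modelling and global fitting for rapid-mixing
    experiments on RNA polymerase transcription elongation complexes (TECs).
    Provides declarative kinetic schemes (three-step nucleotide addition and
    translocation, backtracking-limited RNA cleavage, one-step reversible
    ligand binding with explicit depletion), numerical integration of the
    schemes onto quench-flow and stopped-flow observables, simultaneous
    least-squares fitting of heterogeneous datasets with profile-based
    parameter bounds at a fractional chi-square increase, stretched-exponential
    fitting with the median-reaction-time statistic, depletion-corrected
    equilibrium titration analysis, and seeded synthetic-data generators that
    emulate each assay class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
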
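Package: retrosim
Title: Simulation and Analysis of Retroviral Directed-Evolution Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning, simulating and analysing directed-evolution
    experiments in which a passenger gene is mutagenized by the error-prone
    reverse transcriptase of HIV-1-derived vectors over successive
    transduction cycles. Provides a seeded stochastic simulator of mutation
    accumulation (with a G>A-dominated substitution spectrum, copy-choice
    recombination and an optional cis-lethal mask), substitution calling and
    spectrum summaries for sequenced clones, per-nucleotide per-cycle
    mutation-rate estimation with exact Poisson confidence intervals,
    library-complexity and multiplicity-of-infection planning, and a
    screening pipeline with death-rate computation, replicate-wise hit
    calling, four-parameter log-logistic dose-response fitting, IC50
    fold-change estimation and per-concentration two-sample tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
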
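Package: bmecs
Title: Bayesian/Maximum-Entropy Reweighting of Conformational Ensembles
    Against Averaged NMR Chemical Shifts
Version: 0.1.0
Authors@R:
    person("bmecs", "developers", email = "bmecs@example.org", role = c("aut", "cre"))
Description: Reweights conformational ensembles of disordered proteins so that
    ensemble-averaged calculated observables (NMR chemical shifts) match target
    values, using the Bayesian/Maximum-Entropy (BME) formalism. The confidence
    hyperparameter theta is selected by an interleaved train/validation scan
    with Wasserstein-distance distribution diagnostics. Includes
    secondary-chemical-shift preprocessing against a random-coil reference,
    per-residue helicity under weights, a seeded helix-coil benchmark generator
    with two parametric chemical-shift predictors (systematic plus random
    error), and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
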
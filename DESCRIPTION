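Package: epievolve
Title: Evolution of Epigenetic Switching in a Self-Activating Gene Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolution of a self-activating gene circuit in a
    periodically fluctuating environment, where genetic adaptation by mutation
    of biophysical parameters competes with epigenetic switching between
    bistable expression states. Provides exact stochastic simulation
    (Gillespie) of the one-species birth-death kinetics, deterministic
    bifurcation analysis of the autoregulatory circuit (and a toggle-switch
    variant), finite state projection of the chemical master equation with
    noise-load and epimutation-probability maps, solution-genotype manifolds
    and genetic-potential (mutational distance) maps, a generational
    evolutionary engine with tournament selection and multiplicative
    mutation, and lineage genealogy analysis classifying adaptation
    strategies as epigenetic switching, bistable adaptation, or genetic
    adaptation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
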
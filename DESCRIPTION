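Package: kinens
Title: Ensemble Kinetic Modelling of Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Kinens", "Developers", email = "kinens@example.org", role = c("aut", "cre"))
Description: Construct, sample, simulate and parameterize ensembles of
    elementary mass-action kinetic models of metabolic networks against
    multi-mutant steady-state flux data.  Reactions and substrate-level
    regulatory interactions are decomposed into elementary steps; rate
    constants are anchored to a reference flux state obtained by flux
    balance and flux variability analysis; a two-stage genetic algorithm
    estimates parameters and condition-specific enzyme levels from
    knockout-mutant fluxomic data sets; anchored parameterizations are
    back-converted to apparent Michaelis-Menten constants; and product
    yields of designed strains are predicted with the kinetic model and
    with the stoichiometric comparators FBA, MOMA and yield maximization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    quadprog,
    xml2,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
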
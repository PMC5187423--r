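#' @title Synthetic ground-truth fixtures
#' @description Deterministic toy metabolic networks with known
#'   elementary kinetics, plus generators for noisy mutant flux data sets
#'   and jittered "measured" Michaelis-Menten ranges.  They emulate the
#'   structure of real fluxomic training data — a glycolysis-like
#'   backbone, branch points, a cycled cofactor pair, an isozyme pair,
#'   substrate-level inhibition, a biomass drain, and per-reaction
#'   coefficients of variation — without reproducing any real organism's
#'   flux values.
#' @name synthetic_fixtures
NULL

#' Toy fixture specification
#'
#' @param preset one of `"linear-8"`, `"branched-14"`, `"core-24"`.
#' @param noise_cv multiplicative noise CV for generated flux data sets,
#'   default 0.1.
#' @param seed integer seed; fully determines every generated output.
#' @param mutants named list of `\link{genotype}` objects; defaults per
#'   preset mimic a mutant panel: several knockouts in one pathway plus
#'   an isozyme deletion.
#' @return a `toy_spec` object.
#' @export
toy_spec <- function(preset = c("branched-14", "linear-8", "core-24"),
                     noise_cv = 0.1, seed = 1L, mutants = NULL) {
  preset <- match.arg(preset)
  if (is.null(mutants)) mutants <- default_mutants(preset)
  structure(list(preset = preset, noise_cv = noise_cv,
                 seed = as.integer(seed), mutants = mutants),
            class = "toy_spec")
}

default_mutants <- function(preset) {
  switch(preset,
    "linear-8" = list(WT = genotype(), dE3 = genotype(ko = "E3")),
    "branched-14" = list(
      WT = genotype(),
      dE4 = genotype(ko = "E4"),
      dE5 = genotype(ko = "E5"),
      dE6 = genotype(ko = "E6"),
      dE3a = genotype(iso_ko = "E3a"),
      dE3b = genotype(iso_ko = "E3b")),
    "core-24" = list(
      WT = genotype(),
      dE4 = genotype(ko = "E4"),
      dE5 = genotype(ko = "E5"),
      dE12 = genotype(ko = "E12"),
      dE3a = genotype(iso_ko = "E3a")))
}

rxn <- function(id, st, enz = character(), reversible = FALSE,
                exchange = FALSE, subsystem = "") {
  r <- data.frame(id = id, reversible = reversible, exchange = exchange,
                  subsystem = subsystem, stringsAsFactors = FALSE)
  r$stoichiometry <- list(st)
  r$enzymes <- list(enz)
  r
}

mets_table <- function(ids, cofactors = character()) {
  data.frame(id = ids, name = ids, compartment = "c",
             cofactor = ids %in% cofactors,
             conc_lo = 0.5, conc_hi = 2.0, stringsAsFactors = FALSE)
}

#' Build a toy network from a preset
#'
#' All presets contain a substrate uptake, a linear backbone, a cycled
#' cofactor pair and a biomass drain; the branched and core presets add
#' branch points, secreted products, an isozyme pair and substrate-level
#' regulation.  Reference concentration ranges default to 0.5--2 mM.
#'
#' @param spec a `\link{toy_spec}` (or preset name).
#' @return a `\link{metabolic_network}`.
#' @export
make_toy_network <- function(spec) {
  if (is.character(spec)) spec <- toy_spec(preset = spec)
  switch(spec$preset,
         "linear-8" = toy_linear8(),
         "branched-14" = toy_branched14(),
         "core-24" = toy_core24())
}

toy_linear8 <- function() {
  mets <- mets_table(c("m1", "m2", "m3", "m4", "m5", "m6", "bm",
                       "nad", "nadh"), cofactors = c("nad", "nadh"))
  rx <- rbind(
    rxn("EX_glc", c(m1 = 1), exchange = TRUE, subsystem = "exchange"),
    rxn("R1", c(m1 = -1, m2 = 1), "E1", subsystem = "backbone"),
    rxn("R2", c(m2 = -1, nad = -1, m3 = 1, nadh = 1), "E2"),
    rxn("R3", c(m3 = -1, m4 = 1), "E3"),
    rxn("R4", c(m4 = -1, nadh = -1, m5 = 1, nad = 1), "E4"),
    rxn("R5", c(m5 = -1, m6 = 1), "E5"),
    rxn("BIO", c(m6 = -1, bm = 1), subsystem = "biomass"),
    rxn("EX_bm", c(bm = -1), exchange = TRUE))
  metabolic_network(mets, rx, biomass_id = "BIO")
}

toy_branched14 <- function() {
  mets <- mets_table(c("A", "B", "C", "D", "F", "G", "P1", "P2", "bm",
                       "nad", "nadh"), cofactors = c("nad", "nadh"))
  rx <- rbind(
    rxn("EX_glc", c(A = 1), exchange = TRUE, subsystem = "exchange"),
    rxn("R1", c(A = -1, B = 1), "E1", subsystem = "backbone"),
    rxn("R2", c(B = -1, nad = -1, C = 1, nadh = 1), "E2"),
    rxn("R3", c(C = -1, D = 1), c("E3a", "E3b")),
    rxn("R4", c(D = -1, P1 = 1), "E4", subsystem = "product1"),
    rxn("R5", c(D = -1, nadh = -1, P2 = 1, nad = 1), "E5",
        subsystem = "product2"),
    rxn("R6", c(C = -1, F = 1), "E6", subsystem = "biomassbranch"),
    rxn("R8", c(B = -1, F = 1), "E8", subsystem = "biomassbranch"),
    rxn("R7", c(F = -1, G = 1), "E7"),
    rxn("R9", c(nadh = -1, nad = 1), "E9", subsystem = "respiration"),
    rxn("BIO", c(G = -1, bm = 1), subsystem = "biomass"),
    rxn("EX_P1", c(P1 = -1), exchange = TRUE),
    rxn("EX_P2", c(P2 = -1), exchange = TRUE),
    rxn("EX_bm", c(bm = -1), exchange = TRUE))
  regs <- data.frame(regulator = "P2", target = "R1",
                     mode = "competitive-inhibition",
                     stringsAsFactors = FALSE)
  metabolic_network(mets, rx, regs, biomass_id = "BIO")
}

toy_core24 <- function() {
  mets <- mets_table(c("A", "B", "C", "C2", "D", "F", "G", "G2", "H", "I",
                       "P1", "P2", "P3", "bm", "nad", "nadh", "atp",
                       "adp", "o2"),
                     cofactors = c("nad", "nadh", "atp", "adp"))
  rx <- rbind(
    rxn("EX_glc", c(A = 1), exchange = TRUE),
    rxn("R1", c(A = -1, B = 1), "E1"),
    rxn("R2", c(B = -1, nad = -1, C = 1, nadh = 1), "E2"),
    rxn("R3", c(C = -1, D = 1), c("E3a", "E3b")),
    rxn("R4", c(D = -1, adp = -1, P1 = 1, atp = 1), "E4"),
    rxn("R5", c(D = -1, nadh = -1, P2 = 1, nad = 1), "E5"),
    rxn("R6", c(C = -1, F = 1), "E6"),
    rxn("R7", c(F = -1, G = 1), "E7"),
    rxn("R8", c(B = -1, F = 1), "E8"),
    rxn("R9", c(nadh = -2, o2 = -1, nad = 2), "E9"),
    rxn("R10", c(atp = -1, adp = 1), "E10"),
    rxn("R11", c(F = -1, P3 = 1), "E11"),
    rxn("R12", c(B = -1, C2 = 1), "E12"),
    rxn("R13", c(C2 = -1, D = 1), "E13"),
    rxn("R14", c(D = -1, H = 1), "E14"),
    rxn("R15", c(H = -1, atp = -1, I = 1, adp = 1), "E15"),
    rxn("R16", c(G = -1, G2 = 1), "E16"),
    rxn("R17", c(C2 = -1, F = 1), "E17"),
    rxn("BIO", c(G2 = -0.6, I = -0.4, bm = 1), subsystem = "biomass"),
    rxn("EX_P1", c(P1 = -1), exchange = TRUE),
    rxn("EX_P2", c(P2 = -1), exchange = TRUE),
    rxn("EX_P3", c(P3 = -1), exchange = TRUE),
    rxn("EX_bm", c(bm = -1), exchange = TRUE),
    rxn("EX_o2", c(o2 = 1), exchange = TRUE))
  regs <- data.frame(
    regulator = c("P2", "P1", "B"),
    target = c("R1", "R7", "R4"),
    mode = c("competitive-inhibition", "uncompetitive-inhibition",
             "activation"),
    stringsAsFactors = FALSE)
  metabolic_network(mets, rx, regs, biomass_id = "BIO")
}

#' Reference measurements of a toy preset
#'
#' The "wild-type chemostat" measurement set imposed during reference
#' construction: uptake, secreted products and one internal branch flux,
#' with ~3% standard deviations.  Together with biomass maximization
#' these pin the reference flux distribution of each preset.
#'
#' @param preset preset name.
#' @return data.frame with `reaction`, `mean`, `sd`.
#' @export
toy_reference_measurements <- function(preset) {
  switch(preset,
    "linear-8" = data.frame(reaction = "EX_glc", mean = 100, sd = 1),
    "branched-14" = data.frame(
      reaction = c("EX_glc", "EX_P1", "EX_P2", "R6"),
      mean = c(100, 30, 15, 20), sd = c(1, 0.9, 0.45, 0.6)),
    "core-24" = data.frame(
      reaction = c("EX_glc", "EX_P1", "EX_P2", "EX_P3", "R6", "R12",
                   "R14"),
      mean = c(100, 25, 15, 10, 15, 20, 20),
      sd = c(1, 0.75, 0.45, 0.3, 0.45, 0.6, 0.6)))
}

#' Reactions reported in generated flux data sets
#'
#' @param preset preset name.
#' @return character vector of reaction ids whose fluxes are "measured".
#' @export
toy_measured_reactions <- function(preset) {
  switch(preset,
    "linear-8" = c("EX_glc", "R1", "R2", "R3", "R4", "R5", "EX_bm"),
    "branched-14" = c("EX_glc", "R1", "R2", "R3", "R4", "R5", "R6", "R7",
                      "R8", "R9", "EX_P1", "EX_P2", "EX_bm"),
    "core-24" = c("EX_glc", "R1", "R2", "R3", "R4", "R5", "R6", "R7",
                  "R8", "R12", "R14", "EX_P1", "EX_P2", "EX_P3",
                  "EX_bm"))
}

#' Full ground-truth bundle for a toy spec
#'
#' Builds the network, its reference state (via the three-phase LP
#' construction), the elementary decomposition and a ground-truth
#' parameterization sampled under the spec's seed.
#'
#' @param spec a `\link{toy_spec}`.
#' @return list with `network`, `reference`, `elementary`, `truth`
#'   (parameterization), `compiled`.
#' @export
toy_ground_truth <- function(spec) {
  net <- make_toy_network(spec)
  ref <- compute_reference_flux(net, toy_reference_measurements(spec$preset),
                                uptake_bounds = c(EX_glc = 100, EX_o2 = 200))
  en <- decompose_network(net)
  truth <- sample_parameterization(en, ref, seed = spec$seed)
  list(network = net, reference = ref, elementary = en, truth = truth,
       compiled = compile_elementary(en))
}

#' Generate noisy mutant flux data sets from a ground truth
#'
#' For each genotype the perturbed steady state is solved, the configured
#' flux subset recorded, multiplicative Gaussian noise of the given CV
#' added, and that CV attached per reaction.  The wild-type data set is
#' always included (as strain `"WT"` when present in `genotypes`).
#'
#' @param gtb a ground-truth bundle (`\link{toy_ground_truth}`) or a list
#'   with `network`, `elementary`, `truth`, `compiled`.
#' @param genotypes named list of `\link{genotype}` objects.
#' @param noise_cv multiplicative noise coefficient of variation; 0 gives
#'   exact steady-state fluxes.
#' @param seed integer seed for the noise draws.
#' @param measured reaction ids to report; defaults to the preset subset.
#' @param condition condition label attached to every data set.
#' @return list of `flux_dataset` objects (lethal/non-converged genotypes
#'   are flagged via the `lethal` field).
#' @export
ground_truth_datasets <- function(gtb, genotypes, noise_cv = 0.1,
                                  seed = 1L, measured = NULL,
                                  condition = "aerobic_glucose") {
  if (is.null(measured))
    measured <- intersect(toy_measured_reactions_for(gtb),
                          gtb$network$reactions$id)
  set.seed(seed)
  out <- vector("list", length(genotypes))
  names(out) <- names(genotypes)
  for (nm in names(genotypes)) {
    gt <- genotypes[[nm]]
    p <- apply_perturbation(gtb$truth, gt, gtb$elementary)
    ss <- solve_steady_state(gtb$elementary, p, compiled = gtb$compiled)
    v <- ss$flux[measured]
    noisy <- v * (1 + noise_cv * stats::rnorm(length(v)))
    # a strictly positive CV is required downstream (z weights by 1/CV);
    # noiseless data sets carry a nominal floor
    cv_eff <- max(noise_cv, 1e-6)
    meas <- data.frame(reaction = measured, mean = unname(noisy),
                       sd = abs(unname(noisy)) * cv_eff,
                       cv = cv_eff, stringsAsFactors = FALSE)
    out[[nm]] <- structure(
      list(strain = nm, genotype = gt, condition = condition,
           measurements = meas,
           uptake = list(reaction = "EX_glc", value = 100, basis = 100),
           lethal = !ss$converged),
      class = "flux_dataset")
  }
  out
}

toy_measured_reactions_for <- function(gtb) {
  n <- nrow(gtb$network$reactions)
  preset <- c("8" = "linear-8", "14" = "branched-14",
              "24" = "core-24")[as.character(n)]
  if (is.na(preset)) return(gtb$network$reactions$id)
  toy_measured_reactions(preset)
}

#' Jittered "measured" Michaelis-Menten ranges from a ground truth
#'
#' Extracts the true apparent constants of each catalysed reaction with
#' `\link{elementary_to_mm}`, multiplies them by a lognormal jitter and
#' wraps them in confidence ranges (the 10% single-value rule), yielding
#' a synthetic stand-in for a measured-constant table with a known
#' expected overlap fraction.
#'
#' @param gtb ground-truth bundle.
#' @param jitter lognormal sigma of the multiplicative jitter; 0 gives
#'   100% overlap by construction.
#' @param seed integer seed.
#' @return data.frame with `reaction`, `constant` (`Km.<met>` or
#'   `kcat`), `true_value`, `lo`, `hi`.
#' @export
ground_truth_mm_ranges <- function(gtb, jitter = 0, seed = 1L) {
  set.seed(seed)
  rows <- list()
  cat_rx <- gtb$network$reactions$id[
    lengths(gtb$network$reactions$enzymes) > 0L]
  for (r in cat_rx) {
    mm <- elementary_to_mm(gtb$elementary, gtb$truth, r)
    if (!mm$resolved) next
    vals <- c(stats::setNames(mm$Km, paste0("Km.", names(mm$Km))),
              kcat = mm$kcat)
    for (nm in names(vals)) {
      obs <- vals[[nm]] * exp(jitter * stats::rnorm(1))
      rows[[length(rows) + 1L]] <- data.frame(
        reaction = r, constant = nm, true_value = vals[[nm]],
        lo = 0.9 * obs, hi = 1.1 * obs, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
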
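test_that("network round-trips byte-identically through the tabular dialect", {
  net <- make_toy_network("branched-14")
  stem1 <- file.path(tempdir(), "rt1")
  stem2 <- file.path(tempdir(), "rt2")
  write_network(net, stem1)
  net2 <- read_network(stem1)
  write_network(net2, stem2)
  for (suffix in c(".metabolites.csv", ".reactions.csv",
                   ".regulations.csv")) {
    expect_identical(readLines(paste0(stem1, suffix)),
                     readLines(paste0(stem2, suffix)),
                     info = suffix)
  }
  expect_equal(net2$biomass_id, net$biomass_id)
  expect_equal(stoich_matrix(net2), stoich_matrix(net))
  expect_equal(net2$reactions$enzymes, net$reactions$enzymes)
  expect_equal(net2$regulations$mode, net$regulations$mode)
})

test_that("validation names dangling references", {
  net <- make_toy_network("branched-14")
  bad <- net
  bad$regulations <- rbind(bad$regulations,
                           data.frame(regulator = "P2", target = "NOPE",
                                      mode = "competitive-inhibition"))
  expect_error(validate_network(bad), "NOPE")
  bad2 <- net
  bad2$regulations$regulator <- "ghost_met"
  expect_error(validate_network(bad2), "ghost_met")
  bad3 <- net
  bad3$regulations$mode <- "allosteric-banana"
  expect_error(validate_network(bad3), "allosteric-banana")
})

test_that("flux dataset reader copies wild-type CVs and rescales to basis", {
  csv <- file.path(tempdir(), "flux.csv")
  writeLines(c(
    "strain,condition,genotype,reaction,mean,sd",
    "WT,aerobic_glucose,,EX_glc,100,2",
    "WT,aerobic_glucose,,R2,5.0,0.5",
    "mutA,aerobic_glucose,ko:E4,EX_glc,50,",
    "mutA,aerobic_glucose,ko:E4,R2,6.0,"), csv)
  ds <- read_flux_datasets(csv)
  expect_named(ds, c("WT", "mutA"))
  # mutant CV copied from the wild-type row of the same reaction
  mA <- ds$mutA$measurements
  expect_equal(mA$cv[mA$reaction == "R2"], 0.5 / 5.0)
  # uptake mean 50 on basis 100: all fluxes doubled
  expect_equal(mA$mean[mA$reaction == "R2"], 12.0)
  expect_equal(mA$mean[mA$reaction == "EX_glc"], 100)
  expect_equal(ds$mutA$genotype$ko, "E4")
  # rows carrying their own sd use sd/|mean|, no copying
  expect_equal(ds$WT$measurements$cv,
               c(2 / 100, 0.5 / 5.0))
})

test_that("flux dataset reader rejects missing or nonpositive CVs", {
  csv <- file.path(tempdir(), "flux_bad.csv")
  writeLines(c(
    "strain,condition,genotype,reaction,mean,sd",
    "WT,aerobic_glucose,,EX_glc,100,2",
    "mutA,aerobic_glucose,ko:E4,R9,6.0,"), csv)
  expect_error(read_flux_datasets(csv), "R9")
  csv2 <- file.path(tempdir(), "flux_bad2.csv")
  writeLines(c(
    "strain,condition,genotype,reaction,mean,sd",
    "WT,aerobic_glucose,,EX_glc,100,0"), csv2)
  expect_error(read_flux_datasets(csv2), "nonpositive")
})

test_that("flux datasets round-trip through the long CSV", {
  gtb <- get_gtb()
  ds <- ground_truth_datasets(gtb, list(WT = genotype(),
                                        dE4 = genotype(ko = "E4")),
                              noise_cv = 0.05, seed = 3)
  path <- file.path(tempdir(), "rt_flux.csv")
  write_flux_datasets(ds, path)
  back <- read_flux_datasets(path)
  # means are rescaled to the same basis, so only relative values survive
  sc <- 100 / ds$dE4$measurements$mean[
    ds$dE4$measurements$reaction == "EX_glc"]
  expect_equal(back$dE4$measurements$mean,
               ds$dE4$measurements$mean * sc, tolerance = 1e-12)
  expect_equal(back$dE4$genotype$ko, "E4")
})

test_that("parameterization JSON round-trip is lossless", {
  gtb <- get_gtb()
  p <- gtb$truth
  p$iso_tau <- c("dE3a:R3" = 0.4)
  path <- file.path(tempdir(), "param.json")
  write_parameterization(p, path)
  q <- read_parameterization(path)
  expect_equal(q$steps$kf, p$steps$kf, tolerance = 1e-12)
  expect_equal(q$steps$kb, p$steps$kb, tolerance = 1e-12)
  expect_equal(q$fractions, p$fractions, tolerance = 1e-12)
  expect_equal(q$pool_ref, p$pool_ref, tolerance = 1e-12)
  expect_equal(q$iso_tau, p$iso_tau, tolerance = 1e-12)
  expect_equal(q$reference_flux, p$reference_flux, tolerance = 1e-12)

  # ensembles, including the empty one
  write_parameterization(list(p, p), path)
  qq <- read_parameterization(path)
  expect_length(qq, 2)
  write_parameterization(list(), path)
  expect_identical(read_parameterization(path), list())
})

test_that("parameterization reader enforces invariants", {
  gtb <- get_gtb()
  p <- gtb$truth
  path <- file.path(tempdir(), "param_bad.json")
  p$fractions[[1]] <- p$fractions[[1]] * 1.2
  expect_error({
    write_parameterization(p, path)
    read_parameterization(path)
  }, "simplex")
  j <- jsonlite::read_json(path)
  j$schema_version <- 99
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_parameterization(path), "schema version")
})

test_that("SBML stoichiometry import works with sidecar enzymes", {
  sbml <- file.path(tempdir(), "toy.xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="toy"><listOfSpecies>',
    '<species id="A" compartment="c"/>',
    '<species id="B" compartment="c"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="EX_A" reversible="false">',
    '<listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '<reaction id="R1" reversible="true">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>',
    '</reaction>',
    '<reaction id="EX_B" reversible="false">',
    '<listOfReactants><speciesReference species="B"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions></model></sbml>'), sbml)
  ez <- file.path(tempdir(), "enz.csv")
  writeLines(c("reaction,enzymes", "R1,E1a;E1b"), ez)
  net <- read_network(sbml, enzyme_csv = ez)
  expect_equal(nrow(net$reactions), 3)
  expect_equal(net$reactions$stoichiometry[[2]], c(A = -1, B = 2))
  expect_true(net$reactions$exchange[1])
  expect_false(net$reactions$exchange[2])
  expect_equal(net$reactions$enzymes[[2]], c("E1a", "E1b"))
})

test_that("genotype and design parsing reject malformed input", {
  expect_error(kinens:::parse_genotype("explode:E1"), "malformed")
  gt <- kinens:::parse_genotype("ko:E4;iso:E3a;level:E5=2.5")
  expect_equal(gt$ko, "E4")
  expect_equal(gt$iso_ko, "E3a")
  expect_equal(gt$levels$E5, 2.5)
  csv <- file.path(tempdir(), "designs.csv")
  writeLines(c(
    "design_id,interventions,product_metabolite,product_reaction,y_exp",
    "d1,ko:E5;up:E4,P1,EX_P1,0.45"), csv)
  d <- read_strain_designs(csv)
  expect_equal(d[[1]]$interventions,
               c(E5 = "knockout", E4 = "upregulate"))
  expect_equal(d[[1]]$y_exp, 0.45)
})
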
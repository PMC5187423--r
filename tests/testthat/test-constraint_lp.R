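# small hand-checkable networks ---------------------------------------------

chain_net <- function() {
  mets <- data.frame(id = c("A", "B", "bm"), name = c("A", "B", "bm"),
                     compartment = "c", cofactor = FALSE,
                     conc_lo = NA_real_, conc_hi = NA_real_)
  rx <- rbind(
    kinens:::rxn("EX_A", c(A = 1), exchange = TRUE),
    kinens:::rxn("R1", c(A = -1, B = 1), "E1"),
    kinens:::rxn("BIO", c(B = -1, bm = 1)),
    kinens:::rxn("EX_bm", c(bm = -1), exchange = TRUE))
  metabolic_network(mets, rx, biomass_id = "BIO")
}

# uptake feeding two equivalent branches that rejoin at a sink; Rblocked
# produces a dead-end metabolite, so it can never carry steady flux
parallel_net <- function() {
  mets <- data.frame(id = c("A", "B", "C", "D"),
                     name = c("A", "B", "C", "D"),
                     compartment = "c", cofactor = FALSE,
                     conc_lo = NA_real_, conc_hi = NA_real_)
  rx <- rbind(
    kinens:::rxn("EX_A", c(A = 1), exchange = TRUE),
    kinens:::rxn("Rb1", c(A = -1, B = 1), "E1"),
    kinens:::rxn("Rb2", c(A = -1, B = 1), "E2"),
    kinens:::rxn("Rjoin", c(B = -1, C = 1), "E3"),
    kinens:::rxn("Rblocked", c(B = -1, D = 1), "E4"),
    kinens:::rxn("EX_C", c(C = -1), exchange = TRUE))
  metabolic_network(mets, rx)
}

test_that("linear chain: biomass equals the uptake cap, all fluxes coupled", {
  net <- chain_net()
  sol <- fba_predict(net, uptake_bounds = c(EX_A = 10))
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(sol$v[c("EX_A", "R1", "BIO", "EX_bm")]),
               rep(10, 4), tolerance = 1e-9)
  expect_flux_balance(net, sol$v)
  fva <- flux_variability(net, fixed = list(EX_A = 10))
  expect_equal(fva$min, fva$max, tolerance = 1e-9)
})

test_that("infeasible measurements are reported as such", {
  net <- chain_net()
  bad <- data.frame(reaction = c("EX_A", "BIO"), mean = c(5, 7),
                    sd = c(0, 0))
  expect_error(compute_reference_flux(net, bad,
                                      uptake_bounds = c(EX_A = 10)),
               "infeasible")
})

test_that("fully determined measurements survive phases 2-3 unchanged", {
  net <- chain_net()
  meas <- data.frame(reaction = c("EX_A", "R1"), mean = c(8, 8),
                     sd = c(0, 0))
  ref <- compute_reference_flux(net, meas, uptake_bounds = c(EX_A = 10))
  expect_equal(unname(ref$v), rep(8, 4), tolerance = 1e-8)
  expect_equal(unname(ref$conc), rep(1, 3))
})

test_that("two equivalent branches each span [0, uptake] under FVA", {
  net <- parallel_net()
  fva <- flux_variability(net, fixed = list(EX_A = 10),
                          reactions = c("Rb1", "Rb2", "Rblocked"))
  expect_equal(fva$min[1:2], c(0, 0), tolerance = 1e-8)
  expect_equal(fva$max[1:2], c(10, 10), tolerance = 1e-8)
  # structurally blocked reaction pinned to [0, 0]
  expect_equal(unname(unlist(fva[3, c("min", "max")])), c(0, 0),
               tolerance = 1e-8)
})

test_that("LP and QP solutions match brute-force vertex enumeration", {
  net <- parallel_net()
  S <- stoich_matrix(net)
  bnd <- default_bounds(net, big = 50)
  bnd$ub["EX_A"] <- 10
  set.seed(42)
  for (i in 1:6) {
    obj <- round(stats::rnorm(ncol(S)), 2)
    for (maximize in c(TRUE, FALSE)) {
      got <- solve_lp(obj, S, bnd$lb, bnd$ub, maximize = maximize)
      want <- brute_lp(obj, S, bnd$lb, bnd$ub, maximize = maximize)
      expect_equal(got$value, want$value, tolerance = 1e-6,
                   info = paste("objective draw", i, "max =", maximize))
    }
  }
  # MOMA projection against active-set enumeration
  ref <- fba_predict(net, objective = "EX_C",
                     uptake_bounds = c(EX_A = 10))$v
  for (ko in list("E1", "E2", "E3")) {
    got <- moma_predict(net, genotype(ko = ko), ref,
                        uptake_bounds = c(EX_A = 10))
    bnd2 <- kinens:::apply_genotype_bounds(net, genotype(ko = ko), bnd)
    want <- brute_moma(ref, S, bnd2$lb, bnd2$ub)
    expect_equal(sum((got$v - ref)^2), want$value, tolerance = 1e-6,
                 info = paste("KO", ko))
  }
})

test_that("FVA ranges bracket the FBA optimum componentwise", {
  net <- make_toy_network("branched-14")
  sol <- fba_predict(net, uptake_bounds = c(EX_glc = 100))
  fva <- flux_variability(net, fixed = stats::setNames(
    list(sol$objective_value), net$biomass_id),
    uptake_bounds = c(EX_glc = 100))
  expect_true(all(fva$min <= sol$v[fva$reaction] + 1e-6))
  expect_true(all(fva$max >= sol$v[fva$reaction] - 1e-6))
})

test_that("MOMA with an empty genotype returns the reference exactly", {
  net <- make_toy_network("branched-14")
  ref <- get_gtb()$reference$v
  got <- moma_predict(net, genotype(), ref,
                      uptake_bounds = c(EX_glc = 100))
  expect_equal(got$v, ref, tolerance = 1e-6)
  expect_lt(got$distance, 1e-3)
  # KO of an already-zero-flux reaction leaves the reference unchanged
  pnet <- parallel_net()
  ref0 <- c(EX_A = 10, Rb1 = 10, Rb2 = 0, Rjoin = 10, Rblocked = 0,
            EX_C = 10)
  got0 <- moma_predict(pnet, genotype(ko = "E2"), ref0,
                       uptake_bounds = c(EX_A = 10))
  expect_equal(got0$v, ref0, tolerance = 1e-6)
  # KO closing one branch shifts its flux to the open branch (1-D QP)
  ref1 <- c(EX_A = 10, Rb1 = 5, Rb2 = 5, Rjoin = 10, Rblocked = 0,
            EX_C = 10)
  got1 <- moma_predict(pnet, genotype(ko = "E2"), ref1,
                       uptake_bounds = c(EX_A = 10))
  # by hand: with Rb2 = 0 the chain EX_A = Rb1 = Rjoin = EX_C = x and
  # the objective 3(x-10)^2 + (x-5)^2 is minimized at x = 35/4
  expect_equal(unname(got1$v[c("Rb1", "Rb2")]), c(35 / 4, 0),
               tolerance = 1e-6)
})

test_that("biomass coupling: single-route pathways couple, branched ones do not", {
  net <- chain_net()
  coupled <- biomass_coupled_reactions(net, uptake_bounds = c(EX_A = 10))
  expect_true(all(c("EX_A", "R1", "BIO", "EX_bm") %in% coupled))

  net2 <- make_toy_network("branched-14")
  coupled2 <- biomass_coupled_reactions(net2,
                                        uptake_bounds = c(EX_glc = 100))
  # reactions upstream of the product branches can drain elsewhere
  expect_false("R1" %in% coupled2)
  expect_false("R2" %in% coupled2)
  expect_true("EX_bm" %in% coupled2)
  # oracle: ratio-FVA by brute force on the small chain
  S <- stoich_matrix(net)
  bnd <- default_bounds(net)
  bnd$ub["EX_A"] <- 10
  bnd$lb["BIO"] <- bnd$ub["BIO"] <- 1
  for (r in setdiff(net$reactions$id, "BIO")) {
    obj <- as.numeric(net$reactions$id == r)
    lo <- brute_lp(obj, S, bnd$lb, bnd$ub, maximize = FALSE)$value
    hi <- brute_lp(obj, S, bnd$lb, bnd$ub, maximize = TRUE)$value
    expect_equal(r %in% coupled, abs(hi - lo) < 1e-9, info = r)
  }
})

test_that("FBA knockout semantics: lethal knockouts are flagged", {
  net <- chain_net()
  sol <- fba_predict(net, genotype(ko = "E1"),
                     uptake_bounds = c(EX_A = 10))
  expect_true(sol$lethal)
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
  # isozymes: deleting one of two leaves the reaction open
  net2 <- make_toy_network("branched-14")
  s1 <- fba_predict(net2, genotype(iso_ko = "E3a"),
                    uptake_bounds = c(EX_glc = 100))
  s2 <- fba_predict(net2, genotype(ko = c("E3a", "E3b")),
                    uptake_bounds = c(EX_glc = 100))
  expect_false(s1$lethal)
  expect_equal(unname(s2$v["R3"]), 0, tolerance = 1e-9)
})

test_that("max-yield prediction reaches the stoichiometric envelope", {
  net <- make_toy_network("branched-14")
  sol <- max_yield_predict(net, genotype(), "EX_P1",
                           uptake_bounds = c(EX_glc = 100))
  # every carbon can be routed A -> B -> C -> D -> P1
  expect_equal(sol$product_flux, 100, tolerance = 1e-8)
  dead <- max_yield_predict(net, genotype(ko = "E4"), "EX_P1",
                            uptake_bounds = c(EX_glc = 100))
  expect_equal(dead$product_flux, 0, tolerance = 1e-9)
})
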
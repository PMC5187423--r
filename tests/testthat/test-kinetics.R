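test_that("anchoring reproduces the defining flux split", {
  # V=1, R=0.5: forward elementary flux 2, backward 1; with free-enzyme
  # fraction 0.25 and unit substrate the binding constant is 2/0.25 = 8
  net <- uni_uni_network()
  en <- decompose_network(net)
  R <- stats::setNames(rep(0.5, nrow(en$steps)), en$steps$id)
  fr <- list(`R.E1` = c(0.25, 0.35, 0.40))
  names(fr$R.E1) <- en$pools$forms[[1]]
  es <- stats::setNames(rep(0.5, nrow(en$steps)), en$steps$id)
  pr <- c(R.E1 = 1)
  k <- anchor_rate_constants(en, uni_uni_reference(), R, fr, pr, es)
  bind <- which(en$steps$kind == "binding")
  expect_equal(k$kf[bind], 2 / 0.25, tolerance = 1e-12)
  expect_equal(k$kb[bind], 1 / 0.35, tolerance = 1e-12)
  # R = 0 gives an irreversible step
  R0 <- R; R0[] <- 0
  k0 <- anchor_rate_constants(en, uni_uni_reference(), R0, fr, pr, es)
  expect_equal(k0$kb[bind], 0)
  # a zero fraction on a needed form is an error
  frbad <- fr; frbad$R.E1[1] <- 0; frbad$R.E1[2] <- 0.6
  expect_error(anchor_rate_constants(en, uni_uni_reference(), R, frbad,
                                     pr, es), "fraction")
})

test_that("sampled parameterizations are anchored and reproducible", {
  gtb <- get_gtb()
  en <- gtb$elementary
  p1 <- sample_parameterization(en, gtb$reference, seed = 123)
  p2 <- sample_parameterization(en, gtb$reference, seed = 123)
  expect_identical(p1$steps, p2$steps)
  expect_identical(p1$fractions, p2$fractions)
  # anchoring exactness via the pure-R RHS oracle, several seeds
  for (seed in 1:10) {
    p <- sample_parameterization(en, gtb$reference, seed = seed)
    ode <- build_odes(en, p)
    expect_lt(max(abs(ode$rhs(initial_state(en, p)))), 1e-9)
  }
})

test_that("the reference state is a fixed point of the solved system", {
  gtb <- get_gtb()
  ss <- solve_steady_state(gtb$elementary, gtb$truth,
                           compiled = gtb$compiled)
  expect_true(ss$converged)
  expect_lt(max(abs(ss$flux - gtb$reference$v[names(ss$flux)])), 1e-9)
  expect_lt(ss$pool_drift, 1e-9)
})

test_that("time-rescaling a cycle preserves its enzyme-form fixed point", {
  # doubling every elementary constant of one cycle doubles its flux at
  # unchanged enzyme-form occupancies (with metabolites clamped): the
  # form distribution is invariant under time-rescaling
  net <- uni_uni_network()
  en <- decompose_network(net)
  compiled <- compile_elementary(en)
  p <- sample_parameterization(en, uni_uni_reference(), seed = 3)
  clamp <- c(S = 2.5, P = 0.7)
  s1 <- solve_steady_state(en, p, perturbation(clamp = clamp),
                           compiled = compiled, tol = 1e-12)
  p2 <- p
  rows <- p2$steps$reaction == "R"
  p2$steps$kf[rows] <- 2 * p2$steps$kf[rows]
  p2$steps$kb[rows] <- 2 * p2$steps$kb[rows]
  s2 <- solve_steady_state(en, p2, perturbation(clamp = clamp),
                           compiled = compiled, tol = 1e-12)
  forms <- en$pools$forms[[1]]
  expect_equal(s2$conc[forms], s1$conc[forms], tolerance = 1e-8)
  expect_equal(s2$flux[["R"]], 2 * s1$flux[["R"]], tolerance = 1e-8)
})

test_that("knockout of the only product-forming enzyme silences the product", {
  gtb <- get_gtb()
  p <- apply_perturbation(gtb$truth, genotype(ko = "E4"),
                          gtb$elementary)
  ss <- solve_steady_state(gtb$elementary, p, compiled = gtb$compiled)
  expect_true(ss$converged)
  expect_equal(unname(ss$flux["R4"]), 0, tolerance = 1e-9)
  expect_equal(unname(ss$flux["EX_P1"]), 0, tolerance = 1e-6)
  expect_lt(ss$pool_drift, 1e-9)
  expect_flux_balance(gtb$network, ss$flux, tol = 1e-6)
})

test_that("all steps of a catalytic cycle carry equal net flux at steady state", {
  gtb <- get_gtb()
  en <- gtb$elementary
  p <- apply_perturbation(gtb$truth, genotype(ko = "E5"), en)
  ss <- solve_steady_state(en, p, compiled = gtb$compiled)
  ode <- build_odes(en, p)
  rates <- ode$rates(ss$conc)
  for (pool in en$pools$id) {
    cyc <- rates[which(en$steps$pool %in% pool & !en$steps$regulatory)]
    expect_lt(diff(range(cyc)), 1e-8)
  }
  # regulatory dead-end steps are at equilibrium
  reg <- rates[which(en$steps$regulatory)]
  expect_lt(max(abs(reg)), 1e-8)
})

test_that("enzyme pools are conserved along explicit trajectories", {
  # explicit RK4 on a mildly-parameterized uni-uni model perturbed off
  # its fixed point; the pool total must not drift
  net <- uni_uni_network()
  en <- decompose_network(net)
  p <- sample_parameterization(en, uni_uni_reference(), seed = 2)
  rows <- p$steps$reaction == "R"
  p$steps$kf[rows] <- c(4, 2, 5)     # benign magnitudes for explicit RK4
  p$steps$kb[rows] <- c(1, 0.5, 0.2)
  ode <- build_odes(en, p)
  x <- initial_state(en, p)
  x["S"] <- 3; x["P"] <- 0.2         # off the fixed point
  h <- 1e-3
  for (i in 1:10000) {
    k1 <- ode$rhs(x); k2 <- ode$rhs(x + h / 2 * k1)
    k3 <- ode$rhs(x + h / 2 * k2); k4 <- ode$rhs(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  forms <- en$pools$forms[[1]]
  expect_lt(abs(sum(x[forms]) - 1), 1e-9)
  # the implicit solver conserves pools on the full toy model as well
  gtb <- get_gtb()
  pp <- apply_perturbation(gtb$truth, genotype(ko = "E6"),
                           gtb$elementary)
  ss <- solve_steady_state(gtb$elementary, pp, compiled = gtb$compiled)
  expect_lt(ss$pool_drift, 1e-9)
})

test_that("elementary uni-uni flux matches the reversible MM closed form", {
  net <- uni_uni_network()
  en <- decompose_network(net)
  compiled <- compile_elementary(en)
  set.seed(99)
  for (i in 1:20) {
    p <- sample_parameterization(en, uni_uni_reference())
    k <- p$steps[match(paste0("R.E1.s", 1:3), p$steps$id), ]
    S <- stats::runif(1, 0.05, 20); P <- stats::runif(1, 0.05, 5)
    ss <- solve_steady_state(en, p,
                             perturbation(clamp = c(S = S, P = P)),
                             compiled = compiled, tol = 1e-12)
    expect_true(ss$converged)
    want <- uni_uni_closed_form(k$kf[1], k$kb[1], k$kf[2], k$kb[2],
                                k$kf[3], k$kb[3], S, P,
                                et = p$pool_ref[["R.E1"]])
    expect_equal(unname(ss$flux["R"]), want,
                 tolerance = 1e-6 * max(1e-6, abs(want)))
  }
})

test_that("saturating flux scales with the total enzyme level", {
  net <- uni_uni_network()
  en <- decompose_network(net)
  compiled <- compile_elementary(en)
  p <- sample_parameterization(en, uni_uni_reference(), seed = 5)
  clamp <- c(S = 1e6, P = 1)
  v1 <- solve_steady_state(en, p, perturbation(clamp = clamp),
                           compiled = compiled, tol = 1e-12)$flux[["R"]]
  v2 <- solve_steady_state(en, p, perturbation(e_level = c(E1 = 2),
                                               clamp = clamp),
                           compiled = compiled, tol = 1e-12)$flux[["R"]]
  expect_equal(v2 / v1, 2, tolerance = 1e-6)
})

test_that("perturbation semantics: knockouts, isozyme deletions, clipping", {
  gtb <- get_gtb()
  en <- gtb$elementary
  p <- apply_perturbation(gtb$truth, genotype(ko = "E4"), en)
  expect_equal(unname(p$e_level["R4.E4"]), 0)
  p2 <- apply_perturbation(gtb$truth, genotype(iso_ko = "E3a"), en)
  expect_equal(unname(p2$e_level["R3.E3a"]), 0)
  expect_equal(attr(p2, "fit_free"), "R3.E3b")
  expect_warning(
    p3 <- apply_perturbation(gtb$truth,
                             genotype(levels = list(E5 = 50)), en),
    "clipped")
  expect_equal(unname(p3$e_level["R5.E5"]), 10)
  expect_error(apply_perturbation(gtb$truth, genotype(ko = "E99"), en),
               "E99")
  expect_warning(perturbation(e_level = c(E5 = -2)), "clipped")
})

test_that("zero-reference-flux steps preserve the fixed point", {
  # a network whose branch carries no reference flux still anchors, and
  # the equilibrium-scaled steps keep the reference an exact fixed point
  mets <- data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                     compartment = "c", cofactor = FALSE,
                     conc_lo = NA_real_, conc_hi = NA_real_)
  rx <- rbind(
    kinens:::rxn("EX_A", c(A = 1), exchange = TRUE),
    kinens:::rxn("R1", c(A = -1, B = 1), "E1"),
    kinens:::rxn("Rside", c(A = -1, C = 1), "E2", reversible = TRUE),
    kinens:::rxn("Rback", c(C = -1, B = 1), "E3", reversible = TRUE),
    kinens:::rxn("EX_B", c(B = -1), exchange = TRUE))
  net <- metabolic_network(mets, rx)
  en <- decompose_network(net)
  vref <- c(EX_A = 10, R1 = 10, Rside = 0, Rback = 0, EX_B = 10)
  p <- sample_parameterization(en, vref, seed = 11)
  ode <- build_odes(en, p)
  expect_lt(max(abs(ode$rhs(initial_state(en, p)))), 1e-9)
  ss <- solve_steady_state(en, p)
  expect_true(ss$converged)
  expect_equal(unname(ss$flux["Rside"]), 0, tolerance = 1e-9)
})
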
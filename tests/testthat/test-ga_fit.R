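fake_ds <- function(reaction, mean, cv, strain = "m1") {
  structure(list(strain = strain, genotype = genotype(),
                 condition = "aerobic_glucose",
                 measurements = data.frame(reaction = reaction,
                                           mean = mean,
                                           sd = abs(mean) * cv, cv = cv),
                 uptake = list(reaction = "EX_glc", value = 100,
                               basis = 100),
                 lethal = FALSE), class = "flux_dataset")
}

test_that("objective z matches its hand-computed definition", {
  ds <- fake_ds("R1", 1.0, 0.1)
  perfect <- list(list(flux = c(R1 = 1.0), converged = TRUE))
  expect_identical(objective_z(perfect, list(ds)), 0)
  # one mutant, one reaction: |1.2 - 1.0| / 1.0 / 0.1 = 2.0
  pred <- list(list(flux = c(R1 = 1.2), converged = TRUE))
  expect_equal(objective_z(pred, list(ds)), 2.0, tolerance = 1e-12)
  # halving the CV doubles the contribution
  ds2 <- fake_ds("R1", 1.0, 0.05)
  expect_equal(objective_z(pred, list(ds2)),
               2 * objective_z(pred, list(ds)), tolerance = 1e-12)
  # near-zero measurements are floored at eps = 1e-3 * basis
  ds3 <- fake_ds("R1", 0.0, 0.1)
  pred3 <- list(list(flux = c(R1 = 0.05), converged = TRUE))
  expect_equal(objective_z(pred3, list(ds3)), (0.05 / 0.1) / 0.1,
               tolerance = 1e-12)
  # non-converged mutants contribute the penalty
  expect_equal(objective_z(list(list(flux = NULL, converged = FALSE)),
                           list(ds)), 1e6)
  expect_error(objective_z(list(list(flux = c(R9 = 1), converged = TRUE)),
                           list(ds)), "missing prediction")
})

test_that("reaction-block crossover produces anchored recombinants", {
  gtb <- get_gtb()
  en <- gtb$elementary
  a <- sample_parameterization(en, gtb$reference, seed = 21)
  b <- sample_parameterization(en, gtb$reference, seed = 22)
  set.seed(1)
  kids <- crossover(a, a)
  expect_identical(kids$a$steps, a$steps)
  expect_identical(kids$b$fractions, a$fractions)
  # parents differing in exactly one reaction block yield the two
  # possible combinations
  b1 <- a
  rows <- b1$steps$reaction == "R2"
  b1$steps[rows, c("R", "equil_scale", "kf", "kb")] <-
    b$steps[rows, c("R", "equil_scale", "kf", "kb")]
  b1$fractions[["R2.E2"]] <- b$fractions[["R2.E2"]]
  for (rep in 1:5) {
    kids <- crossover(a, b1)
    ka <- kids$a$steps$kf[rows][1]
    expect_true(ka %in% c(a$steps$kf[rows][1], b1$steps$kf[rows][1]))
    expect_equal(sort(c(kids$a$steps$kf[rows][1],
                        kids$b$steps$kf[rows][1])),
                 sort(c(a$steps$kf[rows][1], b1$steps$kf[rows][1])))
  }
  # children remain anchored (residual oracle) and re-anchoring is a no-op
  set.seed(7)
  kids <- crossover(a, b)
  for (kid in kids) {
    ode <- build_odes(en, kid)
    expect_lt(max(abs(ode$rhs(initial_state(en, kid)))), 1e-9)
    re <- reanchor(en, kid)
    expect_equal(re$steps$kf, kid$steps$kf, tolerance = 1e-12)
  }
  expect_error(crossover(a, sample_parameterization(
    decompose_network(uni_uni_network()), uni_uni_reference())),
    "different elementary networks")
})

test_that("mutation resamples whole blocks and keeps anchoring", {
  gtb <- get_gtb()
  en <- gtb$elementary
  a <- sample_parameterization(en, gtb$reference, seed = 31)
  set.seed(4)
  m <- kinens:::mutate_individual(a, en, gtb$reference, prob = 0.5)
  changed <- unique(m$steps$reaction[m$steps$R != a$steps$R])
  expect_gt(length(changed), 0)
  ode <- build_odes(en, m)
  expect_lt(max(abs(ode$rhs(initial_state(en, m)))), 1e-9)
})

test_that("a small stage-1 fit is monotone, reproducible and improves", {
  gtb <- get_gtb()
  ds <- ground_truth_datasets(gtb, genotypes = list(
    WT = genotype(),
    dE4 = genotype(ko = "E4"),
    dE5 = genotype(ko = "E5")),
    noise_cv = 0.1, seed = 5)
  cfg <- ga_config(pop_size = 14, generations = 6, seed = 42)
  fit1 <- stage1_fit(gtb$elementary, gtb$reference, ds, cfg)
  expect_true(all(diff(fit1$trajectory) <= 1e-12))
  expect_lt(fit1$z, fit1$trajectory[1] + 1e-12)
  fit2 <- stage1_fit(gtb$elementary, gtb$reference, ds, cfg)
  expect_identical(fit1$z, fit2$z)
  expect_identical(fit1$best$steps, fit2$best$steps)
  expect_identical(fit1$trajectory, fit2$trajectory)
})

test_that("stage-1 isozyme genes appear exactly for deletion strains", {
  gtb <- get_gtb()
  ds <- ground_truth_datasets(gtb, genotypes = list(
    WT = genotype(), dE3a = genotype(iso_ko = "E3a")),
    noise_cv = 0.1, seed = 6)
  keys <- kinens:::stage1_iso_keys(gtb$elementary, ds)
  expect_identical(keys, "dE3a:R3")
})

test_that("stage 2 with an empty whitelist has no degrees of freedom", {
  gtb <- get_gtb()
  ds <- ground_truth_datasets(gtb, genotypes = list(WT = genotype()),
                              noise_cv = 0.1, seed = 8,
                              condition = "anaerobic_glucose")
  expect_warning(
    fit <- stage2_fit(gtb$truth, gtb$elementary, ds,
                      whitelist = character(),
                      config = ga_config(pop_size = 4, generations = 2,
                                         seed = 1)),
    "empty whitelist")
  expect_length(fit$e_level, 0)
  # predictions are the unmodified stage-1 model's
  expect_equal(unname(fit$predictions[[1]]$flux["R1"]),
               unname(gtb$reference$v["R1"]), tolerance = 1e-6)
})

test_that("stage 2 refuses mixed condition groups", {
  gtb <- get_gtb()
  ds <- ground_truth_datasets(gtb, genotypes = list(WT = genotype()),
                              noise_cv = 0.1, seed = 8)
  ds2 <- ds
  ds2$WT$condition <- "anaerobic_glucose"
  expect_error(stage2_fit(gtb$truth, gtb$elementary, c(ds, ds2),
                          whitelist = "E9"),
               "one condition group")
})

test_that("cross-validation has the fold-summary contract", {
  gtb <- get_gtb()
  # three identical noiseless wild-type data sets: every anchored model
  # reproduces them exactly, so held-out deviation is zero by redundancy
  ds <- ground_truth_datasets(gtb, genotypes = list(WT = genotype()),
                              noise_cv = 0, seed = 9)
  dss <- list(ds$WT, ds$WT, ds$WT)
  dss[[2]]$strain <- "WT2"; dss[[3]]$strain <- "WT3"
  cfg <- ga_config(pop_size = 6, generations = 2, seed = 3)
  cv <- cross_validate(gtb$elementary, gtb$reference, dss, cfg,
                       mode = "loo")
  expect_equal(nrow(cv), 3)
  expect_equal(cv$excluded, c("WT", "WT2", "WT3"))
  expect_lt(max(cv$deviation), 1e-6)
  expect_error(cross_validate(gtb$elementary, gtb$reference, dss[1:2],
                              cfg), "at least 3")
})
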
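#' @title Constraint-based analyses of a metabolic network
#' @description Reference-state construction, flux variability, biomass
#'   coupling and the stoichiometric comparator predictions (FBA, MOMA,
#'   maximum product yield).  All fluxes are on the uptake basis (default
#'   100 mmol/gDW/h of carbon substrate); mass-balance residuals of every
#'   returned vector are below 1e-8 on that scale.
#' @name constraint_lp
NULL

#' Genotype descriptor
#'
#' @param ko enzyme ids knocked out entirely (all isozymes).
#' @param iso_ko individual isozyme ids deleted (other isozymes of the
#'   same reaction survive).
#' @param levels named list of enzyme-level assignments: a single number
#'   (fixed fold change of the total pool) or a length-2 interval
#'   `c(lo, hi)`; values are clipped to `[0, 10]`.
#' @return a `genotype` object.
#' @export
genotype <- function(ko = character(), iso_ko = character(), levels = list()) {
  structure(list(ko = ko, iso_ko = iso_ko, levels = levels),
            class = "genotype")
}

check_genotype <- function(net, gt) {
  enz <- network_enzymes(net)
  bad <- setdiff(c(gt$ko, gt$iso_ko, names(gt$levels)), enz)
  if (length(bad)) stop("unknown enzyme id(s): ", paste(bad, collapse = ", "))
  invisible(gt)
}

# reactions forced to zero: every catalysing isozyme deleted
deleted_reactions <- function(net, gt) {
  check_genotype(net, gt)
  dead <- c(gt$ko, gt$iso_ko)
  rid <- net$reactions$id
  hit <- vapply(seq_along(rid), function(i) {
    enz <- net$reactions$enzymes[[i]]
    length(enz) > 0L && all(enz %in% dead)
  }, logical(1))
  rid[hit]
}

apply_genotype_bounds <- function(net, gt, bnd) {
  dead <- deleted_reactions(net, gt)
  bnd$lb[dead] <- 0
  bnd$ub[dead] <- 0
  bnd
}

apply_uptake_bounds <- function(bnd, uptake_bounds) {
  for (r in intersect(names(uptake_bounds), names(bnd$ub)))
    bnd$ub[r] <- uptake_bounds[[r]]
  bnd
}

#' Flux balance analysis prediction
#'
#' Maximizes the objective reaction (biomass by default) under mass
#' balance, default bounds, uptake limits and genotype knockouts (a
#' reaction is blocked when all its isozymes are deleted).
#'
#' @param net a `metabolic_network`.
#' @param gt a `\link{genotype}`; default none.
#' @param objective reaction id to maximize; default the biomass reaction.
#' @param uptake_bounds named numeric, upper bounds on uptake exchanges,
#'   e.g. `c(EX_glc = 100, EX_o2 = 200)`.
#' @return list with `v` (flux vector), `objective_value`, `lethal`
#'   (TRUE when no growth is possible in silico) and `status`.
#' @export
fba_predict <- function(net, gt = genotype(), objective = net$biomass_id,
                        uptake_bounds = NULL) {
  S <- stoich_matrix(net)
  bnd <- default_bounds(net)
  if (!is.null(uptake_bounds)) bnd <- apply_uptake_bounds(bnd, uptake_bounds)
  bnd <- apply_genotype_bounds(net, gt, bnd)
  obj <- as.numeric(net$reactions$id == objective)
  sol <- solve_lp(obj, S, bnd$lb, bnd$ub, maximize = TRUE)
  if (sol$status != "optimal") {
    v <- numeric(ncol(S)); names(v) <- colnames(S)
    return(list(v = v, objective_value = 0, lethal = TRUE,
                status = sol$status))
  }
  list(v = sol$v, objective_value = sol$value,
       lethal = sol$value <= 1e-9, status = sol$status)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux under mass balance, bounds and
#' the supplied fixed constraints.
#'
#' @param net a `metabolic_network`.
#' @param fixed named list of flux constraints, each a single value or a
#'   `c(lo, hi)` interval, applied as bounds.
#' @param reactions reaction ids to scan (default all).
#' @param uptake_bounds as in `\link{fba_predict}`.
#' @param gt optional `\link{genotype}`.
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(net, fixed = list(), reactions = NULL,
                             uptake_bounds = NULL, gt = genotype()) {
  S <- stoich_matrix(net)
  bnd <- default_bounds(net)
  if (!is.null(uptake_bounds)) bnd <- apply_uptake_bounds(bnd, uptake_bounds)
  bnd <- apply_genotype_bounds(net, gt, bnd)
  bnd <- impose_fixed(bnd, fixed)
  if (is.null(reactions)) reactions <- net$reactions$id
  lo <- hi <- numeric(length(reactions))
  for (k in seq_along(reactions)) {
    obj <- as.numeric(net$reactions$id == reactions[k])
    a <- solve_lp(obj, S, bnd$lb, bnd$ub, maximize = FALSE)
    b <- solve_lp(obj, S, bnd$lb, bnd$ub, maximize = TRUE)
    if (a$status != "optimal" || b$status != "optimal")
      stop("flux_variability: infeasible constraint set")
    lo[k] <- a$value; hi[k] <- b$value
  }
  data.frame(reaction = reactions, min = lo, max = hi,
             stringsAsFactors = FALSE)
}

impose_fixed <- function(bnd, fixed) {
  for (r in names(fixed)) {
    val <- fixed[[r]]
    if (!r %in% names(bnd$lb)) stop("unknown reaction in constraints: ", r)
    if (length(val) == 1L) val <- c(val, val)
    bnd$lb[r] <- max(bnd$lb[r], val[1])
    bnd$ub[r] <- min(bnd$ub[r], val[2])
  }
  bnd
}

#' Reference flux distribution
#'
#' Three-phase construction of the anchoring state: (1) biomass
#' maximization with the experimental flux measurements imposed as 1-s.d.
#' ranges; (2) flux variability at the optimal biomass for all reactions
#' without measurements; (3) a single biomass-optimal flux vector within
#' the variability ranges, tie-broken by minimizing the L1 norm so the
#' result is reproducible among alternate optima.  Normalized metabolite
#' concentrations at the reference are 1 by definition.
#'
#' @param net a `metabolic_network`.
#' @param measured data.frame with columns `reaction`, `mean` and
#'   optionally `sd` (default 0): each measurement is imposed as the
#'   interval `mean +/- sd`.
#' @param uptake_bounds named numeric of uptake caps.
#' @return a `reference_state`: list with `v` (named flux vector),
#'   `biomass`, `fva` (phase-2 ranges), `conc` (named, all 1) and
#'   `conc_ranges` (absolute mM ranges copied from the network).
#' @export
compute_reference_flux <- function(net, measured, uptake_bounds = NULL) {
  measured <- as.data.frame(measured)
  if (is.null(measured$sd)) measured$sd <- 0
  fixed <- lapply(seq_len(nrow(measured)), function(i)
    c(measured$mean[i] - measured$sd[i], measured$mean[i] + measured$sd[i]))
  names(fixed) <- measured$reaction
  S <- stoich_matrix(net)
  bnd <- default_bounds(net)
  if (!is.null(uptake_bounds)) bnd <- apply_uptake_bounds(bnd, uptake_bounds)
  bnd <- impose_fixed(bnd, fixed)
  obj <- as.numeric(net$reactions$id == net$biomass_id)
  ph1 <- solve_lp(obj, S, bnd$lb, bnd$ub, maximize = TRUE)
  if (ph1$status != "optimal")
    stop("reference construction infeasible: measurements conflict with ",
         "mass balance (status ", ph1$status, ")")
  mu <- ph1$value
  # phase 2: FVA for unmeasured reactions at fixed biomass
  unmeasured <- setdiff(net$reactions$id,
                        c(measured$reaction, net$biomass_id))
  bnd2 <- bnd
  # fix biomass at its optimum with a whisker of numerical slack: the
  # optimal value is an LP output and may be unattainable exactly
  slack <- 1e-9 * max(1, abs(mu))
  bnd2$lb[net$biomass_id] <- mu - slack
  bnd2$ub[net$biomass_id] <- mu + slack
  lo <- bnd2$lb; hi <- bnd2$ub
  for (r in unmeasured) {
    o <- as.numeric(net$reactions$id == r)
    a <- solve_lp(o, S, bnd2$lb, bnd2$ub, maximize = FALSE)
    b <- solve_lp(o, S, bnd2$lb, bnd2$ub, maximize = TRUE)
    if (a$status != "optimal" || b$status != "optimal")
      stop("phase-2 variability infeasible for reaction ", r)
    lo[r] <- a$value; hi[r] <- b$value
  }
  fva <- data.frame(reaction = unmeasured, min = lo[unmeasured],
                    max = hi[unmeasured], stringsAsFactors = FALSE)
  # phase 3: biomass-optimal point inside the FVA box, min ||v||_1
  # tie-break; if the exact box (whose faces are LP optima themselves)
  # is numerically infeasible, widen it by a whisker and retry
  v <- NULL
  for (eps_rel in c(0, 1e-9, 1e-7)) {
    eps <- eps_rel * pmax(1, abs(lo), abs(hi))
    v <- tryCatch(l1_min_point(S, lo - eps, hi + eps),
                  error = function(e) NULL)
    if (!is.null(v)) break
  }
  if (is.null(v)) stop("phase-3 L1 programme infeasible")
  names(v) <- net$reactions$id
  resid <- max(abs(S %*% v))
  if (resid > 1e-8) stop("reference flux mass-balance residual ", resid)
  conc <- rep(1, nrow(net$metabolites))
  names(conc) <- net$metabolites$id
  structure(list(v = v, biomass = mu, fva = fva, conc = conc,
                 conc_ranges = net$metabolites[, c("id", "conc_lo",
                                                  "conc_hi")]),
            class = "reference_state")
}

# minimize sum |v| s.t. S v = 0, lo <= v <= hi  (v = p - q split; exact
# because the per-variable split intervals reproduce [lo, hi])
l1_min_point <- function(S, lo, hi) {
  n <- ncol(S)
  plo <- pmax(lo, 0); phi <- pmax(hi, 0)
  qlo <- pmax(-hi, 0); qhi <- pmax(-lo, 0)
  S2 <- cbind(S, -S)
  sol <- solve_lp(rep(1, 2 * n), S2, c(plo, qlo), c(phi, qhi),
                  maximize = FALSE)
  if (sol$status != "optimal") stop("phase-3 L1 programme infeasible")
  sol$v[seq_len(n)] - sol$v[n + seq_len(n)]
}

#' Reactions fully coupled to biomass
#'
#' Fixes the biomass flux at 1 (uptakes free within bounds) and returns
#' the reactions whose flux is then uniquely determined, i.e. whose
#' flux-to-biomass ratio is fixed by stoichiometry.  Measured biomass
#' therefore resolves these fluxes, which is how the measured set is
#' augmented beyond central metabolism.
#'
#' @param net a `metabolic_network`.
#' @param tol coincidence tolerance on the ratio, default 1e-9.
#' @param uptake_bounds named numeric of uptake caps.
#' @return character vector of coupled reaction ids (with attribute
#'   `ratio`: the fixed flux per unit biomass).
#' @export
biomass_coupled_reactions <- function(net, tol = 1e-9,
                                      uptake_bounds = NULL) {
  if (is.na(net$biomass_id)) stop("no biomass reaction designated")
  fva <- flux_variability(net, fixed = stats::setNames(list(1),
                                                       net$biomass_id),
                          uptake_bounds = uptake_bounds)
  coupled <- abs(fva$max - fva$min) < tol
  ids <- fva$reaction[coupled]
  structure(ids, ratio = stats::setNames((fva$min + fva$max)[coupled] / 2,
                                         ids))
}

#' Minimization-of-metabolic-adjustment prediction
#'
#' Quadratic programme: the mutant flux vector closest (Euclidean) to the
#' wild-type reference, under mass balance and knockout bounds.
#'
#' @param net a `metabolic_network`.
#' @param gt a `\link{genotype}`.
#' @param reference_flux named wild-type flux vector (typically the FBA
#'   solution or a `reference_state$v`).
#' @param uptake_bounds named numeric of uptake caps.
#' @return list with `v`, `distance` (Euclidean) and `status`.
#' @export
moma_predict <- function(net, gt, reference_flux, uptake_bounds = NULL) {
  S <- stoich_matrix(net)
  bnd <- default_bounds(net)
  if (!is.null(uptake_bounds)) bnd <- apply_uptake_bounds(bnd, uptake_bounds)
  bnd <- apply_genotype_bounds(net, gt, bnd)
  ref <- reference_flux[net$reactions$id]
  sol <- solve_qp_projection(ref, S, bnd$lb, bnd$ub)
  if (sol$status != "optimal")
    return(list(v = NULL, distance = NA_real_, status = sol$status))
  list(v = sol$v, distance = sqrt(max(sol$value, 0)), status = "optimal")
}

#' Maximum-product-yield prediction
#'
#' Maximizes the product flux under knockout bounds with growth only
#' required to be non-negative; the theoretical stoichiometric envelope.
#'
#' @param net a `metabolic_network`.
#' @param gt a `\link{genotype}`.
#' @param product_reaction id of the product-forming/exchange reaction.
#' @param uptake_bounds named numeric of uptake caps.
#' @return list with `v`, `product_flux` and `status`.
#' @export
max_yield_predict <- function(net, gt, product_reaction,
                              uptake_bounds = NULL) {
  stopifnot(product_reaction %in% net$reactions$id)
  sol <- fba_predict(net, gt, objective = product_reaction,
                     uptake_bounds = uptake_bounds)
  list(v = sol$v, product_flux = sol$objective_value, status = sol$status)
}
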
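#' @title Anchored elementary kinetics
#' @description Sampling of reaction reversibilities and enzyme fractions,
#'   anchoring of elementary rate constants to a reference flux state, and
#'   steady-state simulation of perturbed models.
#'
#'   The reversibility of an elementary step is the ratio of its backward
#'   to forward rate at the reference state; with net reference flux
#'   `V` through the catalytic cycle, the forward and backward elementary
#'   fluxes are `V/(1-R)` and `V*R/(1-R)`.  Enzyme fractions are the
#'   enzyme-form concentrations normalized by the pool total; metabolite
#'   concentrations are normalized by their wild-type values, so the
#'   reference state is all-ones in the metabolites.  Rate constants are
#'   back-computed so that the reference state is an exact fixed point of
#'   the mass-action ODE system.
#' @name kinetics
NULL

R_CAP_DELTA <- 1e-6   # reversibilities sampled in [0, 1 - delta]

#' Anchor elementary rate constants to a reference state
#'
#' @param en an `elementary_network`.
#' @param reference a `reference_state` (from
#'   `\link{compute_reference_flux}`) or a named flux vector per reaction.
#' @param R named numeric of reversibilities per step id (regulatory,
#'   exchange and zero-flux steps may be present; irrelevant entries are
#'   ignored where the step direction forces them).
#' @param fractions named list per pool id: named numeric over the pool's
#'   forms, each in `[0,1]`, summing to 1.
#' @param pool_ref named numeric per pool: share of the parent reaction's
#'   flux carried by this pool at reference (1 for single-enzyme
#'   reactions; isozyme shares sum to 1 per reaction).
#' @param equil_scale named numeric per step: sampled exchange-flux scale
#'   (in units of the uptake basis) used for steps with zero net
#'   reference flux, including the regulatory dead-end steps.
#' @param basis uptake basis, default 100.
#' @return data.frame per step: `id`, `kf`, `kb`.
#' @export
anchor_rate_constants <- function(en, reference, R, fractions, pool_ref,
                                  equil_scale, basis = 100) {
  vref <- if (inherits(reference, "reference_state")) reference$v
          else reference
  conc <- reference_concentrations(en, fractions, pool_ref)
  steps <- en$steps
  kf <- kb <- numeric(nrow(steps))
  for (s in seq_len(nrow(steps))) {
    V <- vref[[steps$reaction[s]]]
    if (is.null(V) || is.na(V))
      stop("no reference flux for reaction ", steps$reaction[s])
    if (!is.na(steps$pool[s])) V <- V * pool_ref[[steps$pool[s]]]
    if (steps$regulatory[s] && steps$kind[s] == "regulatory") V <- 0
    a <- activity(conc, steps$reactants[[s]])
    b <- activity(conc, steps$products[[s]])
    if (steps$kind[s] == "exchange") {
      if (V > 0) { kf[s] <- V / a; kb[s] <- 0 }
      else if (V < 0) { kf[s] <- 0; kb[s] <- -V / b }
      else {
        s0 <- equil_scale[[steps$id[s]]] * basis
        kf[s] <- s0 / a; kb[s] <- s0 / b
      }
      next
    }
    Rs <- min(max(R[[steps$id[s]]], 0), 1 - R_CAP_DELTA)
    if (V > 0) { vf <- V / (1 - Rs); vb <- V * Rs / (1 - Rs) }
    else if (V < 0) { vf <- -V * Rs / (1 - Rs); vb <- -V / (1 - Rs) }
    else { vf <- vb <- equil_scale[[steps$id[s]]] * basis }
    if (vf > 0 && a <= 0)
      stop("zero reference activity on reactant side of step ",
           steps$id[s], " (an enzyme fraction is 0)")
    if (vb > 0 && b <= 0)
      stop("zero reference activity on product side of step ",
           steps$id[s], " (an enzyme fraction is 0)")
    kf[s] <- if (vf > 0) vf / a else 0
    kb[s] <- if (vb > 0) vb / b else 0
  }
  data.frame(id = steps$id, kf = kf, kb = kb, stringsAsFactors = FALSE)
}

# reference concentration of every species: metabolites 1, enzyme forms
# fraction * pool share
reference_concentrations <- function(en, fractions, pool_ref) {
  conc <- rep(1, nrow(en$species))
  names(conc) <- en$species$id
  ef <- en$species$type == "enzyme_form"
  if (any(ef))
    conc[ef] <- vapply(which(ef), function(i) {
      p <- en$species$pool[i]
      fractions[[p]][[en$species$id[i]]] * pool_ref[[p]]
    }, numeric(1))
  conc
}

activity <- function(conc, side) {
  if (!length(side)) return(1)
  prod(conc[names(side)]^side)
}

#' Sample one anchored parameterization
#'
#' Reversibilities are drawn uniformly on `[0, 1 - 1e-6]` per elementary
#' step; enzyme fractions per pool uniformly on the simplex (symmetric
#' Dirichlet(1)); isozyme flux shares per multi-enzyme reaction on the
#' simplex; zero-flux/equilibrium step scales log-uniform-free
#' `Uniform(0.01, 1)` in units of the uptake basis.  Constants are then
#' anchored so the reference state is an exact fixed point.
#'
#' @param en an `elementary_network`.
#' @param reference a `reference_state` or named flux vector.
#' @param seed optional integer; when given, sampling is reproducible and
#'   the seed is recorded in the parameterization.
#' @param basis uptake basis, default 100.
#' @return a `parameterization`: list with `steps` (data.frame `id`,
#'   `reaction`, `R`, `equil_scale`, `kf`, `kb`), `fractions`,
#'   `pool_ref`, `e_level` (normalized enzyme levels, all 1), `basis`,
#'   `seed`.
#' @export
sample_parameterization <- function(en, reference, seed = NULL,
                                    basis = 100) {
  if (!is.null(seed)) set.seed(seed)
  steps <- en$steps
  R <- stats::runif(nrow(steps), 0, 1 - R_CAP_DELTA)
  names(R) <- steps$id
  equil_scale <- stats::runif(nrow(steps), 0.01, 1)
  names(equil_scale) <- steps$id
  fractions <- lapply(seq_len(nrow(en$pools)), function(i) {
    f <- en$pools$forms[[i]]
    x <- stats::rexp(length(f))
    stats::setNames(x / sum(x), f)
  })
  names(fractions) <- en$pools$id
  pool_ref <- rep(1, nrow(en$pools))
  names(pool_ref) <- en$pools$id
  for (r in unique(en$pools$reaction)) {
    ps <- en$pools$id[en$pools$reaction == r]
    if (length(ps) > 1L) {
      x <- stats::rexp(length(ps))
      pool_ref[ps] <- x / sum(x)
    }
  }
  k <- anchor_rate_constants(en, reference, R, fractions, pool_ref,
                             equil_scale, basis)
  vref <- if (inherits(reference, "reference_state")) reference$v
          else reference
  structure(list(
    steps = data.frame(id = steps$id, reaction = steps$reaction,
                       R = unname(R), equil_scale = unname(equil_scale),
                       kf = k$kf, kb = k$kb, stringsAsFactors = FALSE),
    fractions = fractions, pool_ref = pool_ref,
    pool_reaction = stats::setNames(en$pools$reaction, en$pools$id),
    e_level = stats::setNames(rep(1, nrow(en$pools)), en$pools$id),
    reference_flux = vref[en$network$reactions$id],
    basis = basis, seed = seed),
    class = "parameterization")
}

#' Re-anchor a parameterization
#'
#' Recomputes `kf`/`kb` from the stored reversibilities, fractions and
#' shares; used after mutation/crossover (a no-op check for untouched
#' blocks).
#'
#' @param en an `elementary_network`.
#' @param param a `parameterization`.
#' @return the parameterization with refreshed constants.
#' @export
reanchor <- function(en, param) {
  k <- anchor_rate_constants(
    en, param$reference_flux,
    stats::setNames(param$steps$R, param$steps$id),
    param$fractions, param$pool_ref,
    stats::setNames(param$steps$equil_scale, param$steps$id),
    param$basis)
  param$steps$kf <- k$kf
  param$steps$kb <- k$kb
  param
}

#' Compile an elementary network for the native solver
#'
#' Flattens step reactant/product lists into index arrays; also records
#' the step used to read off each original reaction's net flux (the
#' conversion step of each pool, or the single lumped/exchange step).
#'
#' @param en an `elementary_network`.
#' @return opaque list consumed by `\link{solve_steady_state}`.
#' @export
compile_elementary <- function(en) {
  sp <- en$species$id
  idx <- function(side) match(names(side), sp) - 1L
  rl <- en$steps$reactants; pl <- en$steps$products
  comp <- list(
    n_species = length(sp), n_steps = nrow(en$steps),
    r_ptr = c(0L, cumsum(lengths(rl))),
    r_idx = as.integer(unlist(lapply(rl, idx))),
    r_cnt = as.numeric(unlist(rl, use.names = FALSE)),
    p_ptr = c(0L, cumsum(lengths(pl))),
    p_idx = as.integer(unlist(lapply(pl, idx))),
    p_cnt = as.numeric(unlist(pl, use.names = FALSE)))
  # flux read-off: conversion step per pool, lumped/exchange steps
  fsel <- which(en$steps$kind %in% c("conversion", "lumped", "exchange"))
  comp$flux_step <- fsel
  comp$flux_reaction <- en$steps$reaction[fsel]
  comp$species <- sp
  comp$species_type <- en$species$type
  comp$species_pool <- en$species$pool
  comp$reactions <- en$network$reactions$id
  comp
}

#' Perturbation of enzyme levels and boundary conditions
#'
#' @param e_level named numeric: normalized total enzyme level per enzyme
#'   id or pool id (reference 1, knockout 0); entries are clipped to
#'   `[0, 10]`.
#' @param uptake named numeric: overrides of exchange-reaction clamped
#'   rates (uptake basis units).
#' @param clamp named numeric: metabolite concentrations to clamp.
#' @return a `perturbation` object.
#' @export
perturbation <- function(e_level = numeric(), uptake = numeric(),
                         clamp = numeric()) {
  if (length(e_level)) {
    clipped <- pmin(pmax(e_level, 0), 10)
    if (any(clipped != e_level))
      warning("enzyme level(s) clipped to [0, 10]: ",
              paste(names(e_level)[clipped != e_level], collapse = ", "))
    e_level <- clipped
  }
  structure(list(e_level = e_level, uptake = uptake, clamp = clamp),
            class = "perturbation")
}

#' Map a genotype onto a parameterization
#'
#' Knockouts set the normalized total pool of the enzyme to zero.
#' Deleting one isozyme of a reaction zeroes its pool and flags the
#' surviving pools as free fit variables in `[0, 1]` (sum over the
#' reaction's isozymes at most 1), since the extent of complementation
#' by the remaining isozyme is not known a priori.  Requested enzyme
#' fold changes are clipped to `[0, 10]` with a warning.
#'
#' @param param a `parameterization`.
#' @param gt a `\link{genotype}`.
#' @param en the `elementary_network` the parameterization belongs to.
#' @return the perturbed `parameterization`, with attribute `fit_free`:
#'   character vector of pool ids whose level is to be estimated.
#' @export
apply_perturbation <- function(param, gt, en) {
  check_genotype(en$network, gt)
  pools <- en$pools
  fit_free <- character()
  for (e in gt$ko) param$e_level[pools$id[pools$enzyme == e]] <- 0
  for (e in gt$iso_ko) {
    hit <- pools$id[pools$enzyme == e]
    if (!length(hit)) stop("unknown enzyme id: ", e)
    param$e_level[hit] <- 0
    rxs <- pools$reaction[pools$enzyme == e]
    surv <- pools$id[pools$reaction %in% rxs & pools$enzyme != e &
                       param$e_level[pools$id] > 0]
    fit_free <- union(fit_free, surv)
  }
  for (e in names(gt$levels)) {
    val <- gt$levels[[e]]
    val <- pmin(pmax(val, 0), 10)
    if (any(val != gt$levels[[e]]))
      warning("enzyme level for ", e, " clipped to [0, 10]")
    hit <- pools$id[pools$enzyme == e]
    if (length(val) == 1L) param$e_level[hit] <- val
    else attr(param, "level_box") <-
        c(attr(param, "level_box"), stats::setNames(list(val), e))
  }
  attr(param, "fit_free") <- fit_free
  param
}

#' Mass-action right-hand side evaluator
#'
#' Builds a pure-R evaluator of the ODE right-hand side and elementary
#' rates, independent of the native solver; used as the residual oracle
#' in the test suite and for small ad hoc integrations.
#'
#' @param en an `elementary_network`.
#' @param param a `parameterization`.
#' @return list of functions: `rhs(x)` mapping named concentrations to
#'   time derivatives, and `rates(x)` giving per-step net rates.
#' @export
build_odes <- function(en, param) {
  steps <- en$steps
  kf <- param$steps$kf
  kb <- param$steps$kb
  rates <- function(x) {
    vapply(seq_len(nrow(steps)), function(s) {
      r <- steps$reactants[[s]]; p <- steps$products[[s]]
      kf[s] * (if (length(r)) prod(x[names(r)]^r) else 1) -
        kb[s] * (if (length(p)) prod(x[names(p)]^p) else 1)
    }, numeric(1))
  }
  rhs <- function(x) {
    rt <- rates(x)
    dx <- stats::setNames(rep(0, length(x)), names(x))
    for (s in seq_len(nrow(steps))) {
      r <- steps$reactants[[s]]; p <- steps$products[[s]]
      if (length(r)) dx[names(r)] <- dx[names(r)] - r * rt[s]
      if (length(p)) dx[names(p)] <- dx[names(p)] + p * rt[s]
    }
    dx
  }
  list(rhs = rhs, rates = rates)
}

#' Initial (reference) state of a parameterized model
#'
#' Metabolites at 1 (or clamped values); enzyme forms at
#' `fraction * pool share * normalized level`.
#'
#' @param en an `elementary_network`.
#' @param param a `parameterization`.
#' @param pert optional `\link{perturbation}`.
#' @return named numeric over species.
#' @export
initial_state <- function(en, param, pert = perturbation()) {
  x <- rep(1, nrow(en$species))
  names(x) <- en$species$id
  ef <- which(en$species$type == "enzyme_form")
  lev <- effective_levels(en, param, pert)
  for (i in ef) {
    p <- en$species$pool[i]
    x[i] <- param$fractions[[p]][[en$species$id[i]]] *
      param$pool_ref[[p]] * lev[[p]]
  }
  if (length(pert$clamp)) x[names(pert$clamp)] <- pert$clamp
  x
}

# normalized level per pool after a perturbation (perturbation entries
# may be keyed by pool id or by enzyme id)
effective_levels <- function(en, param, pert) {
  lev <- param$e_level
  for (nm in names(pert$e_level)) {
    hit <- if (nm %in% en$pools$id) nm
           else en$pools$id[en$pools$enzyme == nm]
    if (!length(hit)) stop("unknown enzyme or pool id: ", nm)
    lev[hit] <- pert$e_level[[nm]]
  }
  lev
}

#' Solve for a perturbed steady state
#'
#' Starts from the (perturbed) reference state and drives the stiff
#' mass-action system to `||dC/dt||_inf < tol` by pseudo-transient
#' continuation with Newton polish.  Fluxes are read per original
#' reaction from the catalytic-cycle conversion steps (all cycle steps
#' carry equal net flux at steady state).
#'
#' @param en an `elementary_network`.
#' @param param a `parameterization`.
#' @param pert a `\link{perturbation}`.
#' @param compiled optional precompiled network
#'   (`\link{compile_elementary}`) to avoid recompilation in loops.
#' @param tol steady-state tolerance on `||dC/dt||_inf`, default 1e-9.
#' @param max_time pseudo-time horizon, default 1e6.
#' @return a `steady_state_result`: list with `conc` (named species
#'   concentrations), `flux` (named net flux per original reaction),
#'   `converged`, `residual`, `pool_drift` (max deviation of any pool
#'   total from its target) and `iterations`.
#' @export
solve_steady_state <- function(en, param, pert = perturbation(),
                               compiled = NULL, tol = 1e-9,
                               max_time = 1e6) {
  if (is.null(compiled)) compiled <- compile_elementary(en)
  x0 <- initial_state(en, param, pert)
  kf <- param$steps$kf
  kb <- param$steps$kb
  # uptake overrides rescale the constant-rate exchange steps
  if (length(pert$uptake)) {
    for (r in names(pert$uptake)) {
      sel <- which(en$steps$reaction == r & en$steps$kind == "exchange")
      if (!length(sel)) stop("no exchange step for reaction ", r)
      Vref <- param$reference_flux[[r]]
      if (is.null(Vref) || Vref == 0)
        stop("cannot rescale exchange ", r, " with zero reference flux")
      sc <- pert$uptake[[r]] / Vref
      kf[sel] <- kf[sel] * sc
      kb[sel] <- kb[sel] * sc
    }
  }
  clamped <- en$species$id %in% names(pert$clamp)
  out <- .kinens_solve_ss(compiled, x0, kf, kb, clamped,
                          tol = tol, max_time = max_time)
  x <- stats::setNames(out$x, compiled$species)
  flux <- flux_from_rates(compiled, out$rates)
  drift <- pool_drift(en, param, pert, x)
  structure(list(conc = x, flux = flux, converged = out$converged,
                 residual = out$residual, pool_drift = drift,
                 iterations = out$iterations, time = out$time),
            class = "steady_state_result")
}

flux_from_rates <- function(compiled, rates) {
  v <- rowsum(rates[compiled$flux_step],
              group = compiled$flux_reaction, reorder = FALSE)
  flux <- stats::setNames(rep(0, length(compiled$reactions)),
                          compiled$reactions)
  flux[rownames(v)] <- v[, 1]
  flux
}

pool_drift <- function(en, param, pert, x) {
  if (!nrow(en$pools)) return(0)
  lev <- effective_levels(en, param, pert)
  target <- param$pool_ref * lev[names(param$pool_ref)]
  tot <- vapply(seq_len(nrow(en$pools)), function(i)
    sum(x[en$pools$forms[[i]]]), numeric(1))
  max(abs(tot - target[en$pools$id]))
}

#' @export
print.parameterization <- function(x, ...) {
  cat("parameterization: ", nrow(x$steps), " elementary steps, ",
      length(x$fractions), " enzyme pools",
      if (!is.null(x$seed)) paste0(" (seed ", x$seed, ")"), "\n", sep = "")
  invisible(x)
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat("steady state: converged=", x$converged,
      ", residual=", format(x$residual, digits = 3),
      ", pool drift=", format(x$pool_drift, digits = 3), "\n", sep = "")
  invisible(x)
}
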
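#' @title Two-stage genetic-algorithm parameter estimation
#' @description Stage 1 estimates the elementary kinetic parameters (and
#'   surviving-isozyme activity for isozyme-deletion strains) against the
#'   aerobic-glucose knockout flux data sets; stage 2 fixes those
#'   parameters and estimates condition-specific total enzyme levels (the
#'   Michaelis-Menten `v_max`) for other growth conditions.  Selection
#'   minimizes the CV-scaled average relative flux deviation `z`; the
#'   recombination operator exchanges whole per-reaction parameter blocks
#'   between models, which keeps every offspring anchored to the
#'   reference state by construction.
#' @name ga_fit
NULL

#' GA configuration
#'
#' @param pop_size population size P (>= 2), default 256.
#' @param generations number of generations G, default 60.
#' @param crossover_prob probability of recombining a selected pair,
#'   default 0.9.
#' @param mutation_prob per-reaction probability of resampling that
#'   reaction's parameter block, default 0.05.
#' @param tournament tournament size for selection, default 4.
#' @param elitism number of best individuals copied unchanged, default 1.
#' @param seed RNG seed; fixed seed gives bit-identical fits.
#' @param penalty objective value assigned to non-converged steady
#'   states, default 1e6 (far above any achievable z on valid data).
#' @return a `ga_config` object.
#' @export
ga_config <- function(pop_size = 256, generations = 60,
                      crossover_prob = 0.9, mutation_prob = 0.05,
                      tournament = 4, elitism = 1, seed = 1L,
                      penalty = 1e6) {
  stopifnot(pop_size >= 2, crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1, penalty > 0)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 tournament = as.integer(tournament),
                 elitism = as.integer(elitism), seed = as.integer(seed),
                 penalty = penalty),
            class = "ga_config")
}

#' CV-scaled average relative flux deviation
#'
#' `z = (1/M) * sum_m (1/N_m) * sum_j (1/CV_j) |v_j - v_j^exp| /
#' max(|v_j^exp|, eps)`: the average relative error of each measured
#' reaction, weighted by the reciprocal of its coefficient of variation
#' so that reactions with tighter confidence intervals contribute more.
#' Non-converged mutants contribute the penalty value.
#'
#' @param predictions list (one per data set) with elements `flux`
#'   (named numeric) and `converged` (logical).
#' @param datasets list of `flux_dataset` objects of equal length.
#' @param penalty value for non-converged entries, default 1e6.
#' @param eps_frac floor on `|v^exp|` as a fraction of the uptake basis,
#'   default 1e-3 (i.e. 0.1 on the basis-100 scale).
#' @return scalar z.
#' @export
objective_z <- function(predictions, datasets, penalty = 1e6,
                        eps_frac = 1e-3) {
  stopifnot(length(predictions) == length(datasets))
  zs <- vapply(seq_along(datasets), function(m) {
    ds <- datasets[[m]]; pr <- predictions[[m]]
    if (is.null(pr) || !isTRUE(pr$converged)) return(penalty)
    eps <- eps_frac * ds$uptake$basis
    me <- ds$measurements
    if (any(me$cv <= 0)) stop("nonpositive CV in data set ", ds$strain)
    v <- pr$flux[me$reaction]
    if (anyNA(v)) stop("missing prediction for data set ", ds$strain)
    mean((1 / me$cv) * abs(v - me$mean) / pmax(abs(me$mean), eps))
  }, numeric(1))
  mean(zs)
}

#' Reaction-block recombination
#'
#' For each original reaction, the full parameter block (reversibilities,
#' equilibrium scales, anchored constants of its steps; fractions and
#' flux shares of its pools; any isozyme-activity genes tied to it) is
#' swapped between the parents with probability 1/2.  Blocks are
#' self-consistently anchored, so children need no re-anchoring.
#'
#' @param a,b parent `parameterization`s over the same elementary
#'   network.
#' @return list with `a` and `b`, the two children.
#' @export
crossover <- function(a, b) {
  if (!identical(a$steps$id, b$steps$id))
    stop("parents are parameterizations of different elementary networks")
  rxns <- unique(a$steps$reaction)
  swap <- stats::runif(length(rxns)) < 0.5
  names(swap) <- rxns
  srx <- rxns[swap]
  if (length(srx)) {
    rows <- a$steps$reaction %in% srx
    tmp <- a$steps[rows, ]; a$steps[rows, ] <- b$steps[rows, ]
    b$steps[rows, ] <- tmp
    prx <- a$pool_reaction[names(a$fractions)] %in% srx
    for (p in names(a$fractions)[prx]) {
      tmp <- a$fractions[[p]]; a$fractions[[p]] <- b$fractions[[p]]
      b$fractions[[p]] <- tmp
      tmp <- a$pool_ref[[p]]; a$pool_ref[[p]] <- b$pool_ref[[p]]
      b$pool_ref[[p]] <- tmp
    }
    if (!is.null(a$iso_tau)) {
      key_rxn <- sub("^[^:]+:", "", names(a$iso_tau))
      sel <- key_rxn %in% srx
      tmp <- a$iso_tau[sel]; a$iso_tau[sel] <- b$iso_tau[sel]
      b$iso_tau[sel] <- tmp
    }
  }
  list(a = a, b = b)
}

# resample the parameter block of each reaction hit by mutation and
# re-anchor the individual
mutate_individual <- function(ind, en, reference, prob) {
  rxns <- unique(en$steps$reaction)
  hit <- rxns[stats::runif(length(rxns)) < prob]
  if (!length(hit) && is.null(ind$iso_tau)) return(ind)
  for (r in hit) {
    rows <- which(ind$steps$reaction == r)
    ind$steps$R[rows] <- stats::runif(length(rows), 0, 1 - R_CAP_DELTA)
    ind$steps$equil_scale[rows] <- stats::runif(length(rows), 0.01, 1)
    ps <- en$pools$id[en$pools$reaction == r]
    for (p in ps) {
      x <- stats::rexp(length(ind$fractions[[p]]))
      ind$fractions[[p]][] <- x / sum(x)
    }
    if (length(ps) > 1L) {
      x <- stats::rexp(length(ps))
      ind$pool_ref[ps] <- x / sum(x)
    }
    if (!is.null(ind$iso_tau)) {
      sel <- sub("^[^:]+:", "", names(ind$iso_tau)) == r
      ind$iso_tau[sel] <- stats::runif(sum(sel))
    }
  }
  if (length(hit)) ind <- reanchor(en, ind)
  ind
}

# predicted fluxes of one individual for one data set
predict_dataset <- function(en, compiled, ind, ds) {
  p <- apply_perturbation(ind, ds$genotype, en)
  fit_free <- attr(p, "fit_free")
  if (length(fit_free) && !is.null(ind$iso_tau)) {
    # surviving-isozyme pools: gene tau = remaining total enzyme in [0,1]
    for (r in unique(en$pools$reaction[en$pools$id %in% fit_free])) {
      key <- paste0(ds$strain, ":", r)
      if (key %in% names(ind$iso_tau)) {
        surv <- intersect(fit_free, en$pools$id[en$pools$reaction == r])
        wsum <- sum(p$pool_ref[surv])
        if (wsum > 0) p$e_level[surv] <- ind$iso_tau[[key]] / wsum
      }
    }
  }
  ss <- solve_steady_state(en, p, compiled = compiled)
  list(flux = ss$flux, converged = ss$converged)
}

evaluate_z <- function(en, compiled, ind, datasets, penalty) {
  preds <- lapply(datasets, function(ds)
    predict_dataset(en, compiled, ind, ds))
  objective_z(preds, datasets, penalty = penalty)
}

# generic GA engine over a list population with user hooks
run_ga <- function(pop, fitness, breed, config, trace_label = NULL) {
  z <- vapply(pop, fitness, numeric(1))
  if (all(z >= config$penalty))
    stop("all individuals penalized in generation 0: no parameterization ",
         "reaches a converged steady state on the training data")
  traj <- numeric(config$generations + 1L)
  traj[1] <- min(z)
  for (g in seq_len(config$generations)) {
    ord <- order(z)
    elite_idx <- ord[seq_len(min(config$elitism, length(pop)))]
    newpop <- pop[elite_idx]
    newz <- z[elite_idx]
    while (length(newpop) < config$pop_size) {
      i <- tournament_pick(z, config$tournament)
      j <- tournament_pick(z, config$tournament)
      pa <- pop[[i]]; pb <- pop[[j]]
      kids <- breed(pa, pb)
      for (k in kids) {
        if (length(newpop) < config$pop_size) {
          newpop[[length(newpop) + 1L]] <- k
          newz <- c(newz, NA_real_)
        }
      }
    }
    miss <- which(is.na(newz))
    newz[miss] <- vapply(newpop[miss], fitness, numeric(1))
    pop <- newpop; z <- newz
    traj[g + 1L] <- min(z)
    if (!is.null(trace_label))
      message(sprintf("%s gen %d: best z = %.5g, mean z = %.5g",
                      trace_label, g, min(z), mean(pmin(z, config$penalty))))
  }
  best <- which.min(z)
  list(best = pop[[best]], z = z[best], trajectory = cummin(traj))
}

tournament_pick <- function(z, k) {
  cand <- sample.int(length(z), min(k, length(z)), replace = FALSE)
  cand[which.min(z[cand])]
}

#' Stage-1 fit: elementary kinetic parameters and isozyme activity
#'
#' GA over anchored parameterizations: the initial population is a
#' sampled ensemble; fitness is `\link{objective_z}` over all training
#' data sets with each strain's genotype applied.  For strains with an
#' isozyme deletion, the remaining total enzyme of the affected reaction
#' is an appended gene in `[0, 1]` (the surviving pools share it in
#' proportion to their reference shares, keeping the isozyme sum at most
#' one).
#'
#' @param en an `elementary_network`.
#' @param reference a `reference_state`.
#' @param datasets list of `flux_dataset` objects (one condition;
#'   typically aerobic glucose knockouts).
#' @param config a `\link{ga_config}`.
#' @param verbose print per-generation progress, default FALSE.
#' @return a `fit_result`: list with `best` (parameterization, including
#'   `iso_tau` genes), `z`, `trajectory` (best z per generation,
#'   non-increasing under elitism), `predictions` (per data set) and
#'   `config`.
#' @export
stage1_fit <- function(en, reference, datasets, config = ga_config(),
                       verbose = FALSE) {
  stopifnot(length(datasets) >= 1L)
  set.seed(config$seed)
  compiled <- compile_elementary(en)
  iso_keys <- stage1_iso_keys(en, datasets)
  make_ind <- function() {
    ind <- sample_parameterization(en, reference)
    if (length(iso_keys))
      ind$iso_tau <- stats::setNames(stats::runif(length(iso_keys)),
                                     iso_keys)
    ind
  }
  pop <- replicate(config$pop_size, make_ind(), simplify = FALSE)
  fitness <- function(ind) evaluate_z(en, compiled, ind, datasets,
                                      config$penalty)
  breed <- function(a, b) {
    if (stats::runif(1) < config$crossover_prob) {
      kids <- crossover(a, b)
    } else kids <- list(a = a, b = b)
    lapply(kids, mutate_individual, en = en, reference = reference,
           prob = config$mutation_prob)
  }
  out <- run_ga(pop, fitness, breed, config,
                trace_label = if (verbose) "stage1")
  preds <- lapply(datasets, function(ds)
    predict_dataset(en, compiled, out$best, ds))
  names(preds) <- vapply(datasets, `[[`, "", "strain")
  structure(list(best = out$best, z = out$z, trajectory = out$trajectory,
                 predictions = preds, config = config, stage = 1L),
            class = "fit_result")
}

stage1_iso_keys <- function(en, datasets) {
  keys <- character()
  for (ds in datasets) {
    for (e in ds$genotype$iso_ko) {
      rxs <- en$pools$reaction[en$pools$enzyme == e]
      for (r in rxs) {
        surv <- en$pools$enzyme[en$pools$reaction == r &
                                  en$pools$enzyme != e]
        if (length(surv))
          keys <- c(keys, paste0(ds$strain, ":", r))
      }
    }
  }
  unique(keys)
}

#' Stage-2 fit: condition-specific enzyme levels
#'
#' The stage-1 elementary parameters (the Michaelis-Menten `K_m`) are
#' frozen; only the normalized total enzyme levels of a whitelisted
#' enzyme set vary, each in `[0, 10]` (zero = deletion, 10 = ten-fold
#' overexpression), one fit per condition group.  The whitelist is kept
#' small deliberately to avoid overparameterization.
#'
#' @param stage1_result a stage-1 `fit_result` (or a bare
#'   `parameterization`).
#' @param en the `elementary_network`.
#' @param datasets data sets of one non-reference condition.
#' @param whitelist character vector of enzyme ids allowed to vary; empty
#'   means no degrees of freedom (levels stay at 1).
#' @param config a `\link{ga_config}` (smaller defaults are sensible
#'   here: few genes).
#' @return a `fit_result` with `e_level` (fitted normalized levels per
#'   whitelisted enzyme), `z`, `trajectory`, `predictions`.
#' @export
stage2_fit <- function(stage1_result, en, datasets,
                       whitelist = character(), config = ga_config(),
                       verbose = FALSE) {
  base <- if (inherits(stage1_result, "fit_result")) stage1_result$best
          else stage1_result
  set.seed(config$seed)
  compiled <- compile_elementary(en)
  conds <- unique(vapply(datasets, `[[`, "", "condition"))
  if (length(conds) > 1L)
    stop("stage2_fit handles one condition group per call; got: ",
         paste(conds, collapse = ", "))
  with_levels <- function(lev) {
    p <- base
    for (e in names(lev)) p$e_level[en$pools$id[en$pools$enzyme == e]] <- lev[[e]]
    p
  }
  fitness <- function(lev) evaluate_z(en, compiled, with_levels(lev),
                                      datasets, config$penalty)
  if (!length(whitelist)) {
    lev <- stats::setNames(numeric(0), character(0))
    z <- fitness(lev)
    if (z > 0)
      warning("empty whitelist with nonzero misfit (z = ",
              format(z, digits = 4), ")")
    preds <- lapply(datasets, function(ds)
      predict_dataset(en, compiled, base, ds))
    return(structure(list(best = base, e_level = lev, z = z,
                          trajectory = z, predictions = preds,
                          config = config, stage = 2L),
                     class = "fit_result"))
  }
  ng <- length(whitelist)
  make_lev <- function() stats::setNames(10^stats::runif(ng, -1, 1),
                                         whitelist)
  pop <- replicate(config$pop_size, make_lev(), simplify = FALSE)
  breed <- function(a, b) {
    if (stats::runif(1) < config$crossover_prob) {
      sw <- stats::runif(ng) < 0.5
      tmp <- a[sw]; a[sw] <- b[sw]; b[sw] <- tmp
    }
    jitter <- function(x) {
      hit <- stats::runif(ng) < 0.35
      x[hit] <- pmin(pmax(x[hit] * exp(stats::rnorm(sum(hit), 0, 0.3)),
                          0), 10)
      res <- stats::runif(ng) < 0.05
      x[res] <- 10^stats::runif(sum(res), -1, 1)
      x
    }
    list(jitter(a), jitter(b))
  }
  out <- run_ga(pop, fitness, breed, config,
                trace_label = if (verbose) "stage2")
  best_param <- with_levels(out$best)
  preds <- lapply(datasets, function(ds)
    predict_dataset(en, compiled, best_param, ds))
  names(preds) <- vapply(datasets, `[[`, "", "strain")
  structure(list(best = best_param, e_level = out$best, z = out$z,
                 trajectory = out$trajectory, predictions = preds,
                 config = config, stage = 2L),
            class = "fit_result")
}

#' Leave-one-out / leave-two-out cross-validation
#'
#' Refits stage 1 with each fold of data sets excluded and reports the
#' average scaled relative deviation of the held-out strains' predicted
#' fluxes from the full-data fit's predictions for the same strains.
#'
#' @param en an `elementary_network`.
#' @param reference a `reference_state`.
#' @param datasets list of `flux_dataset`s (>= 3).
#' @param config a `\link{ga_config}` (applied to the full fit and every
#'   fold refit).
#' @param mode `"loo"` (folds of 1) or `"lto"` (folds of 2).
#' @param full optional precomputed full-data `fit_result` to reuse.
#' @return data.frame with one row per fold: `fold`, `excluded`,
#'   `deviation` (mean relative deviation of held-out predictions vs the
#'   full fit), `z_refit`.
#' @export
cross_validate <- function(en, reference, datasets, config = ga_config(),
                           mode = c("loo", "lto"), full = NULL) {
  mode <- match.arg(mode)
  fold_size <- if (mode == "loo") 1L else 2L
  if (length(datasets) < 3L) stop("need at least 3 data sets")
  if (length(datasets) <= fold_size) stop("fewer data sets than fold size")
  if (is.null(full)) full <- stage1_fit(en, reference, datasets, config)
  compiled <- compile_elementary(en)
  folds <- utils::combn(length(datasets), fold_size, simplify = FALSE)
  rows <- lapply(seq_along(folds), function(k) {
    idx <- folds[[k]]
    refit <- stage1_fit(en, reference, datasets[-idx], config)
    devs <- vapply(idx, function(i) {
      ds <- datasets[[i]]
      ph <- predict_dataset(en, compiled, refit$best, ds)
      pf <- predict_dataset(en, compiled, full$best, ds)
      eps <- 1e-3 * ds$uptake$basis
      v <- ph$flux[ds$measurements$reaction]
      w <- pf$flux[ds$measurements$reaction]
      mean(abs(v - w) / pmax(abs(w), eps))
    }, numeric(1))
    data.frame(fold = k,
               excluded = paste(vapply(datasets[idx], `[[`, "", "strain"),
                                collapse = "+"),
               deviation = mean(devs), z_refit = refit$z,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result (stage ", x$stage, "): best z = ",
      format(x$z, digits = 5), " after ",
      length(x$trajectory) - 1L, " generations\n", sep = "")
  invisible(x)
}
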
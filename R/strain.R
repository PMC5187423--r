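#' @title Strain-design yield evaluation
#' @description Product-yield prediction for designed (overproducing)
#'   strains with the kinetic ensemble model and with the three
#'   stoichiometric comparators (FBA, MOMA, maximization of product
#'   yield), plus the agreement statistics used to benchmark them:
#'   Pearson correlation with measured yields, the count of designs
#'   predicted within 20% relative error, and grouped mean relative
#'   errors.
#' @name strain_eval
NULL

#' Strain design record
#'
#' @param id design identifier.
#' @param interventions named character: enzyme id -> one of
#'   `"knockout"`, `"upregulate"`, `"downregulate"`.
#' @param product_metabolite product metabolite id.
#' @param product_reaction id of the reaction whose flux is the product
#'   formation rate (typically the exchange).
#' @param y_exp measured yield, mol product per mol substrate (>= 0).
#' @param condition condition label.
#' @param substrate_reaction uptake reaction id, default `"EX_glc"`.
#' @return a `strain_design` object.
#' @export
strain_design <- function(id, interventions, product_metabolite,
                          product_reaction, y_exp,
                          condition = "aerobic_glucose",
                          substrate_reaction = "EX_glc") {
  stopifnot(y_exp >= 0,
            all(interventions %in% c("knockout", "upregulate",
                                     "downregulate")))
  structure(list(id = id, interventions = interventions,
                 product_metabolite = product_metabolite,
                 product_reaction = product_reaction, y_exp = y_exp,
                 condition = condition,
                 substrate_reaction = substrate_reaction),
            class = "strain_design")
}

design_genotype <- function(design) {
  genotype(ko = names(design$interventions)[
    design$interventions == "knockout"])
}

#' Kinetic product-yield prediction for a designed strain
#'
#' Knockouts fix the enzyme's normalized pool at zero.  Reported up- and
#' downregulations rarely come with a fold change, so they are treated
#' as boxes: downregulation allows the pool in `[0.1, 1]` (up to
#' ten-fold down), upregulation in `[1, 10]`; the box is resolved by
#' maximizing the steady-state product flux over a coarse log grid (4
#' points per varied enzyme, at most 3 enzymes varied jointly) followed
#' by Nelder-Mead refinement.
#'
#' @param en an `elementary_network`.
#' @param param a fitted `parameterization`.
#' @param design a `\link{strain_design}`.
#' @param compiled optional precompiled network.
#' @return list with `y` (mol/mol; 0 with `converged = FALSE` when no
#'   steady state exists in the box), `levels` (resolved enzyme levels),
#'   `flux` (the steady-state vector) and `converged`.
#' @export
predict_yield_kinetic <- function(en, param, design, compiled = NULL) {
  if (is.null(compiled)) compiled <- compile_elementary(en)
  iv <- design$interventions
  fixed <- stats::setNames(rep(0, sum(iv == "knockout")),
                           names(iv)[iv == "knockout"])
  boxed <- iv[iv != "knockout"]
  box_lo <- ifelse(boxed == "downregulate", 0.1, 1)
  box_hi <- ifelse(boxed == "downregulate", 1, 10)
  names(box_lo) <- names(box_hi) <- names(boxed)
  if (length(boxed) > 3L) {
    warning("more than 3 bounded interventions; optimizing the first 3 ",
            "jointly and fixing the rest at their nearest bound midpoint")
    keep <- names(boxed)[1:3]
    mid <- sqrt(box_lo * box_hi)
    fixed <- c(fixed, mid[setdiff(names(boxed), keep)])
    box_lo <- box_lo[keep]; box_hi <- box_hi[keep]
  }
  eval_levels <- function(lev) {
    pert <- perturbation(e_level = c(fixed, lev))
    ss <- solve_steady_state(en, param, pert, compiled = compiled)
    if (!ss$converged) return(list(y = -Inf, ss = NULL))
    up <- ss$flux[[design$substrate_reaction]]
    if (abs(up) < 1e-9) return(list(y = -Inf, ss = NULL))
    list(y = ss$flux[[design$product_reaction]] / up, ss = ss)
  }
  if (!length(box_lo)) {
    out <- eval_levels(stats::setNames(numeric(0), character(0)))
    if (!is.finite(out$y))
      return(list(y = 0, levels = fixed, flux = NULL, converged = FALSE))
    return(list(y = max(out$y, 0), levels = fixed, flux = out$ss$flux,
                converged = TRUE))
  }
  # coarse log-spaced grid, then Nelder-Mead on log levels
  grids <- lapply(seq_along(box_lo), function(i)
    exp(seq(log(box_lo[i]), log(box_hi[i]), length.out = 4)))
  grid <- as.matrix(do.call(expand.grid, grids))
  colnames(grid) <- names(box_lo)
  ys <- apply(grid, 1, function(g) eval_levels(g)$y)
  if (all(!is.finite(ys)))
    return(list(y = 0, levels = fixed, flux = NULL, converged = FALSE))
  best <- which.max(ys)
  obj <- function(lg) {
    lev <- pmin(pmax(exp(lg), box_lo), box_hi)
    names(lev) <- names(box_lo)
    y <- eval_levels(lev)$y
    if (!is.finite(y)) 1e6 else -y
  }
  if (length(box_lo) == 1L) {
    opt <- stats::optimize(obj, interval = log(c(box_lo, box_hi)),
                           tol = 1e-4)
    par <- opt$minimum
  } else {
    opt <- stats::optim(log(grid[best, ]), obj, method = "Nelder-Mead",
                        control = list(maxit = 60, reltol = 1e-4))
    par <- opt$par
  }
  lev <- pmin(pmax(exp(par), box_lo), box_hi)
  names(lev) <- names(box_lo)
  out <- eval_levels(lev)
  if (!is.finite(out$y) || out$y < ys[best]) {
    lev <- grid[best, ]
    out <- eval_levels(lev)
  }
  list(y = max(out$y, 0), levels = c(fixed, lev), flux = out$ss$flux,
       converged = TRUE)
}

#' Stoichiometric product-yield prediction
#'
#' Comparator predictions from the constraint-based analyses.  Only
#' knockouts are representable; bounded up/downregulations are ignored
#' with a message (stoichiometric models carry no enzyme levels).
#'
#' @param net a `metabolic_network`.
#' @param design a `\link{strain_design}`.
#' @param method `"FBA"`, `"MOMA"` or `"max-yield"`.
#' @param uptake_bounds named numeric of uptake caps (the substrate cap
#'   defines the yield denominator).
#' @param reference_flux wild-type reference for MOMA (defaults to the
#'   wild-type FBA solution).
#' @return list with `y` and `flux`.
#' @export
predict_yield_stoichiometric <- function(net, design,
                                         method = c("FBA", "MOMA",
                                                    "max-yield"),
                                         uptake_bounds = c(EX_glc = 100),
                                         reference_flux = NULL) {
  method <- match.arg(method)
  iv <- design$interventions
  if (any(iv != "knockout"))
    message("design ", design$id, ": ", sum(iv != "knockout"),
            " non-knockout intervention(s) ignored by ", method)
  gt <- design_genotype(design)
  sol <- switch(method,
    "FBA" = fba_predict(net, gt, uptake_bounds = uptake_bounds),
    "MOMA" = {
      if (is.null(reference_flux))
        reference_flux <- fba_predict(net,
                                      uptake_bounds = uptake_bounds)$v
      moma_predict(net, gt, reference_flux, uptake_bounds = uptake_bounds)
    },
    "max-yield" = max_yield_predict(net, gt, design$product_reaction,
                                    uptake_bounds = uptake_bounds))
  v <- sol$v
  if (is.null(v))
    return(list(y = 0, flux = NULL))
  up <- v[[design$substrate_reaction]]
  y <- if (abs(up) < 1e-9) 0 else v[[design$product_reaction]] / up
  list(y = max(y, 0), flux = v)
}

#' Yield agreement statistics
#'
#' @param records data.frame with columns `design`, `method`, `y_exp`,
#'   `y_pre`, and optionally `product` and `condition`.
#' @param within relative-error threshold for the "within" count,
#'   default 0.20.
#' @return list with `per_method` (data.frame: `method`, `pcc`, `n`,
#'   `n_within`, `mean_rel_error`) and `grouped` (mean relative error by
#'   product/condition when those columns exist).  The correlation is
#'   `NA` with a note when either vector has zero variance.
#' @export
compare_yields <- function(records, within = 0.20) {
  records <- as.data.frame(records)
  stopifnot(all(c("method", "y_exp", "y_pre") %in% names(records)))
  pos <- records$y_exp > 0
  per_method <- do.call(rbind, lapply(split(records, records$method),
                                      function(d) {
    rel <- ifelse(d$y_exp > 0, abs(d$y_exp - d$y_pre) / d$y_exp, NA_real_)
    pcc <- if (nrow(d) >= 2 && stats::sd(d$y_exp) > 0 &&
               stats::sd(d$y_pre) > 0)
      stats::cor(d$y_exp, d$y_pre) else NA_real_
    data.frame(method = d$method[1], pcc = pcc, n = nrow(d),
               n_within = sum(rel <= within, na.rm = TRUE),
               mean_rel_error = mean(rel, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(per_method) <- NULL
  grouped <- NULL
  gcols <- intersect(c("product", "condition"), names(records))
  if (length(gcols)) {
    rec <- records[pos, , drop = FALSE]
    rec$rel <- abs(rec$y_exp - rec$y_pre) / rec$y_exp
    grouped <- stats::aggregate(
      rec["rel"], by = c(rec[gcols], rec["method"]), FUN = mean)
    names(grouped)[names(grouped) == "rel"] <- "mean_rel_error"
  }
  list(per_method = per_method, grouped = grouped)
}
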
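#' @title Michaelis-Menten back-conversion
#' @description An anchored elementary parameterization implies apparent
#'   Michaelis-Menten constants: clamping one substrate over a
#'   logarithmic grid (co-substrates, products, activators and inhibitors
#'   held at their reference levels) and solving the enzyme-form
#'   quasi-steady state traces the flux curve `v(S)`, whose plateau is
#'   `v_max` and whose half-saturation point is the apparent `K_m`.
#'   Because the elementary formalism is scaled by the wild-type
#'   metabolite concentrations, normalized constants are converted to
#'   absolute mM ranges by interval multiplication with the reference
#'   concentration range.
#' @name mm_convert
NULL

#' Apparent Michaelis-Menten constants of one reaction
#'
#' @param en an `elementary_network`.
#' @param param an anchored `parameterization`.
#' @param reaction reaction id (must be catalysed).
#' @param co_substrate_levels named numeric of clamped co-substrate
#'   levels (normalized), default all 1.
#' @param grid_decades half-width of the log10 clamp grid around the
#'   reference level, default 3 (i.e. `[1e-3, 1e3]`); widened once to 6
#'   if the curve has not saturated.
#' @param n_grid points per curve, default 61.
#' @return an `mm_parameters` object: list with `reaction`, `Km` (named
#'   numeric per substrate, normalized units), `vmax` (flux units),
#'   `kcat` (`vmax` per unit total enzyme), `e_total`, `resolved`
#'   (FALSE when a curve never saturates) and `curves` (the raw grids).
#' @export
elementary_to_mm <- function(en, param, reaction,
                             co_substrate_levels = NULL,
                             grid_decades = 3, n_grid = 61) {
  rx <- en$network$reactions[en$network$reactions$id == reaction, ]
  if (!nrow(rx)) stop("unknown reaction: ", reaction)
  if (!length(rx$enzymes[[1]]))
    stop("reaction ", reaction, " is not enzyme-catalysed")
  st <- rx$stoichiometry[[1]]
  substrates <- names(st)[st < 0]
  mets <- en$species$id[en$species$type == "metabolite"]
  compiled <- compile_elementary(en)
  lev <- effective_levels(en, param, perturbation())
  pools <- en$pools$id[en$pools$reaction == reaction]
  e_total <- sum(param$pool_ref[pools] * lev[pools])

  clamp_base <- stats::setNames(rep(1, length(mets)), mets)
  if (!is.null(co_substrate_levels))
    clamp_base[names(co_substrate_levels)] <- co_substrate_levels

  flux_at <- function(clamp) {
    ss <- solve_steady_state(en, param,
                             perturbation(clamp = clamp),
                             compiled = compiled, tol = 1e-11)
    if (!ss$converged) return(NA_real_)
    ss$flux[[reaction]]
  }

  Km <- stats::setNames(rep(NA_real_, length(substrates)), substrates)
  curves <- list()
  resolved <- TRUE
  for (sub in substrates) {
    dec <- grid_decades
    repeat {
      S <- 10^seq(-dec, dec, length.out = n_grid)
      v <- vapply(S, function(s) {
        cl <- clamp_base; cl[sub] <- s
        flux_at(cl)
      }, numeric(1))
      ok <- is.finite(v)
      if (sum(ok) < 5) { resolved <- FALSE; break }
      vmax_est <- max(v[ok])
      # plateau: relative change across the last decade below 0.1%
      last_dec <- S >= max(S) / 10 & ok
      sat <- diff(range(v[last_dec])) < 1e-3 * abs(vmax_est)
      if (sat || dec >= 6) {
        if (!sat) resolved <- FALSE
        curves[[sub]] <- data.frame(S = S[ok], v = v[ok])
        km0 <- half_saturation(S[ok], v[ok])
        # refine: plateau far into saturation, then root-find v = vmax/2
        vm <- flux_at(`[<-`(clamp_base, sub, 1e8 * km0))
        if (is.finite(vm) && is.finite(km0)) {
          g <- function(s) flux_at(`[<-`(clamp_base, sub, s)) - vm / 2
          lo <- km0 / 100; hi <- km0 * 100
          km0 <- tryCatch(
            stats::uniroot(g, c(lo, hi), tol = km0 * 1e-9)$root,
            error = function(e) km0)
          attr(km0, "vmax") <- vm
        }
        Km[sub] <- as.numeric(km0)
        if (!is.null(attr(km0, "vmax")))
          curves[[sub]] <- structure(curves[[sub]], vmax = attr(km0, "vmax"))
        break
      }
      dec <- 6
    }
  }
  vmax <- if (length(curves)) max(vapply(curves, function(cv) {
    vm <- attr(cv, "vmax")
    if (is.null(vm)) max(cv$v) else vm
  }, numeric(1))) else NA_real_
  structure(list(reaction = reaction, Km = Km, vmax = vmax,
                 kcat = vmax / e_total, e_total = e_total,
                 resolved = resolved && all(is.finite(Km)),
                 curves = curves),
            class = "mm_parameters")
}

# interpolate the clamp level where v crosses vmax/2 (log-linear)
half_saturation <- function(S, v) {
  vmax <- max(v)
  half <- vmax / 2
  i <- which(v >= half)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(S[1])
  x <- log10(S[(i - 1):i]); y <- v[(i - 1):i]
  10^(x[1] + (half - y[1]) * (x[2] - x[1]) / (y[2] - y[1]))
}

#' Rescale a normalized constant to absolute units
#'
#' Interval product of the normalized value with the metabolite's
#' reference (wild-type) concentration range.
#'
#' @param value normalized constant (>= 0).
#' @param reference_range length-2 numeric `c(lo, hi)` in mM.
#' @return length-2 numeric, the absolute range in mM.
#' @export
rescale_to_absolute <- function(value, reference_range) {
  stopifnot(length(reference_range) == 2L,
            reference_range[1] <= reference_range[2])
  if (is.na(value)) return(c(NA_real_, NA_real_))
  sort(value * reference_range)
}

#' Interval overlap test
#'
#' TRUE iff the closed intervals intersect; symmetric in its arguments.
#'
#' @param predicted,measured length-2 numeric intervals `c(lo, hi)`.
#' @return logical.
#' @export
range_overlap <- function(predicted, measured) {
  stopifnot(length(predicted) == 2L, length(measured) == 2L,
            predicted[1] <= predicted[2], measured[1] <= measured[2])
  predicted[1] <= measured[2] && measured[1] <= predicted[2]
}

#' Confidence range of reported measurements
#'
#' Two or more reported values: mean plus/minus one (sample) standard
#' deviation.  A single value: plus/minus 10% of the reported value.
#'
#' @param values numeric vector of reported measurements (>= 1 value).
#' @return length-2 numeric `c(lo, hi)`.
#' @export
measured_range <- function(values) {
  if (!length(values)) stop("no reported values")
  if (length(values) == 1L)
    return(sort(c(0.9 * values, 1.1 * values)))
  m <- mean(values); s <- stats::sd(values)
  c(m - s, m + s)
}

#' Overlap report between predicted and measured constant ranges
#'
#' @param predicted data.frame with `constant` and `lo`/`hi` columns (or
#'   normalized values already rescaled).
#' @param measured data.frame with `constant`, `lo`, `hi`.
#' @return data.frame with `constant`, predicted and measured ranges and
#'   `overlap`; attribute `fraction` gives the overlap fraction.
#' @export
overlap_report <- function(predicted, measured) {
  common <- intersect(predicted$constant, measured$constant)
  rows <- lapply(common, function(k) {
    p <- predicted[predicted$constant == k, ][1, ]
    m <- measured[measured$constant == k, ][1, ]
    data.frame(constant = k, pred_lo = p$lo, pred_hi = p$hi,
               meas_lo = m$lo, meas_hi = m$hi,
               overlap = range_overlap(c(p$lo, p$hi), c(m$lo, m$hi)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fraction") <- if (length(common)) mean(out$overlap) else NA_real_
  out
}

#' @export
print.mm_parameters <- function(x, ...) {
  cat("mm_parameters for ", x$reaction, ": vmax = ",
      format(x$vmax, digits = 4), ", kcat = ",
      format(x$kcat, digits = 4), "\n  Km: ", sep = "")
  cat(paste0(names(x$Km), " = ", format(x$Km, digits = 4),
             collapse = ", "), "\n")
  invisible(x)
}
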
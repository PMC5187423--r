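#' Bounded linear programme over a flux space
#'
#' Solves max (or min) `obj' v` subject to `S v = b`, `lb <= v <= ub`.
#' This is the single entry point through which all constraint-based
#' analyses reach the LP solver; the backend (an in-package two-phase
#' bounded-variable simplex) is hidden behind the `status`/`v`/`value`
#' contract so it can be swapped.
#'
#' @param obj objective coefficients.
#' @param S constraint matrix (equalities).
#' @param lb,ub finite variable bounds.
#' @param b right-hand side, default zero.
#' @param maximize direction, default `TRUE`.
#' @return list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `v` (primal vector, named like `lb`) and `value`.
#' @export
solve_lp <- function(obj, S, lb, ub, b = NULL, maximize = TRUE) {
  n <- length(obj)
  S <- matrix(S, ncol = n)
  if (is.null(b)) b <- numeric(nrow(S))
  stopifnot(length(lb) == n, length(ub) == n, all(is.finite(lb)),
            all(is.finite(ub)))
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", v = NULL, value = NA_real_))
  # eliminate collapsed variables (lb == ub): they are constants
  fixed <- ub - lb < 1e-12
  if (all(fixed)) {
    ok <- max(abs(S %*% lb - b)) <= 1e-7 * max(1, max(abs(b)))
    return(if (ok) list(status = "optimal", v = lb, value = sum(obj * lb))
           else list(status = "infeasible", v = NULL, value = NA_real_))
  }
  if (any(fixed)) {
    vfix <- lb[fixed]
    sub <- solve_lp(obj[!fixed], S[, !fixed, drop = FALSE],
                    lb[!fixed], ub[!fixed],
                    b = as.vector(b - S[, fixed, drop = FALSE] %*% vfix),
                    maximize = maximize)
    if (sub$status != "optimal") return(sub)
    v <- numeric(n); v[fixed] <- vfix; v[!fixed] <- sub$v
    names(v) <- names(lb)
    return(list(status = "optimal", v = v, value = sum(obj * v)))
  }
  # conserved moieties (e.g. cofactor pairs) make mass-balance rows
  # linearly dependent; reduce to full row rank, checking consistency
  qrS <- qr(t(S))
  Sfull <- S; bfull <- b
  if (qrS$rank < nrow(S)) {
    keep <- qrS$pivot[seq_len(qrS$rank)]
    S <- S[keep, , drop = FALSE]
    b <- b[keep]
  }
  out <- lp_simplex(obj, S, b, lb, ub, maximize = maximize)
  # dropped (dependent) equality rows must still be satisfied
  if (out$status == "optimal" &&
      max(abs(Sfull %*% out$v - bfull)) > 1e-7 * max(1, max(abs(bfull)))) {
    out <- list(status = "infeasible", v = NULL, value = NA_real_)
  }
  out
}

#' Bounded convex quadratic programme
#'
#' Solves min `0.5 ||v - ref||^2` subject to `S v = 0`, `lb <= v <= ub`
#' (the MOMA projection).  Backend: dual active-set method (quadprog).
#'
#' @param ref reference vector to project.
#' @param S equality constraint matrix.
#' @param lb,ub finite bounds.
#' @return list with `status`, `v`, `value` (the squared distance).
#' @export
solve_qp_projection <- function(ref, S, lb, ub, b = NULL,
                                presolved = FALSE) {
  n <- length(ref)
  S <- matrix(S, ncol = n)
  if (is.null(b)) b <- numeric(nrow(S))
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", v = NULL, value = NA_real_))
  # eliminate collapsed variables (knockouts): quadprog cannot digest
  # equalities disguised as opposing inequalities
  fixed <- ub - lb < 1e-12
  if (any(fixed)) {
    vfix <- lb[fixed]
    if (all(fixed)) {
      ok <- max(abs(S %*% lb - b)) <= 1e-7 * max(1, max(abs(b)))
      return(if (ok) list(status = "optimal", v = lb,
                          value = sum((lb - ref)^2))
             else list(status = "infeasible", v = NULL, value = NA_real_))
    }
    sub <- solve_qp_projection(
      ref[!fixed], S[, !fixed, drop = FALSE], lb[!fixed], ub[!fixed],
      b = as.vector(b - S[, fixed, drop = FALSE] %*% vfix))
    if (sub$status != "optimal") return(sub)
    v <- numeric(n); v[fixed] <- vfix; v[!fixed] <- sub$v
    names(v) <- names(lb)
    return(list(status = "optimal", v = v, value = sum((v - ref)^2)))
  }
  # drop linearly dependent mass-balance rows (quadprog requires full rank)
  qrS <- qr(t(S))
  keep <- qrS$pivot[seq_len(qrS$rank)]
  Sr <- S[keep, , drop = FALSE]
  Amat <- cbind(t(Sr), diag(n), -diag(n))
  bvec <- c(b[keep], lb, -ub)
  out <- tryCatch(
    quadprog::solve.QP(Dmat = diag(n), dvec = ref, Amat = Amat,
                       bvec = bvec, meq = nrow(Sr)),
    error = function(e) NULL)
  if ((is.null(out) ||
       max(abs(S %*% out$solution - b)) > 1e-6 * max(1, max(abs(b)))) &&
      !presolved) {
    # degenerate feasible set (e.g. knockouts pinning whole branches):
    # tighten every variable by its LP variability and retry once
    lb2 <- lb; ub2 <- ub
    for (j in seq_len(n)) {
      o <- numeric(n); o[j] <- 1
      a <- lp_simplex(o, S, b, lb, ub, maximize = FALSE)
      z <- lp_simplex(o, S, b, lb, ub, maximize = TRUE)
      if (a$status != "optimal" || z$status != "optimal")
        return(list(status = "infeasible", v = NULL, value = NA_real_))
      lb2[j] <- max(lb[j], a$value); ub2[j] <- min(ub[j], z$value)
    }
    return(solve_qp_projection(ref, S, lb2, pmax(ub2, lb2), b,
                               presolved = TRUE))
  }
  if (is.null(out) ||
      max(abs(S %*% out$solution - b)) > 1e-6 * max(1, max(abs(b))))
    return(list(status = "infeasible", v = NULL, value = NA_real_))
  v <- out$solution
  names(v) <- names(lb)
  list(status = "optimal", v = v, value = sum((v - ref)^2))
}
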
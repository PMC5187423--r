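# Two-phase bounded-variable primal simplex.
#
# Solves  max/min  c'v   s.t.  A v = b,  lb <= v <= ub  (finite bounds on
# structural variables).  Dense implementation sized for flux spaces of a
# few dozen reactions; validated in the test suite against brute-force
# vertex enumeration.  Phase 1 drives artificial variables out of the
# basis; in phase 2 their upper bounds collapse to zero.

lp_simplex <- function(obj, A, b, lb, ub, maximize = TRUE,
                       tol = 1e-9) {
  n <- length(obj)
  m <- nrow(A)
  if (!maximize) {
    out <- lp_simplex(-obj, A, b, lb, ub, TRUE, tol)
    out$value <- -out$value
    return(out)
  }
  # shift to x = v - lb in [0, w]
  w <- ub - lb
  b0 <- as.vector(b - A %*% lb)
  A2 <- A
  neg <- b0 < 0
  if (any(neg)) { A2[neg, ] <- -A2[neg, , drop = FALSE]; b0[neg] <- -b0[neg] }
  # artificials
  AT <- cbind(A2, diag(m))
  wt <- c(w, rep(Inf, m))
  basis <- n + seq_len(m)
  at_upper <- rep(FALSE, n + m)   # nonbasic variables default to lower
  xB <- b0

  run_phase <- function(cost, basis, at_upper, xB, wt) {
    iter <- 0L; stall <- 0L; last <- -Inf
    maxit <- 200L + 40L * (n + m)
    repeat {
      iter <- iter + 1L
      if (iter > maxit) return(NULL)
      B <- AT[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
      if (is.null(y)) return(NULL)
      nonbasic <- setdiff(seq_len(n + m), basis)
      d <- cost[nonbasic] - as.vector(y %*% AT[, nonbasic, drop = FALSE])
      improving <- (d > tol & !at_upper[nonbasic]) |
                   (d < -tol & at_upper[nonbasic])
      if (!any(improving)) {
        return(list(basis = basis, at_upper = at_upper, xB = xB))
      }
      cand <- nonbasic[improving]
      obj_now <- sum(cost[basis] * xB) +
        sum(cost[nonbasic][at_upper[nonbasic]] *
              wt[nonbasic][at_upper[nonbasic]])
      if (obj_now <= last + tol) stall <- stall + 1L else stall <- 0L
      last <- max(last, obj_now)
      j <- if (stall > n + m) min(cand)       # Bland fallback
           else cand[which.max(abs(d[match(cand, nonbasic)]))]
      sgn <- if (at_upper[j]) -1 else 1       # direction of change of x_j
      dir <- tryCatch(solve(B, AT[, j]) * sgn, error = function(e) NULL)
      if (is.null(dir)) return(NULL)
      # ratio test: basics move as xB - dir * t
      t_own <- if (is.finite(wt[j])) wt[j] else Inf
      t_max <- t_own; leave <- 0L; leave_to_upper <- FALSE
      for (i in seq_len(m)) {
        if (dir[i] > tol) {
          tt <- xB[i] / dir[i]
          if (tt < t_max - 1e-12) { t_max <- tt; leave <- i
                                    leave_to_upper <- FALSE }
        } else if (dir[i] < -tol && is.finite(wt[basis[i]])) {
          tt <- (wt[basis[i]] - xB[i]) / (-dir[i])
          if (tt < t_max - 1e-12) { t_max <- tt; leave <- i
                                    leave_to_upper <- TRUE }
        }
      }
      if (!is.finite(t_max)) return("unbounded")
      xB <- xB - dir * t_max
      if (leave == 0L) {          # bound flip, basis unchanged
        at_upper[j] <- !at_upper[j]
      } else {
        out_var <- basis[leave]
        at_upper[out_var] <- leave_to_upper
        basis[leave] <- j
        xB[leave] <- (if (at_upper[j]) wt[j] else 0) + sgn * t_max
        at_upper[j] <- FALSE
      }
      xB[xB < 0 & xB > -1e-9] <- 0
    }
  }

  # phase 1: minimize artificial mass
  cost1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(cost1, basis, at_upper, xB, wt)
  if (is.null(ph1) || identical(ph1, "unbounded"))
    return(list(status = "infeasible", v = NULL, value = NA_real_))
  art_level <- sum(ph1$xB[ph1$basis > n])
  if (art_level > 1e-7)
    return(list(status = "infeasible", v = NULL, value = NA_real_))
  # phase 2: real objective, artificials frozen at zero
  wt2 <- wt; wt2[n + seq_len(m)] <- 0
  ph1$at_upper[n + seq_len(m)] <- FALSE
  cost2 <- c(obj, rep(0, m))
  ph2 <- run_phase(cost2, ph1$basis, ph1$at_upper, ph1$xB, wt2)
  if (is.null(ph2))
    return(list(status = "infeasible", v = NULL, value = NA_real_))
  if (identical(ph2, "unbounded"))
    return(list(status = "unbounded", v = NULL, value = NA_real_))
  x <- numeric(n + m)
  x[ph2$at_upper] <- wt2[ph2$at_upper]
  x[ph2$basis] <- ph2$xB
  v <- x[seq_len(n)] + lb
  names(v) <- names(lb)
  list(status = "optimal", v = v, value = sum(obj * v))
}
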
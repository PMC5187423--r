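# Shared fixtures and independent oracles.  The ground-truth bundle for
# branched-14 is computed once per test run and memoized.

toy_cache <- new.env(parent = emptyenv())

get_gtb <- function(preset = "branched-14", seed = 7L) {
  key <- paste0(preset, ".", seed)
  if (is.null(toy_cache[[key]]))
    toy_cache[[key]] <- toy_ground_truth(toy_spec(preset, seed = seed))
  toy_cache[[key]]
}

# -- brute-force LP oracle: enumerate basic feasible points ------------------
# max/min obj'v  s.t.  S v = 0, lb <= v <= ub, by fixing (n - rank) variables
# at a bound and solving the rest; exact on networks with <= ~8 reactions.
brute_lp <- function(obj, S, lb, ub, maximize = TRUE, tol = 1e-7) {
  n <- length(obj)
  S <- matrix(S, ncol = n)
  r <- qr(S)$rank
  nf <- n - r
  best <- NULL; bestval <- if (maximize) -Inf else Inf
  fix_sets <- if (nf == 0) list(integer(0))
              else utils::combn(n, nf, simplify = FALSE)
  for (fs in fix_sets) {
    assigns <- if (!length(fs)) list(numeric(0)) else {
      g <- expand.grid(rep(list(c(1, 2)), length(fs)))
      lapply(seq_len(nrow(g)), function(i)
        ifelse(g[i, ] == 1, lb[fs], ub[fs]))
    }
    B <- setdiff(seq_len(n), fs)
    SB <- S[, B, drop = FALSE]
    if (qr(SB)$rank < r) next
    for (a in assigns) {
      rhs <- if (length(fs)) -S[, fs, drop = FALSE] %*% as.numeric(a)
             else matrix(0, nrow(S), 1)
      vB <- tryCatch(qr.solve(SB, rhs), error = function(e) NULL)
      if (is.null(vB)) next
      v <- numeric(n); v[B] <- vB; if (length(fs)) v[fs] <- as.numeric(a)
      if (max(abs(S %*% v)) > tol) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      val <- sum(obj * v)
      if ((maximize && val > bestval) || (!maximize && val < bestval)) {
        bestval <- val; best <- v
      }
    }
  }
  list(v = best, value = bestval)
}

# -- brute-force QP oracle (MOMA): active-set enumeration --------------------
brute_moma <- function(ref, S, lb, ub, tol = 1e-7) {
  n <- length(ref)
  S <- matrix(S, ncol = n)
  best <- NULL; bestval <- Inf
  states <- expand.grid(rep(list(0:2), n))   # 0 free, 1 at lb, 2 at ub
  for (i in seq_len(nrow(states))) {
    st <- as.integer(states[i, ])
    fixed <- which(st > 0)
    vals <- ifelse(st[fixed] == 1, lb[fixed], ub[fixed])
    free <- setdiff(seq_len(n), fixed)
    # min ||v - ref||^2 s.t. S v = 0, v[fixed] = vals
    if (length(free)) {
      Sf <- S[, free, drop = FALSE]
      rhs <- if (length(fixed)) -S[, fixed, drop = FALSE] %*% vals
             else matrix(0, nrow(S), 1)
      # KKT system for equality-constrained least squares
      m <- nrow(S)
      K <- rbind(cbind(2 * diag(length(free)), t(Sf)),
                 cbind(Sf, matrix(0, m, m)))
      kr <- c(2 * ref[free], rhs)
      sol <- tryCatch(qr.solve(K, kr, tol = 1e-12),
                      error = function(e) NULL)
      if (is.null(sol)) next
      v <- numeric(n); v[fixed] <- vals; v[free] <- sol[seq_along(free)]
    } else {
      v <- numeric(n); v[fixed] <- vals
    }
    if (max(abs(S %*% v)) > tol) next
    if (any(v < lb - tol) || any(v > ub + tol)) next
    val <- sum((v - ref)^2)
    if (val < bestval - 1e-12) { bestval <- val; best <- v }
  }
  list(v = best, value = bestval)
}

# -- King-Altman / QSSA oracle ----------------------------------------------
# Steady-state cycle flux of one reaction's enzyme pools with all
# metabolites clamped, via direct linear solve of the enzyme-form balance
# (independent of the native pseudo-transient solver).
qssa_flux <- function(en, param, reaction, clamp) {
  total <- 0
  for (pool in en$pools$id[en$pools$reaction == reaction]) {
    forms <- en$pools$forms[[which(en$pools$id == pool)]]
    sel <- which(en$steps$pool %in% pool)
    nf <- length(forms)
    A <- matrix(0, nf, nf, dimnames = list(forms, forms))
    for (s in sel) {
      re <- en$steps$reactants[[s]]; pr <- en$steps$products[[s]]
      fin <- intersect(names(re), forms); fout <- intersect(names(pr), forms)
      met_f <- prod(clamp[setdiff(names(re), forms)]^
                      re[setdiff(names(re), forms)])
      met_b <- prod(clamp[setdiff(names(pr), forms)]^
                      pr[setdiff(names(pr), forms)])
      if (!length(met_f)) met_f <- 1
      if (!length(met_b)) met_b <- 1
      kf <- param$steps$kf[match(en$steps$id[s], param$steps$id)] * met_f
      kb <- param$steps$kb[match(en$steps$id[s], param$steps$id)] * met_b
      A[fin, fin] <- A[fin, fin] - kf
      A[fout, fin] <- A[fout, fin] + kf
      A[fout, fout] <- A[fout, fout] - kb
      A[fin, fout] <- A[fin, fout] + kb
    }
    lev <- param$e_level[[pool]] * param$pool_ref[[pool]]
    # replace one balance row by the conservation constraint
    A[1, ] <- 1
    b <- c(lev, rep(0, nf - 1))
    f <- solve(A, b)
    names(f) <- forms
    conv <- sel[en$steps$kind[sel] == "conversion"]
    re <- en$steps$reactants[[conv]]; pr <- en$steps$products[[conv]]
    kf <- param$steps$kf[match(en$steps$id[conv], param$steps$id)]
    kb <- param$steps$kb[match(en$steps$id[conv], param$steps$id)]
    total <- total + kf * prod(c(f, clamp)[names(re)]^re) -
      kb * prod(c(f, clamp)[names(pr)]^pr)
  }
  total
}

# single uni-uni enzyme network (S -> P) for Michaelis-Menten limit tests
uni_uni_network <- function() {
  mets <- data.frame(id = c("S", "P"), name = c("S", "P"),
                     compartment = "c", cofactor = FALSE,
                     conc_lo = 0.5, conc_hi = 2)
  rx <- rbind(
    kinens:::rxn("EX_S", c(S = 1), exchange = TRUE),
    kinens:::rxn("R", c(S = -1, P = 1), "E1"),
    kinens:::rxn("EX_P", c(P = -1), exchange = TRUE))
  metabolic_network(mets, rx)
}

uni_uni_reference <- function() c(EX_S = 1, R = 1, EX_P = 1)

# reversible uni-uni Michaelis-Menten closed form from elementary
# constants (E+S <-> ES <-> EP <-> E+P), King-Altman determinant form
uni_uni_closed_form <- function(k1, km1, k2, km2, k3, km3, S, P, et = 1) {
  num <- et * (k1 * k2 * k3 * S - km1 * km2 * km3 * P)
  dE  <- km1 * km2 + km1 * k3 + k2 * k3
  dES <- k1 * S * (km2 + k3) + km3 * P * km2
  dEP <- k1 * S * k2 + km3 * P * (km1 + k2)
  num / (dE + dES + dEP)
}

expect_flux_balance <- function(net, v, tol = 1e-8) {
  S <- stoich_matrix(net)
  expect_lt(max(abs(S %*% v[colnames(S)])), tol)
}
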
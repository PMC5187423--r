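// Steady-state solver for elementary mass-action networks.
//
// The system dx/dt = N r(x), r_s = kf_s * prod x^a  -  kb_s * prod x^b,
// is driven to a steady state by pseudo-transient continuation (implicit
// Euler with an adaptive pseudo-step, which turns into full Newton as the
// step grows), starting from the anchored reference state.  Clamped
// species keep dx/dt = 0 by construction.  Enzyme-pool conservation is
// structural (each step has exactly one enzyme form on each side), so the
// linear solves preserve pool totals up to roundoff.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Net {
  int ns, nsteps;
  std::vector<int> rptr, ridx, pptr, pidx;
  std::vector<double> rcnt, pcnt;
};

static Net unpack(const List& compiled) {
  Net w;
  w.ns = as<int>(compiled["n_species"]);
  w.nsteps = as<int>(compiled["n_steps"]);
  w.rptr = as<std::vector<int>>(compiled["r_ptr"]);
  w.ridx = as<std::vector<int>>(compiled["r_idx"]);
  w.rcnt = as<std::vector<double>>(compiled["r_cnt"]);
  w.pptr = as<std::vector<int>>(compiled["p_ptr"]);
  w.pidx = as<std::vector<int>>(compiled["p_idx"]);
  w.pcnt = as<std::vector<double>>(compiled["p_cnt"]);
  return w;
}

static inline double xpow(double x, double c) {
  if (x <= 0.0) return 0.0;
  if (c == 1.0) return x;
  if (c == 2.0) return x * x;
  return std::pow(x, c);
}

// step rates and (optionally) the residual f = N r
static void rates_resid(const Net& w, const arma::vec& x,
                        const arma::vec& kf, const arma::vec& kb,
                        arma::vec& r, arma::vec& f) {
  f.zeros();
  for (int s = 0; s < w.nsteps; ++s) {
    double fwd = kf[s], bwd = kb[s];
    for (int j = w.rptr[s]; j < w.rptr[s + 1]; ++j)
      fwd *= xpow(x[w.ridx[j]], w.rcnt[j]);
    for (int j = w.pptr[s]; j < w.pptr[s + 1]; ++j)
      bwd *= xpow(x[w.pidx[j]], w.pcnt[j]);
    double rate = fwd - bwd;
    r[s] = rate;
    for (int j = w.rptr[s]; j < w.rptr[s + 1]; ++j)
      f[w.ridx[j]] -= w.rcnt[j] * rate;
    for (int j = w.pptr[s]; j < w.pptr[s + 1]; ++j)
      f[w.pidx[j]] += w.pcnt[j] * rate;
  }
}

// dense Jacobian of f
static void jacobian(const Net& w, const arma::vec& x,
                     const arma::vec& kf, const arma::vec& kb,
                     arma::mat& J) {
  J.zeros();
  for (int s = 0; s < w.nsteps; ++s) {
    // forward part
    for (int jj = w.rptr[s]; jj < w.rptr[s + 1]; ++jj) {
      int v = w.ridx[jj];
      double d = kf[s] * w.rcnt[jj] * xpow(x[v], w.rcnt[jj] - 1.0);
      if (w.rcnt[jj] == 1.0) d = kf[s];           // xpow(x,0) would be 0 at x=0
      else if (x[v] <= 0.0) d = 0.0;
      for (int kk = w.rptr[s]; kk < w.rptr[s + 1]; ++kk)
        if (kk != jj) d *= xpow(x[w.ridx[kk]], w.rcnt[kk]);
      if (d == 0.0) continue;
      for (int kk = w.rptr[s]; kk < w.rptr[s + 1]; ++kk)
        J(w.ridx[kk], v) -= w.rcnt[kk] * d;
      for (int kk = w.pptr[s]; kk < w.pptr[s + 1]; ++kk)
        J(w.pidx[kk], v) += w.pcnt[kk] * d;
    }
    // backward part
    for (int jj = w.pptr[s]; jj < w.pptr[s + 1]; ++jj) {
      int v = w.pidx[jj];
      double d = kb[s] * w.pcnt[jj] * xpow(x[v], w.pcnt[jj] - 1.0);
      if (w.pcnt[jj] == 1.0) d = kb[s];
      else if (x[v] <= 0.0) d = 0.0;
      for (int kk = w.pptr[s]; kk < w.pptr[s + 1]; ++kk)
        if (kk != jj) d *= xpow(x[w.pidx[kk]], w.pcnt[kk]);
      if (d == 0.0) continue;
      for (int kk = w.rptr[s]; kk < w.rptr[s + 1]; ++kk)
        J(w.ridx[kk], v) += w.rcnt[kk] * d;
      for (int kk = w.pptr[s]; kk < w.pptr[s + 1]; ++kk)
        J(w.pidx[kk], v) -= w.pcnt[kk] * d;
    }
  }
}

// [[Rcpp::export(name = ".kinens_rhs")]]
List kinens_rhs(List compiled, NumericVector x0, NumericVector kf,
                NumericVector kb) {
  Net w = unpack(compiled);
  arma::vec x(x0.begin(), w.ns), f(w.ns), r(w.nsteps);
  arma::vec kfv(kf.begin(), w.nsteps), kbv(kb.begin(), w.nsteps);
  rates_resid(w, x, kfv, kbv, r, f);
  return List::create(_["dx"] = NumericVector(f.begin(), f.end()),
                      _["rates"] = NumericVector(r.begin(), r.end()));
}

// [[Rcpp::export(name = ".kinens_solve_ss")]]
List kinens_solve_ss(List compiled, NumericVector x0, NumericVector kf,
                     NumericVector kb, LogicalVector clamped,
                     double tol = 1e-9, double max_time = 1e6,
                     int max_iter = 120) {
  Net w = unpack(compiled);
  arma::vec x(x0.begin(), w.ns), f(w.ns), r(w.nsteps);
  arma::vec kfv(kf.begin(), w.nsteps), kbv(kb.begin(), w.nsteps);
  std::vector<bool> cl(w.ns);
  for (int i = 0; i < w.ns; ++i) cl[i] = clamped[i];

  arma::mat J(w.ns, w.ns), A(w.ns, w.ns);
  arma::vec d(w.ns);
  double h = 1e-2, t = 0.0, resid = 0.0;
  bool converged = false;
  int it = 0;

  auto resid_free = [&](const arma::vec& g) {
    double m = 0.0;
    for (int i = 0; i < w.ns; ++i)
      if (!cl[i]) m = std::max(m, std::fabs(g[i]));
    return m;
  };

  rates_resid(w, x, kfv, kbv, r, f);
  resid = resid_free(f);
  while (it < max_iter && t < max_time) {
    if (resid < tol) { converged = true; break; }
    ++it;
    jacobian(w, x, kfv, kbv, J);
    bool accepted = false;
    for (int tries = 0; tries < 40 && !accepted; ++tries) {
      A = -J;
      A.diag() += 1.0 / h;
      for (int i = 0; i < w.ns; ++i)
        if (cl[i]) { A.row(i).zeros(); A(i, i) = 1.0; }
      arma::vec rhs = f;
      for (int i = 0; i < w.ns; ++i) if (cl[i]) rhs[i] = 0.0;
      bool ok = arma::solve(d, A, rhs, arma::solve_opts::no_approx);
      if (ok) {
        arma::vec xn = x + d;
        bool good = xn.is_finite();
        if (good)
          for (int i = 0; i < w.ns; ++i)
            if (xn[i] < -1e-12) { good = false; break; }
        if (good) {
          for (int i = 0; i < w.ns; ++i) if (xn[i] < 0.0) xn[i] = 0.0;
          arma::vec fn(w.ns);
          rates_resid(w, xn, kfv, kbv, r, fn);
          double rn = resid_free(fn);
          if (fn.is_finite()) {
            // switched evolution relaxation: grow the pseudo-step as the
            // residual falls, shrink it when the residual grows
            double ratio = (rn > 0.0) ? resid / rn : 4.0;
            ratio = std::min(std::max(ratio, 0.25), 4.0);
            x = xn; f = fn; t += h; resid = rn;
            h = std::min(h * ratio * 1.5, 1e12);
            accepted = true;
          }
        }
      }
      if (!accepted) h *= 0.25;
      if (h < 1e-14) break;
    }
    if (!accepted) break;           // stalled
    if (x.max() > 1e9) break;       // diverging: no steady state reachable
  }
  if (resid < tol) converged = true;
  rates_resid(w, x, kfv, kbv, r, f);
  return List::create(
      _["x"] = NumericVector(x.begin(), x.end()),
      _["rates"] = NumericVector(r.begin(), r.end()),
      _["residual"] = resid_free(f),
      _["converged"] = converged,
      _["iterations"] = it,
      _["time"] = t);
}
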
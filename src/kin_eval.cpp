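// Flux-law evaluation kernels.
//
// The model is flattened on the R side into plain index vectors (CSR-style
// ragged arrays, 0-based).  Three entry points share one evaluator:
//   kin_eval_cpp    - batched evaluation (columns of theta/lnC), optional
//                     factor decomposition
//   kin_newton_cpp  - damped Newton polish of S_bal v = 0 in log
//                     concentrations
//   kin_grad_kernel_cpp - everything the adjoint gradient needs in one call:
//                     Jacobians wrt log concentrations and the
//                     finite-difference parameter sensitivities
//
// Flux factorization per enzymatic reaction:
//   v = E * kcat * reversibility * saturation * allostery * phosphorylation
// reversibility = 1 - exp(DrG0/RT + ln Q); saturation and the free-enzyme
// ratio come from the common modular denominator; allostery follows the
// generalized MWC model; phosphorylation contributes (1 + p/d)^(-n).
// Drains contribute their flux parameter directly.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// cap on the exponent of the thermodynamic term: keeps the factor finite so
// that 0 * exp(huge) never produces NaN in the S*v contraction
static const double EXP_CAP = 500.0;

struct KinModel {
  int nrxn, nmet, nbal;
  double RT;
  IntegerVector met_bal_pos, met_bound_t;
  IntegerVector rxn_type, reversible;
  NumericVector subunits;
  IntegerVector kcat_t, enz_t, drain_t, L_t;
  IntegerVector sub_off, sub_m, sub_km;
  NumericVector sub_s;
  IntegerVector prod_off, prod_m, prod_km;
  NumericVector prod_s;
  IntegerVector ci_off, ci_m, ci_t;
  IntegerVector act_off, act_m, act_t, inh_off, inh_m, inh_t;
  IntegerVector dg_off, dg_t;
  NumericVector dg_s;
  IntegerVector q_off, q_m;
  NumericVector q_s;
  IntegerVector p_off, p_t, d_off, d_t;
  NumericMatrix S_bal;

  explicit KinModel(List cm)
    : nrxn(as<int>(cm["nrxn"])), nmet(as<int>(cm["nmet"])),
      nbal(as<int>(cm["nbal"])), RT(as<double>(cm["RT"])),
      met_bal_pos(cm["met_bal_pos"]), met_bound_t(cm["met_bound_t"]),
      rxn_type(cm["rxn_type"]), reversible(cm["reversible"]),
      subunits(cm["subunits"]), kcat_t(cm["kcat_t"]), enz_t(cm["enz_t"]),
      drain_t(cm["drain_t"]), L_t(cm["L_t"]), sub_off(cm["sub_off"]),
      sub_m(cm["sub_m"]), sub_km(cm["sub_km"]), sub_s(cm["sub_s"]),
      prod_off(cm["prod_off"]), prod_m(cm["prod_m"]), prod_km(cm["prod_km"]),
      prod_s(cm["prod_s"]), ci_off(cm["ci_off"]), ci_m(cm["ci_m"]),
      ci_t(cm["ci_t"]), act_off(cm["act_off"]), act_m(cm["act_m"]),
      act_t(cm["act_t"]), inh_off(cm["inh_off"]), inh_m(cm["inh_m"]),
      inh_t(cm["inh_t"]), dg_off(cm["dg_off"]), dg_t(cm["dg_t"]),
      dg_s(cm["dg_s"]), q_off(cm["q_off"]), q_m(cm["q_m"]), q_s(cm["q_s"]),
      p_off(cm["p_off"]), p_t(cm["p_t"]), d_off(cm["d_off"]),
      d_t(cm["d_t"]), S_bal(cm["S_bal"]) {}

  // evaluate fluxes (and optionally fbal/factors) for one (theta, lnC)
  void eval(const double* th, const double* lnC, double* flux, double* fbal,
            double* factors /* 7 x nrxn, column-major, or null */) const {
    std::vector<double> C(nmet), lnCfull(nmet);
    for (int m = 0; m < nmet; ++m) {
      if (met_bal_pos[m] >= 0) {
        lnCfull[m] = lnC[met_bal_pos[m]];
        C[m] = std::exp(lnCfull[m]);
      } else {
        C[m] = th[met_bound_t[m]];
        lnCfull[m] = std::log(C[m]);
      }
    }
    for (int r = 0; r < nrxn; ++r) {
      double E = 1.0, kc = 1.0, rev = 1.0, sat = 1.0, allo = 1.0, phos = 1.0;
      double fer = 1.0, v;
      if (rxn_type[r] == 1) {            // drain
        v = th[drain_t[r]];
      } else if (enz_t[r] < 0) {         // knocked out
        E = 0.0; kc = th[kcat_t[r]]; v = 0.0;
      } else {
        E = th[enz_t[r]];
        kc = th[kcat_t[r]];
        if (reversible[r]) {
          double dg = 0.0, lnQ = 0.0;
          for (int k = dg_off[r]; k < dg_off[r + 1]; ++k) dg += dg_s[k] * th[dg_t[k]];
          for (int k = q_off[r]; k < q_off[r + 1]; ++k) lnQ += q_s[k] * lnCfull[q_m[k]];
          double arg = dg / RT + lnQ;
          if (arg > EXP_CAP) arg = EXP_CAP;
          rev = 1.0 - std::exp(arg);
        }
        double num = 1.0, dsub = 1.0, dprod = 1.0, dci = 0.0;
        for (int k = sub_off[r]; k < sub_off[r + 1]; ++k) {
          double x = C[sub_m[k]] / th[sub_km[k]];
          double s = sub_s[k];
          num *= (s == 1.0) ? x : std::pow(x, s);
          dsub *= (s == 1.0) ? (1.0 + x) : std::pow(1.0 + x, s);
        }
        if (reversible[r]) {
          for (int k = prod_off[r]; k < prod_off[r + 1]; ++k) {
            double x = C[prod_m[k]] / th[prod_km[k]];
            double s = prod_s[k];
            dprod *= (s == 1.0) ? (1.0 + x) : std::pow(1.0 + x, s);
          }
        }
        for (int k = ci_off[r]; k < ci_off[r + 1]; ++k)
          dci += C[ci_m[k]] / th[ci_t[k]];
        double D = dsub + dprod - 1.0 + dci;
        sat = num / D;
        fer = 1.0 / D;
        if (L_t[r] >= 0) {
          double sact = 0.0, sinh_ = 0.0;
          for (int k = act_off[r]; k < act_off[r + 1]; ++k)
            sact += C[act_m[k]] / th[act_t[k]];
          for (int k = inh_off[r]; k < inh_off[r + 1]; ++k)
            sinh_ += C[inh_m[k]] / th[inh_t[k]];
          double q = fer * (1.0 + sinh_) / (1.0 + sact);
          allo = 1.0 / (1.0 + th[L_t[r]] * std::pow(q, subunits[r]));
        }
        if (p_off[r + 1] > p_off[r]) {
          double p = 0.0, d = 0.0;
          for (int k = p_off[r]; k < p_off[r + 1]; ++k) p += th[p_t[k]];
          for (int k = d_off[r]; k < d_off[r + 1]; ++k) d += th[d_t[k]];
          if (d_off[r + 1] == d_off[r]) d = 1.0;   // no phosphatase declared
          phos = std::pow(1.0 + p / d, -subunits[r]);
        }
        v = E * kc * rev * sat * allo * phos;
      }
      flux[r] = v;
      if (factors) {
        factors[7 * r + 0] = E; factors[7 * r + 1] = kc;
        factors[7 * r + 2] = rev; factors[7 * r + 3] = sat;
        factors[7 * r + 4] = allo; factors[7 * r + 5] = phos;
        factors[7 * r + 6] = fer;
      }
    }
    if (fbal) {
      for (int m = 0; m < nbal; ++m) {
        double acc = 0.0;
        for (int r = 0; r < nrxn; ++r) {
          double s = S_bal(m, r);
          if (s != 0.0) acc += s * flux[r];
        }
        fbal[m] = acc;
      }
    }
  }
};

static bool all_finite(const double* x, int n) {
  for (int i = 0; i < n; ++i) if (!std::isfinite(x[i])) return false;
  return true;
}

// Gaussian elimination with partial pivoting; returns false when singular.
static bool solve_small(std::vector<double> A, std::vector<double>& b, int n) {
  for (int col = 0; col < n; ++col) {
    int piv = col;
    for (int i = col + 1; i < n; ++i)
      if (std::fabs(A[i + col * n]) > std::fabs(A[piv + col * n])) piv = i;
    if (std::fabs(A[piv + col * n]) < 1e-300) return false;
    if (piv != col) {
      for (int j = 0; j < n; ++j) std::swap(A[col + j * n], A[piv + j * n]);
      std::swap(b[col], b[piv]);
    }
    for (int i = col + 1; i < n; ++i) {
      double f = A[i + col * n] / A[col + col * n];
      for (int j = col; j < n; ++j) A[i + j * n] -= f * A[col + j * n];
      b[i] -= f * b[col];
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    for (int j = i + 1; j < n; ++j) s -= A[i + j * n] * b[j];
    b[i] = s / A[i + i * n];
  }
  return all_finite(b.data(), n);
}

// [[Rcpp::export]]
List kin_eval_cpp(List cm, NumericMatrix theta, NumericMatrix lnC,
                  bool want_factors) {
  KinModel M(cm);
  const int B = theta.ncol();
  NumericMatrix flux(M.nrxn, B), fbal(M.nbal, B);
  NumericMatrix f_enz, f_kcat, f_rev, f_sat, f_allo, f_phos, f_fer;
  if (want_factors) {
    f_enz = NumericMatrix(M.nrxn, B); f_kcat = NumericMatrix(M.nrxn, B);
    f_rev = NumericMatrix(M.nrxn, B); f_sat = NumericMatrix(M.nrxn, B);
    f_allo = NumericMatrix(M.nrxn, B); f_phos = NumericMatrix(M.nrxn, B);
    f_fer = NumericMatrix(M.nrxn, B);
  }
  std::vector<double> fac(want_factors ? 7 * M.nrxn : 0);
  for (int b = 0; b < B; ++b) {
    M.eval(&theta(0, b), M.nbal > 0 ? &lnC(0, b) : nullptr, &flux(0, b),
           M.nbal > 0 ? &fbal(0, b) : nullptr,
           want_factors ? fac.data() : nullptr);
    if (want_factors) {
      for (int r = 0; r < M.nrxn; ++r) {
        f_enz(r, b) = fac[7 * r + 0]; f_kcat(r, b) = fac[7 * r + 1];
        f_rev(r, b) = fac[7 * r + 2]; f_sat(r, b) = fac[7 * r + 3];
        f_allo(r, b) = fac[7 * r + 4]; f_phos(r, b) = fac[7 * r + 5];
        f_fer(r, b) = fac[7 * r + 6];
      }
    }
  }
  if (want_factors) {
    return List::create(_["flux"] = flux, _["fbal"] = fbal,
                        _["enzyme"] = f_enz, _["kcat"] = f_kcat,
                        _["reversibility"] = f_rev, _["saturation"] = f_sat,
                        _["allostery"] = f_allo, _["phosphorylation"] = f_phos,
                        _["free_enzyme_ratio"] = f_fer);
  }
  return List::create(_["flux"] = flux, _["fbal"] = fbal);
}

// Damped Newton polish of S_bal v = 0 in log-concentration coordinates.
// [[Rcpp::export]]
List kin_newton_cpp(List cm, NumericVector theta, NumericVector lnC0,
                    double tol, int max_iters, double h) {
  KinModel M(cm);
  const int n = M.nbal;
  const double* th = REAL(theta);
  std::vector<double> lnC(lnC0.begin(), lnC0.end());
  std::vector<double> flux(M.nrxn), res(n), resn(n), cand(n), step(n);
  std::vector<double> J(n * n), fp(n), fm(n), lp(n);
  int iters = 0;
  M.eval(th, lnC.data(), flux.data(), res.data(), nullptr);
  if (!all_finite(res.data(), n)) {
    return List::create(_["lnC"] = lnC0, _["residual"] = R_PosInf,
                        _["iters"] = 0, _["converged"] = false);
  }
  double best = 0;
  for (int i = 0; i < n; ++i) best = std::max(best, std::fabs(res[i]));
  while (best > tol && iters < max_iters) {
    // Jacobian by central differences in log concentrations
    for (int j = 0; j < n; ++j) {
      lp = lnC; lp[j] += h;
      M.eval(th, lp.data(), flux.data(), fp.data(), nullptr);
      lp[j] -= 2 * h;
      M.eval(th, lp.data(), flux.data(), fm.data(), nullptr);
      for (int i = 0; i < n; ++i) J[i + j * n] = (fp[i] - fm[i]) / (2 * h);
    }
    for (int i = 0; i < n; ++i) step[i] = -res[i];
    if (!solve_small(J, step, n)) break;
    double mx = 0;
    for (int i = 0; i < n; ++i) mx = std::max(mx, std::fabs(step[i]));
    if (mx > 4.0) for (int i = 0; i < n; ++i) step[i] *= 4.0 / mx;
    double lambda = 1.0;
    bool improved = false;
    for (int t = 0; t < 12; ++t) {
      for (int i = 0; i < n; ++i) cand[i] = lnC[i] + lambda * step[i];
      M.eval(th, cand.data(), flux.data(), resn.data(), nullptr);
      if (all_finite(resn.data(), n)) {
        double nb = 0;
        for (int i = 0; i < n; ++i) nb = std::max(nb, std::fabs(resn[i]));
        if (nb < best) {
          lnC = cand; res = resn; best = nb; improved = true;
          break;
        }
      }
      lambda *= 0.5;
    }
    ++iters;
    if (!improved) break;
  }
  return List::create(_["lnC"] = NumericVector(lnC.begin(), lnC.end()),
                      _["residual"] = best, _["iters"] = iters,
                      _["converged"] = best <= tol);
}

// One-call gradient kernel: flux and fbal at (theta, lnC), Jacobians wrt
// log concentrations, and central-difference sensitivities wrt selected
// parameters (perturbed multiplicatively for positive parameters, i.e. on
// the unconstrained log scale, when pos_scale = true).
// [[Rcpp::export]]
List kin_grad_kernel_cpp(List cm, NumericVector theta, NumericVector lnC,
                         IntegerVector idx, LogicalVector pos,
                         bool pos_scale, double h) {
  KinModel M(cm);
  const int n = M.nbal, K = idx.size(), nr = M.nrxn;
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> ln(lnC.begin(), lnC.end());
  NumericVector flux(nr), fbal(n);
  M.eval(th.data(), ln.data(), REAL(flux), REAL(fbal), nullptr);
  NumericMatrix J(n, n), Vc(nr, n), Fu(n, K), Vu(nr, K);
  std::vector<double> fp(n), fm(n), vp(nr), vm(nr), lp(n);
  for (int j = 0; j < n; ++j) {
    lp = ln; lp[j] += h;
    M.eval(th.data(), lp.data(), vp.data(), fp.data(), nullptr);
    lp[j] -= 2 * h;
    M.eval(th.data(), lp.data(), vm.data(), fm.data(), nullptr);
    for (int i = 0; i < n; ++i) J(i, j) = (fp[i] - fm[i]) / (2 * h);
    for (int r = 0; r < nr; ++r) Vc(r, j) = (vp[r] - vm[r]) / (2 * h);
  }
  const double eh = std::exp(h), emh = std::exp(-h);
  for (int k = 0; k < K; ++k) {
    int j = idx[k];
    double orig = th[j], hp, hm, denom;
    if (pos_scale && pos[k]) {
      hp = orig * eh; hm = orig * emh; denom = 2 * h;      // d/d(ln theta)
    } else {
      double step = h * std::max(std::fabs(orig), 1e-4);
      hp = orig + step; hm = orig - step; denom = 2 * step; // d/d(theta)
    }
    th[j] = hp;
    M.eval(th.data(), ln.data(), vp.data(), fp.data(), nullptr);
    th[j] = hm;
    M.eval(th.data(), ln.data(), vm.data(), fm.data(), nullptr);
    th[j] = orig;
    for (int i = 0; i < n; ++i) Fu(i, k) = (fp[i] - fm[i]) / denom;
    for (int r = 0; r < nr; ++r) Vu(r, k) = (vp[r] - vm[r]) / denom;
  }
  return List::create(_["flux"] = flux, _["fbal"] = fbal, _["J"] = J,
                      _["Vc"] = Vc, _["Fu"] = Fu, _["Vu"] = Vu);
}

// LU with partial pivoting for the shared Rosenbrock matrix W = I - h d J.
static bool lu_factor(std::vector<double>& A, std::vector<int>& piv, int n) {
  for (int col = 0; col < n; ++col) {
    int p = col;
    for (int i = col + 1; i < n; ++i)
      if (std::fabs(A[i + col * n]) > std::fabs(A[p + col * n])) p = i;
    if (std::fabs(A[p + col * n]) < 1e-300) return false;
    piv[col] = p;
    if (p != col)
      for (int j = 0; j < n; ++j) std::swap(A[col + j * n], A[p + j * n]);
    for (int i = col + 1; i < n; ++i) {
      A[i + col * n] /= A[col + col * n];
      double f = A[i + col * n];
      for (int j = col + 1; j < n; ++j) A[i + j * n] -= f * A[col + j * n];
    }
  }
  return true;
}

static void lu_solve(const std::vector<double>& A, const std::vector<int>& piv,
                     std::vector<double>& b, int n) {
  for (int col = 0; col < n; ++col) {
    if (piv[col] != col) std::swap(b[col], b[piv[col]]);
    for (int i = col + 1; i < n; ++i) b[i] -= A[i + col * n] * b[col];
  }
  for (int i = n - 1; i >= 0; --i) {
    for (int j = i + 1; j < n; ++j) b[i] -= A[i + j * n] * b[j];
    b[i] /= A[i + i * n];
  }
}

// Adaptive Rosenbrock 2(3) evolution of d lnC/dt = S_bal v / C for t_end
// seconds: the first stage of the hybrid steady-state scheme.
// [[Rcpp::export]]
List kin_evolve_cpp(List cm, NumericVector theta, NumericVector lnC0,
                    double t_end, double rel_tol, double abs_tol,
                    int max_steps) {
  KinModel M(cm);
  const int n = M.nbal;
  const double* th = REAL(theta);
  const double d = 1.0 / (2.0 + std::sqrt(2.0));
  const double e32 = 6.0 + std::sqrt(2.0);
  std::vector<double> y(lnC0.begin(), lnC0.end());
  std::vector<double> flux(M.nrxn), fb(n);
  std::vector<double> f0(n), f1(n), f2(n), k1(n), k2(n), k3(n);
  std::vector<double> ytmp(n), ynew(n), err(n);
  std::vector<double> J(n * n), W(n * n), fp(n), fm(n), lp(n);
  std::vector<int> piv(n);

  auto rhs = [&](const std::vector<double>& ln, std::vector<double>& out) {
    M.eval(th, ln.data(), flux.data(), fb.data(), nullptr);
    for (int i = 0; i < n; ++i) out[i] = fb[i] * std::exp(-ln[i]);
  };

  double t = 0.0;
  rhs(y, f0);
  if (!all_finite(f0.data(), n)) {
    return List::create(_["lnC"] = lnC0, _["t"] = 0.0, _["n_steps"] = 0,
                        _["success"] = false);
  }
  double ymax = 0, fmax = 0;
  for (int i = 0; i < n; ++i) {
    ymax = std::max(ymax, std::fabs(y[i]));
    fmax = std::max(fmax, std::fabs(f0[i]));
  }
  double h = std::min(t_end, 0.01 * (1.0 + ymax) / (fmax + 1e-10));
  int steps = 0;
  const double jh = 1e-6;
  while (t < t_end && steps < max_steps) {
    if (h > t_end - t) h = t_end - t;
    // Jacobian of the log-space rhs by central differences
    for (int j = 0; j < n; ++j) {
      lp = y; lp[j] += jh; rhs(lp, fp);
      lp[j] -= 2 * jh; rhs(lp, fm);
      for (int i = 0; i < n; ++i) J[i + j * n] = (fp[i] - fm[i]) / (2 * jh);
    }
    bool ok = true;
    for (int i = 0; i < n * n; ++i) W[i] = -h * d * J[i];
    for (int i = 0; i < n; ++i) W[i + i * n] += 1.0;
    std::vector<double> LU = W;
    ok = lu_factor(LU, piv, n);
    double err_norm = 2.0;
    if (ok) {
      k1 = f0; lu_solve(LU, piv, k1, n);
      for (int i = 0; i < n; ++i) ytmp[i] = y[i] + 0.5 * h * k1[i];
      rhs(ytmp, f1);
      for (int i = 0; i < n; ++i) k2[i] = f1[i] - k1[i];
      lu_solve(LU, piv, k2, n);
      for (int i = 0; i < n; ++i) k2[i] += k1[i];
      for (int i = 0; i < n; ++i) ynew[i] = y[i] + h * k2[i];
      rhs(ynew, f2);
      for (int i = 0; i < n; ++i)
        k3[i] = f2[i] - e32 * (k2[i] - f1[i]) - 2.0 * (k1[i] - f0[i]);
      lu_solve(LU, piv, k3, n);
      ok = all_finite(ynew.data(), n) && all_finite(f2.data(), n) &&
           all_finite(k3.data(), n);
      if (ok) {
        err_norm = 0.0;
        for (int i = 0; i < n; ++i) {
          double e = (h / 6.0) * (k1[i] - 2.0 * k2[i] + k3[i]);
          double scale = abs_tol +
            rel_tol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
          err_norm = std::max(err_norm, std::fabs(e) / scale);
        }
        if (err_norm <= 1.0) {
          t += h;
          y = ynew;
          f0 = f2;
        }
        h *= std::min(5.0, std::max(0.2, 0.9 * std::pow(err_norm, -1.0 / 3.0)));
      }
    }
    if (!ok) {
      h *= 0.25;
      if (h < 1e-14 * t_end) {
        return List::create(_["lnC"] = NumericVector(y.begin(), y.end()),
                            _["t"] = t, _["n_steps"] = steps,
                            _["success"] = false);
      }
    }
    ++steps;
  }
  return List::create(_["lnC"] = NumericVector(y.begin(), y.end()),
                      _["t"] = t, _["n_steps"] = steps,
                      _["success"] = t >= t_end);
}
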
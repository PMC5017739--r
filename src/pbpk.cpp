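// Whole-body PBPK system for a PSMA-targeting peptide and a linearly
// implicit Rosenbrock(2,3) integrator (Shampine-Reichelt ode23s scheme).
//
// State layout per species: [serum, serum_catabolite, urine, organ blocks...]
// PSMA-positive organ block: [vascular, interstitial_free, bound, internalized]
// PSMA-negative organ block: [vascular, interstitial_free]
//
// Units: amounts nmol, volumes ml, flows ml/min, time min,
// k_on is supplied in l.nmol^-1.min^-1 and converted to (nmol/ml)^-1.min^-1.
//
// Two modes:
//   single species ("total ligand"): no physical decay; the labeled tracer is
//     recovered in R as labeled_fraction * exp(-lambda*t) * total.
//   two species: labeled block then unlabeled block, coupled through the
//     shared free-receptor pool and by physical decay (labeled -> unlabeled),
//     with decay of the vial content during the infusion included.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct PbpkPars {
  int norg;
  arma::vec F, PS, Vv, Vf, Rtot, lint, lrel;
  arma::ivec psma, off;      // off: state offset of each organ within a species block
  double Vs, TER, fu, CLcat, konp, koff;
  int kidney;                // organ index of the kidneys (for unspecific uptake)
  double inf_rate, t_inf;    // zero-order infusion of total peptide, nmol/min
  double lambda;             // physical decay constant (two-species mode)
  double lf;                 // labeled fraction at infusion start
  bool two;
  int m;                     // states per species
  int n;                     // total states
};

static PbpkPars unpack(const List& pars) {
  PbpkPars P;
  P.F    = as<arma::vec>(pars["F"]);
  P.PS   = as<arma::vec>(pars["PS"]);
  P.Vv   = as<arma::vec>(pars["Vv"]);
  P.Vf   = as<arma::vec>(pars["Vf"]);
  P.Rtot = as<arma::vec>(pars["Rtot"]);
  P.lint = as<arma::vec>(pars["lint"]);
  P.lrel = as<arma::vec>(pars["lrel"]);
  P.psma = as<arma::ivec>(pars["psma"]);
  P.norg = P.F.n_elem;
  P.Vs    = as<double>(pars["Vs"]);
  P.TER   = as<double>(pars["TER"]);
  P.fu    = as<double>(pars["fu"]);
  P.CLcat = as<double>(pars["CLcat"]);
  P.konp  = as<double>(pars["kon"]) * 1000.0; // l/nmol/min -> (nmol/ml)^-1 min^-1
  P.koff  = as<double>(pars["koff"]);
  P.kidney = as<int>(pars["kidney"]) - 1;     // 1-based from R
  P.inf_rate = as<double>(pars["inf_rate"]);
  P.t_inf    = as<double>(pars["t_inf"]);
  P.lambda   = as<double>(pars["lambda"]);
  P.lf       = as<double>(pars["lf"]);
  P.two      = as<bool>(pars["two_species"]);
  P.off.set_size(P.norg);
  int k = 3;
  for (int o = 0; o < P.norg; ++o) {
    P.off[o] = k;
    k += P.psma[o] ? 4 : 2;
  }
  P.m = k;
  P.n = P.two ? 2 * k : k;
  return P;
}

// RHS of one species block; `xo` points at the other species block (receptor
// competition) or is null. `x`/`dx` point at this species block.
static void species_rhs(const double* x, double* dx, const PbpkPars& P,
                        const double* xo, double input_rate) {
  const double Cs = x[0] / P.Vs, Cc = x[1] / P.Vs;
  double ds = input_rate - P.TER * Cs;
  double dc = -P.CLcat * Cc;
  double du = (1.0 - P.fu) * P.TER * Cs + P.CLcat * Cc;
  for (int o = 0; o < P.norg; ++o) {
    const int k = P.off[o];
    const double Cv = x[k] / P.Vv[o], Cf = x[k + 1] / P.Vf[o];
    double dv = P.F[o] * (Cs - Cv) - P.PS[o] * (Cv - Cf);
    double df = P.PS[o] * (Cv - Cf);
    ds += P.F[o] * (Cv - Cs);
    if (P.psma[o]) {
      const double bo = xo ? xo[k + 2] : 0.0;
      const double Rfree = P.Rtot[o] - x[k + 2] - bo;
      const double bind = P.konp * Cf * Rfree - P.koff * x[k + 2];
      df -= bind;
      double dn = P.lint[o] * x[k + 2] - P.lrel[o] * x[k + 3];
      if (o == P.kidney) dn += P.fu * P.TER * Cs;
      dc += P.lrel[o] * x[k + 3];
      dx[k + 2] = bind - P.lint[o] * x[k + 2];
      dx[k + 3] = dn;
    }
    dx[k] = dv;
    dx[k + 1] = df;
  }
  dx[0] = ds; dx[1] = dc; dx[2] = du;
}

static void rhs(double t, const arma::vec& x, arma::vec& dx, const PbpkPars& P) {
  dx.zeros();
  const double irt = (t < P.t_inf) ? P.inf_rate : 0.0;
  if (!P.two) {
    species_rhs(x.memptr(), dx.memptr(), P, nullptr, irt);
  } else {
    const double ir_l = irt * P.lf * std::exp(-P.lambda * t); // vial decays too
    const double ir_u = irt - ir_l;
    species_rhs(x.memptr(), dx.memptr(), P, x.memptr() + P.m, ir_l);
    species_rhs(x.memptr() + P.m, dx.memptr() + P.m, P, x.memptr(), ir_u);
    for (int i = 0; i < P.m; ++i) {
      const double d = P.lambda * x[i];
      dx[i] -= d;
      dx[i + P.m] += d;
    }
  }
}

// Explicit time derivative of the RHS (nonzero only while the labeled
// infusion decays in two-species mode).
static void dfdt(double t, arma::vec& T, const PbpkPars& P) {
  T.zeros();
  if (P.two && t < P.t_inf) {
    const double d = -P.lambda * P.inf_rate * P.lf * std::exp(-P.lambda * t);
    T[0] += d;
    T[P.m] -= d;
  }
}

// In-place LU with partial pivoting (column-major), small dense systems.
static bool lu_factor(arma::mat& A, arma::ivec& piv) {
  const int n = A.n_rows;
  for (int k = 0; k < n; ++k) {
    int p = k;
    double amax = std::fabs(A(k, k));
    for (int i = k + 1; i < n; ++i) {
      const double v = std::fabs(A(i, k));
      if (v > amax) { amax = v; p = i; }
    }
    if (amax == 0.0) return false;
    piv[k] = p;
    if (p != k) A.swap_rows(p, k);
    const double d = 1.0 / A(k, k);
    for (int i = k + 1; i < n; ++i) A(i, k) *= d;
    for (int j = k + 1; j < n; ++j) {
      const double ak = A(k, j);
      if (ak != 0.0) {
        double* col = A.colptr(j);
        const double* lk = A.colptr(k);
        for (int i = k + 1; i < n; ++i) col[i] -= lk[i] * ak;
      }
    }
  }
  return true;
}

static void lu_solve(const arma::mat& A, const arma::ivec& piv, arma::vec& b) {
  const int n = A.n_rows;
  for (int k = 0; k < n; ++k) {
    const int p = piv[k];
    if (p != k) std::swap(b[p], b[k]);
    const double* lk = A.colptr(k);
    const double bk = b[k];
    for (int i = k + 1; i < n; ++i) b[i] -= lk[i] * bk;
  }
  for (int k = n - 1; k >= 0; --k) {
    b[k] /= A(k, k);
    const double bk = b[k];
    const double* uk = A.colptr(k);
    for (int i = 0; i < k; ++i) b[i] -= uk[i] * bk;
  }
}

// The iteration matrix W = I - h*d*J is block-arrow: per-organ diagonal
// blocks (4 or 2 states per species) coupled to a small border (serum,
// catabolite, urine per species). Factor the organ blocks, form the Schur
// complement on the border and solve in O(n) instead of O(n^3).
struct ArrowW {
  const PbpkPars* P;
  int S, nB;
  std::vector<arma::mat> D, Y, R;
  std::vector<arma::ivec> piv;
  std::vector<arma::vec> z;
  std::vector<arma::uvec> idx;
  arma::mat BB;
  arma::ivec pivB;
  arma::uvec idxB;
  arma::vec bB, col;

  void init(const PbpkPars& pars) {
    P = &pars;
    S = pars.two ? 2 : 1;
    nB = 3 * S;
    const int norg = P->norg;
    D.resize(norg); Y.resize(norg); R.resize(norg);
    piv.resize(norg); z.resize(norg); idx.resize(norg);
    for (int o = 0; o < norg; ++o) {
      const int sz = P->psma[o] ? 4 : 2, bs = S * sz;
      D[o].set_size(bs, bs); Y[o].set_size(bs, nB); R[o].set_size(nB, bs);
      piv[o].set_size(bs); z[o].set_size(bs); idx[o].set_size(bs);
      for (int s = 0; s < S; ++s)
        for (int i = 0; i < sz; ++i)
          idx[o][s * sz + i] = s * P->m + P->off[o] + i;
    }
    BB.set_size(nB, nB); pivB.set_size(nB); bB.set_size(nB); col.set_size(8);
    idxB.set_size(nB);
    for (int s = 0; s < S; ++s)
      for (int i = 0; i < 3; ++i) idxB[s * 3 + i] = s * P->m + i;
  }

  bool factor(const arma::vec& x, double hd) {
    const PbpkPars& Pp = *P;
    const double iVs = 1.0 / Pp.Vs;
    const double sumF = arma::accu(Pp.F);
    BB.zeros();
    for (int s = 0; s < S; ++s) {
      const int b0 = 3 * s;
      BB(b0, b0) = -(Pp.TER + sumF) * iVs;
      BB(b0 + 1, b0 + 1) = -Pp.CLcat * iVs;
      BB(b0 + 2, b0) = (1 - Pp.fu) * Pp.TER * iVs;
      BB(b0 + 2, b0 + 1) = Pp.CLcat * iVs;
    }
    if (Pp.two)
      for (int i = 0; i < 3; ++i) {
        BB(i, i) -= Pp.lambda;
        BB(3 + i, i) += Pp.lambda;
      }
    BB *= -hd;
    BB.diag() += 1.0;
    for (int o = 0; o < Pp.norg; ++o) {
      const int sz = Pp.psma[o] ? 4 : 2;
      arma::mat &Do = D[o], &Yo = Y[o], &Ro = R[o];
      Do.zeros(); Yo.zeros(); Ro.zeros();
      const double iVv = 1.0 / Pp.Vv[o], iVf = 1.0 / Pp.Vf[o];
      for (int s = 0; s < S; ++s) {
        const int l0 = s * sz, g0 = s * Pp.m + Pp.off[o], b0 = 3 * s;
        Do(l0, l0) = -(Pp.F[o] + Pp.PS[o]) * iVv;
        Do(l0, l0 + 1) = Pp.PS[o] * iVf;
        Do(l0 + 1, l0) = Pp.PS[o] * iVv;
        Do(l0 + 1, l0 + 1) = -Pp.PS[o] * iVf;
        if (Pp.psma[o]) {
          const double bo = Pp.two ? x[(1 - s) * Pp.m + Pp.off[o] + 2] : 0.0;
          const double Cf = x[g0 + 1] * iVf;
          const double Rfree = Pp.Rtot[o] - x[g0 + 2] - bo;
          const double gf = Pp.konp * Rfree * iVf;
          const double gb = -Pp.konp * Cf - Pp.koff;
          Do(l0 + 1, l0 + 1) -= gf;
          Do(l0 + 1, l0 + 2) = -gb;
          Do(l0 + 2, l0 + 1) = gf;
          Do(l0 + 2, l0 + 2) = gb - Pp.lint[o];
          Do(l0 + 3, l0 + 2) = Pp.lint[o];
          Do(l0 + 3, l0 + 3) = -Pp.lrel[o];
          if (Pp.two) {
            const int lo = (1 - s) * sz;
            Do(l0 + 1, lo + 2) += Pp.konp * Cf;
            Do(l0 + 2, lo + 2) -= Pp.konp * Cf;
          }
          Ro(b0 + 1, l0 + 3) = Pp.lrel[o];
          if (o == Pp.kidney) Yo(l0 + 3, b0) = Pp.fu * Pp.TER * iVs;
        }
        Yo(l0, b0) = Pp.F[o] * iVs;
        Ro(b0, l0) = Pp.F[o] * iVv;
      }
      if (Pp.two)
        for (int i = 0; i < sz; ++i) {
          Do(i, i) -= Pp.lambda;
          Do(sz + i, i) += Pp.lambda;
        }
      Do *= -hd;
      Do.diag() += 1.0;
      Yo *= -hd;
      Ro *= -hd;
      if (!lu_factor(Do, piv[o])) return false;
      for (int j = 0; j < nB; ++j) {
        arma::vec cj = Yo.col(j);
        lu_solve(Do, piv[o], cj);
        Yo.col(j) = cj;
      }
      BB -= Ro * Yo;
    }
    return lu_factor(BB, pivB);
  }

  void solve(arma::vec& b) {
    for (int i = 0; i < nB; ++i) bB[i] = b[idxB[i]];
    for (size_t o = 0; o < D.size(); ++o) {
      arma::vec& zo = z[o];
      for (arma::uword i = 0; i < idx[o].n_elem; ++i) zo[i] = b[idx[o][i]];
      lu_solve(D[o], piv[o], zo);
      bB -= R[o] * zo;
    }
    lu_solve(BB, pivB, bB);
    for (size_t o = 0; o < D.size(); ++o) {
      const arma::vec xo = z[o] - Y[o] * bB;
      for (arma::uword i = 0; i < idx[o].n_elem; ++i) b[idx[o][i]] = xo[i];
    }
    for (int i = 0; i < nB; ++i) b[idxB[i]] = bB[i];
  }
};

// Cubic Hermite interpolation inside an accepted step.
static arma::vec hermite(double theta, double h, const arma::vec& y0,
                         const arma::vec& y1, const arma::vec& f0,
                         const arma::vec& f1) {
  const double h00 = (1 + 2 * theta) * (1 - theta) * (1 - theta);
  const double h10 = theta * (1 - theta) * (1 - theta);
  const double h01 = theta * theta * (3 - 2 * theta);
  const double h11 = theta * theta * (theta - 1);
  return h00 * y0 + (h10 * h) * f0 + h01 * y1 + (h11 * h) * f1;
}

// Integrate one smooth segment [t0, t1], writing requested output times.
// Returns number of steps, throws on failure.
static int integrate_segment(double t0, double t1, arma::vec& y,
                             const PbpkPars& P, double rtol, double atol,
                             double hmax, int max_steps,
                             const arma::vec& out_t, arma::mat& out,
                             int& out_idx, double scale_amount) {
  const double d = 1.0 / (2.0 + std::sqrt(2.0));
  const double e32 = 6.0 + std::sqrt(2.0);
  const int n = P.n;
  arma::vec f0(n), f1(n), f2(n), k1(n), k2(n), k3(n), Tv(n), ynew(n), err(n),
      ytmp(n);
  ArrowW W;
  W.init(P);
  double t = t0;
  double h = std::min({1e-2, (t1 - t0) / 10.0, hmax});
  int nsteps = 0, nfail = 0;
  rhs(t, y, f0, P);
  while (t < t1 - 1e-12 * t1) {
    if (++nsteps > max_steps)
      stop("PBPK integration exceeded max_steps (%d) at t=%g min", max_steps, t);
    if (t + h > t1) h = t1 - t;
    dfdt(t, Tv, P);
    if (!W.factor(y, h * d))
      stop("PBPK integration: singular iteration matrix at t=%g min", t);
    k1 = f0 + (h * d) * Tv;
    W.solve(k1);
    ytmp = y + (0.5 * h) * k1;
    rhs(t + 0.5 * h, ytmp, f1, P);
    k2 = f1 - k1;
    W.solve(k2);
    k2 += k1;
    ynew = y + h * k2;
    rhs(t + h, ynew, f2, P);
    k3 = f2 - e32 * (k2 - f1) - 2.0 * (k1 - f0) + (h * d) * Tv;
    W.solve(k3);
    err = (h / 6.0) * (k1 - 2.0 * k2 + k3);
    // weighted rms error norm
    double en = 0.0;
    for (int i = 0; i < n; ++i) {
      const double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      const double e = err[i] / sc;
      en += e * e;
    }
    en = std::sqrt(en / n);
    if (en <= 1.0) {
      // accept; emit dense output inside (t, t+h]
      while (out_idx < (int)out_t.n_elem && out_t[out_idx] <= t + h + 1e-12) {
        const double theta = (out_t[out_idx] - t) / h;
        out.col(out_idx) = hermite(theta, h, y, ynew, f0, f2);
        ++out_idx;
      }
      t += h;
      y = ynew;
      f0 = f2;
      // guard against runaway negativity; zero out rounding-level dips
      double ymin = y.min();
      if (ymin < -std::max(1e-6 * scale_amount, 1e-6))
        stop("PBPK integration: state went negative (%g nmol) at t=%g min", ymin, t);
      if (ymin < 0) y.transform([](double v) { return v < 0 ? 0.0 : v; });
      nfail = 0;
      h = std::min(hmax, h * std::min(5.0, std::max(0.2, 0.8 * std::pow(en + 1e-16, -1.0 / 3.0))));
    } else {
      if (++nfail > 30)
        stop("PBPK integration: repeated step rejections at t=%g min", t);
      h = std::max(h * std::max(0.2, 0.8 * std::pow(en, -1.0 / 3.0)), 1e-12);
    }
  }
  return nsteps;
}

//' @noRd
// [[Rcpp::export(name = ".pbpk_integrate")]]
List pbpk_integrate(List pars, NumericVector out_times, double rtol,
                    double atol, double hmax, int max_steps) {
  PbpkPars P = unpack(pars);
  arma::vec tt = as<arma::vec>(out_times);
  if (tt.n_elem < 1 || tt[0] < 0) stop("output times must start at t >= 0");
  for (arma::uword i = 1; i < tt.n_elem; ++i)
    if (tt[i] <= tt[i - 1]) stop("output times must be strictly increasing");
  arma::vec y(P.n, arma::fill::zeros);
  const double amount = (P.t_inf > 0) ? P.inf_rate * P.t_inf : P.inf_rate;
  if (P.t_inf <= 0) { // bolus administration
    if (!P.two) y[0] = amount;
    else { y[0] = amount * P.lf; y[P.m] = amount * (1 - P.lf); }
  }
  arma::mat out(P.n, tt.n_elem);
  int out_idx = 0;
  // t = 0 output
  while (out_idx < (int)tt.n_elem && tt[out_idx] <= 0) {
    out.col(out_idx) = y;
    ++out_idx;
  }
  const double tend = tt[tt.n_elem - 1];
  int nsteps = 0;
  if (tend > 0) {
    if (P.t_inf > 0 && P.t_inf < tend) {
      nsteps += integrate_segment(0.0, P.t_inf, y, P, rtol, atol, hmax,
                                  max_steps, tt, out, out_idx, amount);
      nsteps += integrate_segment(P.t_inf, tend, y, P, rtol, atol, hmax,
                                  max_steps - nsteps, tt, out, out_idx, amount);
    } else {
      nsteps += integrate_segment(0.0, tend, y, P, rtol, atol, hmax, max_steps,
                                  tt, out, out_idx, amount);
    }
  }
  if (out_idx != (int)tt.n_elem) stop("internal: dense output incomplete");
  return List::create(_["states"] = wrap(out.t()), _["nsteps"] = nsteps,
                      _["m"] = P.m);
}
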
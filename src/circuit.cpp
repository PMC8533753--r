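#include <Rcpp.h>
using namespace Rcpp;

// Shifted Hill multiplier: lam + (1 - lam) / (1 + (A/A0)^n).
// Interpolates between 1 (no regulator) and lam (saturation).
inline double hs(double A, double A0, double n, double lam) {
  double r = std::pow(A / A0, n);
  return lam + (1.0 - lam) / (1.0 + r);
}

// Combinatorial microRNA-binding weights for a transcript carrying 6 sites:
// M_i(u) = C(6,i) (u/u0)^i / (1 + u/u0)^6, weighted by a coefficient vector.
inline double mir_sum(double u, double u0, const double* coef) {
  static const double binom[7] = {1, 6, 15, 20, 15, 6, 1};
  double m = u / u0, denom = std::pow(1.0 + m, 6), acc = 0.0, p = 1.0;
  for (int i = 0; i <= 6; ++i) {
    acc += coef[i] * binom[i] * p;
    p *= m;
  }
  return acc / denom;
}

struct Model {
  int n, ne;
  const double *g, *k;
  const int *clamped;
  const int *esrc, *etgt;       // 0-based
  const double *thr, *hill, *lam;
  bool has_mirna;
  int mir, mrna, prot;          // 0-based; -1 when absent
  double u0;
  const double *l, *gm, *gu;    // translation / mRNA-loss / miR-loss weights
};

static Model unpack(const List& m) {
  Model M;
  M.g = REAL(as<NumericVector>(m["g"]));
  M.k = REAL(as<NumericVector>(m["k"]));
  M.clamped = INTEGER(as<IntegerVector>(m["clamped"]));
  M.n = as<NumericVector>(m["g"]).size();
  IntegerVector es = m["esrc"], et = m["etgt"];
  M.esrc = INTEGER(es); M.etgt = INTEGER(et);
  M.ne = es.size();
  M.thr = REAL(as<NumericVector>(m["thr"]));
  M.hill = REAL(as<NumericVector>(m["hill"]));
  M.lam = REAL(as<NumericVector>(m["lam"]));
  M.has_mirna = as<bool>(m["has_mirna"]);
  if (M.has_mirna) {
    M.mir = as<int>(m["mir"]); M.mrna = as<int>(m["mrna"]); M.prot = as<int>(m["prot"]);
    M.u0 = as<double>(m["u0"]);
    M.l = REAL(as<NumericVector>(m["l"]));
    M.gm = REAL(as<NumericVector>(m["gm"]));
    M.gu = REAL(as<NumericVector>(m["gu"]));
  } else {
    M.mir = M.mrna = M.prot = -1; M.u0 = 1;
    M.l = M.gm = M.gu = nullptr;
  }
  return M;
}

// dx/dt for the full circuit; thr may be overridden (epigenetic feedback).
static void rhs(const Model& M, const double* x, double* dx, const double* thr) {
  for (int j = 0; j < M.n; ++j) {
    if (M.clamped[j]) { dx[j] = 0.0; continue; }
    double prod = M.g[j];
    if (M.has_mirna && j == M.prot) {
      // protein translated from its mRNA, attenuated by microRNA binding
      prod *= x[M.mrna] * mir_sum(x[M.mir], M.u0, M.l);
    }
    dx[j] = prod;
  }
  for (int e = 0; e < M.ne; ++e) {
    int t = M.etgt[e];
    if (M.clamped[t]) continue;
    dx[t] *= hs(x[M.esrc[e]], thr[e], M.hill[e], M.lam[e]);
  }
  for (int j = 0; j < M.n; ++j) {
    if (M.clamped[j]) continue;
    dx[j] -= M.k[j] * x[j];
  }
  if (M.has_mirna) {
    double u = x[M.mir], mz = x[M.mrna];
    if (!M.clamped[M.mrna]) dx[M.mrna] -= mz * mir_sum(u, M.u0, M.gm);
    if (!M.clamped[M.mir])  dx[M.mir]  -= mz * mir_sum(u, M.u0, M.gu);
  }
}

static void rk4_step(const Model& M, double* x, double dt, const double* thr,
                     double* k1, double* k2, double* k3, double* k4, double* tmp) {
  int n = M.n;
  rhs(M, x, k1, thr);
  for (int j = 0; j < n; ++j) tmp[j] = x[j] + 0.5 * dt * k1[j];
  rhs(M, tmp, k2, thr);
  for (int j = 0; j < n; ++j) tmp[j] = x[j] + 0.5 * dt * k2[j];
  rhs(M, tmp, k3, thr);
  for (int j = 0; j < n; ++j) tmp[j] = x[j] + dt * k3[j];
  rhs(M, tmp, k4, thr);
  for (int j = 0; j < n; ++j) {
    x[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    if (x[j] < 0.0) x[j] = 0.0;
  }
}

// [[Rcpp::export(name = ".rhs_cpp")]]
NumericVector rhs_cpp(NumericVector x, List model) {
  Model M = unpack(model);
  NumericVector dx(M.n);
  rhs(M, REAL(x), REAL(dx), M.thr);
  return dx;
}

// Relax many initial conditions to (stable) fixed points by RK4 with early exit
// once max |dx| / (|x| + 1) < tol.
// [[Rcpp::export(name = ".settle_cpp")]]
List settle_cpp(NumericMatrix X0, List model, double t_max, double dt,
                double tol, int check_every) {
  Model M = unpack(model);
  int m = X0.nrow(), n = M.n;
  NumericMatrix out(m, n);
  LogicalVector conv(m);
  std::vector<double> x(n), k1(n), k2(n), k3(n), k4(n), tmp(n), dx(n);
  long nstep = (long)std::ceil(t_max / dt);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) x[j] = X0(i, j);
    bool ok = false;
    for (long s = 0; s < nstep; ++s) {
      rk4_step(M, x.data(), dt, M.thr, k1.data(), k2.data(), k3.data(), k4.data(), tmp.data());
      if ((s + 1) % check_every == 0) {
        rhs(M, x.data(), dx.data(), M.thr);
        double worst = 0.0;
        for (int j = 0; j < n; ++j) {
          double r = std::fabs(dx[j]) / (std::fabs(x[j]) + 1.0);
          if (r > worst) worst = r;
        }
        if (worst < tol) { ok = true; break; }
      }
    }
    for (int j = 0; j < n; ++j) out(i, j) = x[j];
    conv[i] = ok;
  }
  return List::create(_["states"] = out, _["converged"] = conv);
}

// One cell of the stochastic population model. The external signal node
// (i_node) follows an Euler-Maruyama Ornstein-Uhlenbeck update driven by the
// pre-generated standard-normal increments xi; two edge thresholds (e1: the
// KLF4 -| SNAIL edge, e2: SNAIL -| KLF4) carry slow epigenetic dynamics; the
// circuit ODEs are advanced by `substeps` RK4 steps between signal updates.
// epi_form: 0 = saturating occupancy, 1 = linear level, 2 = constant alpha.
// [[Rcpp::export(name = ".simulate_cell_cpp")]]
List simulate_cell_cpp(NumericVector x0, List model, int i_node,
                       double I0, double beta, double Nnoise,
                       NumericVector xi, double dt, int substeps,
                       bool epi_on, int e1, int e2, int sil1, int sil2,
                       double a1, double a2, double zeta,
                       double base1, double base2, int epi_form,
                       int record_every, int zeb_node) {
  Model M = unpack(model);
  int n = M.n, nstep = xi.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> thr(M.thr, M.thr + M.ne);
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);
  double KS0 = epi_on ? thr[e1] : 0.0, SK0 = epi_on ? thr[e2] : 0.0;
  double floor1 = 1e-4 * base1, floor2 = 1e-4 * base2;
  int nrec = nstep / record_every;
  NumericVector t_rec(nrec), zeb_rec(nrec), I_rec(nrec), ks0_rec(nrec), sk0_rec(nrec);
  double sq = std::sqrt(Nnoise * dt);
  double h = dt / substeps;
  int r = 0;
  for (int s = 0; s < nstep; ++s) {
    // OU update of the external signal
    double I = x[i_node];
    I += beta * (I0 - I) * dt + sq * xi[s];
    if (I < 0.0) I = 0.0;
    x[i_node] = I;
    if (epi_on) {
      double occ1, occ2;
      double K = x[sil1], S = x[sil2];
      if (epi_form == 0) { occ1 = K / (K + base1); occ2 = S / (S + base2); }
      else if (epi_form == 1) { occ1 = K / base1; occ2 = S / base2; }
      else { occ1 = 1.0; occ2 = 1.0; }
      KS0 += dt / zeta * (base1 - KS0 - a1 * occ1 * base1);
      SK0 += dt / zeta * (base2 - SK0 - a2 * occ2 * base2);
      if (KS0 < floor1) KS0 = floor1;
      if (SK0 < floor2) SK0 = floor2;
      thr[e1] = KS0; thr[e2] = SK0;
    }
    for (int ss = 0; ss < substeps; ++ss)
      rk4_step(M, x.data(), h, thr.data(), k1.data(), k2.data(), k3.data(), k4.data(), tmp.data());
    if ((s + 1) % record_every == 0 && r < nrec) {
      t_rec[r] = (s + 1) * dt;
      zeb_rec[r] = x[zeb_node];
      I_rec[r] = x[i_node];
      ks0_rec[r] = KS0; sk0_rec[r] = SK0;
      ++r;
    }
  }
  return List::create(_["time"] = t_rec, _["zeb"] = zeb_rec, _["I"] = I_rec,
                      _["KS0"] = ks0_rec, _["SK0"] = sk0_rec,
                      _["final"] = NumericVector(x.begin(), x.end()));
}
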
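// Compiled core: threshold tail probabilities, SIJR right-hand sides,
// adaptive Dormand-Prince ODE integration with dense output, exact
// event-driven (Gillespie) simulation, and the per-series Gamma
// log-likelihood used by the maximum-likelihood fitter.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const int MECH_COMPLEX = 1;
static const int MECH_SIMPLE = 2;

// ---------------------------------------------------------------------------
// Threshold tail probabilities
// ---------------------------------------------------------------------------

// Trinomial tail: P(K >= ti) + P(K < ti, L >= tj) for (K, L) ~ Multi(C; i, j).
// Coefficients precomputed once per (C, ti, tj); evaluation is a polynomial
// in (i, j, 1-i-j) so it is cheap inside the ODE right-hand side.
struct TriTail {
  int C, ti, tj;
  std::vector<double> coef; // (C+1)*(C+1); 0 outside support/region

  TriTail() : C(0), ti(0), tj(0) {}

  void init(int C_, int ti_, int tj_) {
    C = C_; ti = ti_; tj = tj_;
    coef.assign((C + 1) * (C + 1), 0.0);
    for (int k = 0; k <= C; ++k) {
      for (int l = 0; l + k <= C; ++l) {
        bool in_region = (k >= ti) || (l >= tj);
        if (!in_region) continue;
        int m = C - k - l;
        double lc = R::lgammafn(C + 1.0) - R::lgammafn(k + 1.0) -
                    R::lgammafn(l + 1.0) - R::lgammafn(m + 1.0);
        coef[k * (C + 1) + l] = std::exp(lc);
      }
    }
  }

  double eval(double i, double j) const {
    if (i < 0) i = 0;
    if (j < 0) j = 0;
    double s = i + j;
    if (s > 1.0) { i /= s; j /= s; } // clamp solver drift onto the simplex
    double rest = 1.0 - i - j;
    if (rest < 0) rest = 0;
    // power tables
    double ip[16], jp[16], rp[16];
    ip[0] = jp[0] = rp[0] = 1.0;
    for (int p = 1; p <= C; ++p) {
      ip[p] = ip[p - 1] * i;
      jp[p] = jp[p - 1] * j;
      rp[p] = rp[p - 1] * rest;
    }
    double out = 0.0;
    for (int k = 0; k <= C; ++k) {
      const double* row = &coef[k * (C + 1)];
      double acc = 0.0;
      for (int l = 0; l + k <= C; ++l) {
        if (row[l] != 0.0) acc += row[l] * jp[l] * rp[C - k - l];
      }
      out += acc * ip[k];
    }
    if (out < 0) out = 0;
    if (out > 1) out = 1;
    return out;
  }
};

// Binomial upper tail P(Y >= tr), Y ~ Bin(C, j), as a polynomial in j.
struct BinTail {
  int C, tr;
  std::vector<double> coef; // choose(C, y) for y >= tr else 0

  BinTail() : C(0), tr(0) {}

  void init(int C_, int tr_) {
    C = C_; tr = tr_;
    coef.assign(C + 1, 0.0);
    for (int y = tr; y <= C; ++y) coef[y] = R::choose((double)C, (double)y);
  }

  double eval(double j) const {
    if (j < 0) j = 0;
    if (j > 1) j = 1;
    double q = 1.0 - j;
    double jp[16], qp[16];
    jp[0] = qp[0] = 1.0;
    for (int p = 1; p <= C; ++p) { jp[p] = jp[p - 1] * j; qp[p] = qp[p - 1] * q; }
    double out = 0.0;
    for (int y = tr; y <= C; ++y) out += coef[y] * jp[y] * qp[C - y];
    if (out < 0) out = 0;
    if (out > 1) out = 1;
    return out;
  }
};

// [[Rcpp::export]]
NumericVector cpp_multi_tail(NumericVector i_frac, NumericVector j_frac,
                             int C, int tau_i, int tau_j) {
  TriTail tt; tt.init(C, tau_i, tau_j);
  R_xlen_t n = i_frac.size();
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) out[k] = tt.eval(i_frac[k], j_frac[k]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_binom_tail(NumericVector j_frac, int C, int tau_r) {
  BinTail bt; bt.init(C, tau_r);
  R_xlen_t n = j_frac.size();
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) out[k] = bt.eval(j_frac[k]);
  return out;
}

// ---------------------------------------------------------------------------
// Model right-hand sides (fractions, N = 1)
// ---------------------------------------------------------------------------

struct Model {
  int mech;
  // complex: beta, eps; simple: beta_i, beta_j, gamma, eps
  double beta, eps, beta_i, beta_j, gamma_;
  TriTail f_tail;
  BinTail g2_tail;

  void init_complex(double beta_, double eps_, int C, int ti, int tj, int tr) {
    mech = MECH_COMPLEX; beta = beta_; eps = eps_;
    f_tail.init(C, ti, tj);
    g2_tail.init(C, tr);
  }
  void init_simple(double bi, double bj, double g, double eps_) {
    mech = MECH_SIMPLE; beta_i = bi; beta_j = bj; gamma_ = g; eps = eps_;
  }

  // per-capita adoption and quit rates at state fractions
  double adopt_rate(double I, double J) const {
    if (mech == MECH_COMPLEX) return beta * f_tail.eval(I, J);
    return beta_i * I + beta_j * J;
  }
  double quit_rate(double J) const {
    if (mech == MECH_COMPLEX) return g2_tail.eval(J);
    return gamma_;
  }

  void rhs(const double* y, double* dy) const {
    double S = y[0], I = y[1], J = y[2];
    double f = adopt_rate(I, J);
    double g2 = quit_rate(J);
    dy[0] = -f * S;
    dy[1] = f * S - eps * I;
    dy[2] = eps * I - g2 * J;
    dy[3] = g2 * J;
  }
};

static Model make_model(int mech, NumericVector dyn, IntegerVector taus, int C) {
  Model m;
  if (mech == MECH_COMPLEX) {
    if (dyn.size() != 2 || taus.size() != 3) stop("complex model needs dyn=(beta,eps), taus=(tau_i,tau_j,tau_r)");
    m.init_complex(dyn[0], dyn[1], C, taus[0], taus[1], taus[2]);
  } else if (mech == MECH_SIMPLE) {
    if (dyn.size() != 4) stop("simple model needs dyn=(beta_i,beta_j,gamma,epsilon)");
    m.init_simple(dyn[0], dyn[1], dyn[2], dyn[3]);
  } else {
    stop("unknown mechanism code");
  }
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_rhs(int mech, NumericVector dyn, IntegerVector taus, int C,
                      NumericVector state) {
  Model m = make_model(mech, dyn, taus, C);
  double dy[4];
  double y[4] = { state[0], state[1], state[2], state[3] };
  m.rhs(y, dy);
  return NumericVector::create(dy[0], dy[1], dy[2], dy[3]);
}

// ---------------------------------------------------------------------------
// Adaptive Dormand-Prince 5(4) with cubic Hermite dense output onto a grid
// ---------------------------------------------------------------------------

static const int NDIM = 4;

struct SolveResult {
  std::vector<double> t;
  std::vector<double> y; // npts x 4, row-major
  bool ok;
};

static void dopri_solve(const Model& m, const double* y0, double t_max,
                        double dt, double rtol, double atol, double hmax,
                        SolveResult& res, long max_iter = 2000000) {
  int npts = (int)std::floor(t_max / dt + 1e-9) + 1;
  res.t.resize(npts);
  res.y.assign((size_t)npts * NDIM, NA_REAL);
  for (int p = 0; p < npts; ++p) res.t[p] = p * dt;
  res.ok = true;

  double y[NDIM], ynew[NDIM], ytmp[NDIM];
  double k1[NDIM], k2[NDIM], k3[NDIM], k4[NDIM], k5[NDIM], k6[NDIM], k7[NDIM];
  for (int d = 0; d < NDIM; ++d) y[d] = y0[d];

  double t = 0.0;
  int next_pt = 0;
  // grid point at t = 0
  res.y[0] = y[0]; res.y[1] = y[1]; res.y[2] = y[2]; res.y[3] = y[3];
  next_pt = 1;

  m.rhs(y, k1); // FSAL seed
  double h = std::min(0.01, hmax);
  long iter = 0;

  while (t < t_max - 1e-12 && next_pt < npts) {
    if (++iter > max_iter) { res.ok = false; return; }
    if (t + h > t_max) h = t_max - t;

    // Dormand-Prince stages
    for (int d = 0; d < NDIM; ++d) ytmp[d] = y[d] + h * (0.2 * k1[d]);
    m.rhs(ytmp, k2);
    for (int d = 0; d < NDIM; ++d) ytmp[d] = y[d] + h * (3.0/40.0*k1[d] + 9.0/40.0*k2[d]);
    m.rhs(ytmp, k3);
    for (int d = 0; d < NDIM; ++d) ytmp[d] = y[d] + h * (44.0/45.0*k1[d] - 56.0/15.0*k2[d] + 32.0/9.0*k3[d]);
    m.rhs(ytmp, k4);
    for (int d = 0; d < NDIM; ++d) ytmp[d] = y[d] + h * (19372.0/6561.0*k1[d] - 25360.0/2187.0*k2[d] + 64448.0/6561.0*k3[d] - 212.0/729.0*k4[d]);
    m.rhs(ytmp, k5);
    for (int d = 0; d < NDIM; ++d) ytmp[d] = y[d] + h * (9017.0/3168.0*k1[d] - 355.0/33.0*k2[d] + 46732.0/5247.0*k3[d] + 49.0/176.0*k4[d] - 5103.0/18656.0*k5[d]);
    m.rhs(ytmp, k6);
    for (int d = 0; d < NDIM; ++d) ynew[d] = y[d] + h * (35.0/384.0*k1[d] + 500.0/1113.0*k3[d] + 125.0/192.0*k4[d] - 2187.0/6784.0*k5[d] + 11.0/84.0*k6[d]);
    m.rhs(ynew, k7);

    // embedded error estimate
    double errnorm = 0.0;
    for (int d = 0; d < NDIM; ++d) {
      double e = h * (71.0/57600.0*k1[d] - 71.0/16695.0*k3[d] + 71.0/1920.0*k4[d]
                      - 17253.0/339200.0*k5[d] + 22.0/525.0*k6[d] - 1.0/40.0*k7[d]);
      double sc = atol + rtol * std::max(std::fabs(y[d]), std::fabs(ynew[d]));
      double r = e / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / NDIM);

    if (!std::isfinite(errnorm)) { res.ok = false; return; }

    if (errnorm <= 1.0) {
      // accept; fill grid points in (t, t+h] by cubic Hermite on (y, k1, ynew, k7)
      double tnew = t + h;
      while (next_pt < npts && res.t[next_pt] <= tnew + 1e-12) {
        double th = (res.t[next_pt] - t) / h;
        double th2 = th * th, th3 = th2 * th;
        double h00 = 2*th3 - 3*th2 + 1, h10 = th3 - 2*th2 + th;
        double h01 = -2*th3 + 3*th2, h11 = th3 - th2;
        for (int d = 0; d < NDIM; ++d) {
          res.y[(size_t)next_pt * NDIM + d] =
            h00 * y[d] + h10 * h * k1[d] + h01 * ynew[d] + h11 * h * k7[d];
        }
        ++next_pt;
      }
      t = tnew;
      for (int d = 0; d < NDIM; ++d) { y[d] = ynew[d]; k1[d] = k7[d]; }
      double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
      h *= std::min(5.0, std::max(0.2, fac));
      if (h > hmax) h = hmax;
    } else {
      double fac = 0.9 * std::pow(errnorm, -0.2);
      h *= std::max(0.2, fac);
      if (h < 1e-12) { res.ok = false; return; }
    }
  }
}

static bool solve_model(const Model& m, double I0, double t_max, double dt,
                        double rtol, SolveResult& res, long max_iter = 2000000) {
  double y0[4] = { 1.0 - I0, I0, 0.0, 0.0 };
  dopri_solve(m, y0, t_max, dt, rtol, rtol * 1e-2, 1.0, res, max_iter);
  return res.ok;
}

// likelihood-path guards: reject parameter regions no weekly-scale fad can
// occupy instead of letting the solver grind there
static const double MAX_RATE = 200.0;   // per week
static const long FIT_MAX_STEPS = 30000;

// [[Rcpp::export]]
NumericMatrix cpp_solve(int mech, NumericVector dyn, IntegerVector taus, int C,
                        double I0, double t_max, double dt, double rtol) {
  Model m = make_model(mech, dyn, taus, C);
  SolveResult res;
  if (!solve_model(m, I0, t_max, dt, rtol, res))
    stop("ODE solver failed (step size underflow or non-finite state)");
  int npts = (int)res.t.size();
  NumericMatrix out(npts, 5);
  for (int p = 0; p < npts; ++p) {
    out(p, 0) = res.t[p];
    for (int d = 0; d < NDIM; ++d) out(p, d + 1) = res.y[(size_t)p * NDIM + d];
  }
  colnames(out) = CharacterVector::create("time", "S", "I", "J", "R");
  return out;
}

// mu(t) = max(I,0) + max(J,0), linear interpolation; t < 0 reads mu(0)
static double mu_at(const SolveResult& res, double dt, double tm) {
  int npts = (int)res.t.size();
  if (tm <= 0) {
    double I = res.y[1], J = res.y[2];
    return std::max(I, 0.0) + std::max(J, 0.0);
  }
  double idx = tm / dt;
  int lo = (int)std::floor(idx);
  if (lo >= npts - 1) lo = npts - 2;
  double w = idx - lo;
  if (w < 0) w = 0;
  if (w > 1) w = 1;
  double Ilo = std::max(res.y[(size_t)lo * NDIM + 1], 0.0);
  double Jlo = std::max(res.y[(size_t)lo * NDIM + 2], 0.0);
  double Ihi = std::max(res.y[(size_t)(lo + 1) * NDIM + 1], 0.0);
  double Jhi = std::max(res.y[(size_t)(lo + 1) * NDIM + 2], 0.0);
  return (1 - w) * (Ilo + Jlo) + w * (Ihi + Jhi);
}

// ---------------------------------------------------------------------------
// Gamma log-likelihood of a weekly series under the observation model
// ---------------------------------------------------------------------------

// Observation weeks are 0..T-1; observation at week t reads the model at
// t + dshift. Means floored at mean_floor_frac * A.
// Returns -Inf for invalid/unsolvable parameter sets.

// [[Rcpp::export]]
double cpp_series_loglik(int mech, NumericVector dyn, IntegerVector taus, int C,
                         double I0, double A, double dshift, double r,
                         NumericVector y, double dt, double rtol,
                         double mean_floor_frac, double censor_limit) {
  int T = y.size();
  if (!(A > 0) || !std::isfinite(A) || !(r > 1e-3) || !std::isfinite(r)) return R_NegInf;
  if (!(I0 > 1e-12) || I0 >= 1.0) return R_NegInf;
  for (int k = 0; k < dyn.size(); ++k)
    if (!std::isfinite(dyn[k]) || dyn[k] < 0 || dyn[k] > MAX_RATE) return R_NegInf;
  if (!std::isfinite(dshift) || std::fabs(dshift) > 8.0 * T) return R_NegInf;

  double t_need = (T - 1) + dshift;
  double t_max = std::max(2.0 * dt, t_need + dt);
  if (t_max > 1200.0) return R_NegInf;

  Model m = make_model(mech, dyn, taus, C);
  SolveResult res;
  if (!solve_model(m, I0, t_max, dt, rtol, res, FIT_MAX_STEPS)) return R_NegInf;

  double floor_m = mean_floor_frac * A;
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double mean = A * mu_at(res, dt, t + dshift);
    if (mean < floor_m) mean = floor_m;
    double l;
    if (censor_limit > 0 && y[t] < censor_limit) {
      // rounded-to-zero week: the observation was below the reporting
      // threshold, so it contributes the interval probability
      l = R::pgamma(censor_limit, r, mean / r, 1, 1);
    } else {
      l = R::dgamma(y[t], r, mean / r, 1);
    }
    if (!std::isfinite(l)) return R_NegInf;
    ll += l;
  }
  return ll;
}

// Two-sub-population version: same mechanism, shared shape r (and shared
// thresholds for the complex mechanism); observation mean is the sum of the
// two sub-population means.

// [[Rcpp::export]]
double cpp_series_loglik2(int mech, NumericVector dyn1, NumericVector dyn2,
                          IntegerVector taus, int C,
                          double I01, double I02, double A1, double A2,
                          double d1, double d2, double r,
                          NumericVector y, double dt, double rtol,
                          double mean_floor_frac, double censor_limit) {
  int T = y.size();
  if (!(A1 > 0) || !std::isfinite(A1) || !(A2 > 0) || !std::isfinite(A2)) return R_NegInf;
  if (!(r > 1e-3) || !std::isfinite(r)) return R_NegInf;
  if (!(I01 > 1e-12) || I01 >= 1.0 || !(I02 > 1e-12) || I02 >= 1.0) return R_NegInf;
  for (int k = 0; k < dyn1.size(); ++k)
    if (!std::isfinite(dyn1[k]) || dyn1[k] < 0 || dyn1[k] > MAX_RATE) return R_NegInf;
  for (int k = 0; k < dyn2.size(); ++k)
    if (!std::isfinite(dyn2[k]) || dyn2[k] < 0 || dyn2[k] > MAX_RATE) return R_NegInf;
  if (!std::isfinite(d1) || std::fabs(d1) > 8.0 * T) return R_NegInf;
  if (!std::isfinite(d2) || std::fabs(d2) > 8.0 * T) return R_NegInf;

  double t_max1 = std::max(2.0 * dt, (T - 1) + d1 + dt);
  double t_max2 = std::max(2.0 * dt, (T - 1) + d2 + dt);
  if (t_max1 > 1200.0 || t_max2 > 1200.0) return R_NegInf;

  Model m1 = make_model(mech, dyn1, taus, C);
  Model m2 = make_model(mech, dyn2, taus, C);
  SolveResult r1, r2;
  if (!solve_model(m1, I01, t_max1, dt, rtol, r1, FIT_MAX_STEPS)) return R_NegInf;
  if (!solve_model(m2, I02, t_max2, dt, rtol, r2, FIT_MAX_STEPS)) return R_NegInf;

  double floor_m = mean_floor_frac * (A1 + A2);
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double mean = A1 * mu_at(r1, dt, t + d1) + A2 * mu_at(r2, dt, t + d2);
    if (mean < floor_m) mean = floor_m;
    double l;
    if (censor_limit > 0 && y[t] < censor_limit) {
      l = R::pgamma(censor_limit, r, mean / r, 1, 1);
    } else {
      l = R::dgamma(y[t], r, mean / r, 1);
    }
    if (!std::isfinite(l)) return R_NegInf;
    ll += l;
  }
  return ll;
}

// ---------------------------------------------------------------------------
// Exact event-driven simulation of the continuous-time Markov chain
// ---------------------------------------------------------------------------

// Events: adoption S->I at rate S * f(I/N, J/N); progression I->J at rate
// eps * I; quitting J->R at rate J * g2(J/N) (complex) or gamma * J (simple).
// Uses R's RNG so runs are reproducible under set.seed().

// [[Rcpp::export]]
NumericMatrix cpp_gillespie(int mech, NumericVector dyn, IntegerVector taus,
                            int C, IntegerVector init, double t_max) {
  if (init.size() != 4) stop("init must be integer counts (S, I, J, R)");
  long S = init[0], I = init[1], J = init[2], Rr = init[3];
  if (S < 0 || I < 0 || J < 0 || Rr < 0) stop("counts must be non-negative");
  double N = (double)(S + I + J + Rr);
  if (N < 1) stop("population must contain at least one individual");

  Model m = make_model(mech, dyn, taus, C);

  // no replenishment (h = 0): at most 3N events
  long cap = 3 * (long)N + 1;
  std::vector<double> rows;
  rows.reserve((size_t)std::min(cap + 1, (long)4000000) * 6);

  double t = 0.0;
  int ev = 0;
  rows.insert(rows.end(), { t, (double)S, (double)I, (double)J, (double)Rr, 0.0 });

  GetRNGstate();
  for (long n_ev = 0; n_ev < cap; ++n_ev) {
    double i = I / N, j = J / N;
    double a1 = S * m.adopt_rate(i, j);
    double a2 = I * m.eps;
    double a3 = J * m.quit_rate(j);
    double atot = a1 + a2 + a3;
    if (atot <= 0) break;
    t += R::exp_rand() / atot;
    if (t > t_max) break;
    double u = R::unif_rand() * atot;
    if (u < a1)            { --S; ++I; ev = 1; }
    else if (u < a1 + a2)  { --I; ++J; ev = 2; }
    else                   { --J; ++Rr; ev = 3; }
    rows.insert(rows.end(), { t, (double)S, (double)I, (double)J, (double)Rr, (double)ev });
  }
  PutRNGstate();

  int nr = (int)(rows.size() / 6);
  NumericMatrix out(nr, 6);
  for (int p = 0; p < nr; ++p)
    for (int q = 0; q < 6; ++q) out(p, q) = rows[(size_t)p * 6 + q];
  colnames(out) = CharacterVector::create("time", "S", "I", "J", "R", "event");
  return out;
}
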
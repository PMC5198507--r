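// Method-of-steps integrator for the five-compartment delayed viral
// infection model.  Classical fourth-order one-step advance; delayed values
// are read from the cubic Hermite dense interpolant built segment by
// segment from the stored node states and derivatives.  Only models built
// entirely from the registered function forms take this fast path; custom
// forms fall back to the plain-R integrator with identical semantics.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int gcode;            // growth form
  const double *gp;
  int icode;            // incidence form
  const double *ip;
  int rcode[4];         // removal forms g1..g4
  double reps[4];
  double a, b, c, k, u, p, q, r, h;
  double e1, e2;        // survival factors exp(-m1 tau1), exp(-m2 tau2)
  double tau[3];
};

inline double growth_val(const Model &m, double x) {
  if (m.gcode == 1) return m.gp[0] - m.gp[1] * x;
  return m.gp[0] - m.gp[1] * x + m.gp[2] * x * (1.0 - x / m.gp[3]);
}

inline double incid_val(const Model &m, double x, double v) {
  const double *p = m.ip;
  switch (m.icode) {
  case 1: return p[0] * x * v;
  case 2: return p[0] * x * v / (1.0 + p[1] * v);
  case 3: return p[0] * x * v / (1.0 + p[1] * x);
  case 4: return p[0] * x * v / (1.0 + p[1] * x + p[2] * v + p[3] * x * v);
  default: return p[0] * x * ((v - p[1]) * std::exp(-p[2] * v) + p[1]);
  }
}

inline double rem_val(const Model &m, int i, double xi) {
  if (m.rcode[i] == 1) return xi;
  return xi * (1.0 + m.reps[i] * xi);
}

struct Solver {
  Model m;
  double h;                 // step
  int nmax;                 // node capacity
  int idx;                  // last completed node
  std::vector<double> Y;    // 5 x (nmax+1) node states
  std::vector<double> F;    // 5 x (nmax+1) node derivatives
  NumericVector hist0;      // constant history
  Function histf;           // general history callback (time -> 5-vector)
  bool const_hist;

  Solver(const Model &mm, double hh, int nn, NumericVector h0, Function hf,
         bool ch)
    : m(mm), h(hh), nmax(nn), idx(0), Y(5 * (nn + 1)), F(5 * (nn + 1)),
      hist0(h0), histf(hf), const_hist(ch) {}

  void history_at(double t, double *out) {
    if (const_hist) {
      for (int i = 0; i < 5; ++i) out[i] = hist0[i];
    } else {
      NumericVector v = histf(t);
      if (v.size() != 5) stop("history function must return a 5-vector");
      for (int i = 0; i < 5; ++i) out[i] = v[i];
    }
  }

  // dense lookup at time tq <= current front (cubic Hermite on completed
  // segments; exact at nodes)
  void lookup(double tq, double *out) {
    if (tq <= 0.0) { history_at(tq, out); return; }
    int j = (int)std::floor(tq / h + 1e-9);
    if (j >= idx) j = idx - 1;
    if (j < 0) j = 0;
    double th = (tq - j * h) / h;
    if (th < 0) th = 0;
    if (th > 1) th = 1;
    double h00 = (1 + 2 * th) * (1 - th) * (1 - th);
    double h10 = th * (1 - th) * (1 - th);
    double h01 = th * th * (3 - 2 * th);
    double h11 = th * th * (th - 1);
    const double *y0 = &Y[5 * j], *y1 = &Y[5 * (j + 1)];
    const double *f0 = &F[5 * j], *f1 = &F[5 * (j + 1)];
    for (int i = 0; i < 5; ++i)
      out[i] = h00 * y0[i] + h01 * y1[i] + h * (h10 * f0[i] + h11 * f1[i]);
  }

  void rhs(double t, const double *y, double *dy) {
    double l1[5], l2[5], l3[5];
    if (m.tau[0] > 0) lookup(t - m.tau[0], l1);
    else for (int i = 0; i < 5; ++i) l1[i] = y[i];
    if (m.tau[1] > 0) lookup(t - m.tau[1], l2);
    else for (int i = 0; i < 5; ++i) l2[i] = y[i];
    if (m.tau[2] > 0) lookup(t - m.tau[2], l3);
    else for (int i = 0; i < 5; ++i) l3[i] = y[i];

    double x = std::max(y[0], 0.0), yy = std::max(y[1], 0.0),
           v = std::max(y[2], 0.0), z = std::max(y[3], 0.0),
           w = std::max(y[4], 0.0);
    double g1y = rem_val(m, 0, yy), g2v = rem_val(m, 1, v),
           g3w = rem_val(m, 2, w), g4z = rem_val(m, 3, z);
    double g1l2 = rem_val(m, 0, std::max(l2[1], 0.0));
    double g1l3 = rem_val(m, 0, std::max(l3[1], 0.0));
    double g4l3 = rem_val(m, 3, std::max(l3[3], 0.0));

    dy[0] = growth_val(m, x) - incid_val(m, x, v);
    dy[1] = m.e1 * incid_val(m, std::max(l1[0], 0.0), std::max(l1[2], 0.0)) -
            m.a * g1y - m.p * g1y * g4z;
    dy[2] = m.k * m.e2 * g1l2 - m.u * g2v - m.q * g2v * g3w;
    dy[3] = m.c * g1l3 * g4l3 - m.b * g4z;
    dy[4] = m.r * g2v * g3w - m.h * g3w;
  }

  // one RK4 advance of length hh from (t, y) into ynew
  void rk4(double t, const double *y, double hh, double *ynew,
           const double *k1) {
    double k2[5], k3[5], k4[5], tmp[5];
    for (int i = 0; i < 5; ++i) tmp[i] = y[i] + 0.5 * hh * k1[i];
    rhs(t + 0.5 * hh, tmp, k2);
    for (int i = 0; i < 5; ++i) tmp[i] = y[i] + 0.5 * hh * k2[i];
    rhs(t + 0.5 * hh, tmp, k3);
    for (int i = 0; i < 5; ++i) tmp[i] = y[i] + hh * k3[i];
    rhs(t + hh, tmp, k4);
    for (int i = 0; i < 5; ++i)
      ynew[i] = y[i] + hh / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
  }

  bool retried;

  // grid-step advance with positivity guard: a step driving a component
  // below -1e-6 is retried as two internal half steps, recursively (fast
  // immune transients can be locally stiff for the nominal step)
  bool advance(double t, const double *y, double hh, double *ynew,
               const double *k1, int depth) {
    rk4(t, y, hh, ynew, k1);
    double mn = ynew[0];
    for (int i = 1; i < 5; ++i) mn = std::min(mn, ynew[i]);
    if (mn >= -1e-6) return true;
    if (depth >= 12) return false;
    retried = true;
    double ymid[5], khalf[5];
    if (!advance(t, y, 0.5 * hh, ymid, k1, depth + 1)) return false;
    for (int i = 0; i < 5; ++i)
      if (ymid[i] < 0 && ymid[i] > -1e-6) ymid[i] = 0.0;
    rhs(t + 0.5 * hh, ymid, khalf);
    return advance(t + 0.5 * hh, ymid, 0.5 * hh, ynew, khalf, depth + 1);
  }
};

} // namespace

// [[Rcpp::export(name = ".dde_rk4_cpp")]]
List dde_rk4_cpp(int gcode, NumericVector gpar, int icode, NumericVector ipar,
                 IntegerVector rcodes, NumericVector reps,
                 NumericVector rates, NumericVector surv, NumericVector taus,
                 NumericVector hist0, Function histf, bool const_hist,
                 double h, int nsteps) {
  Model m;
  m.gcode = gcode; m.gp = gpar.begin();
  m.icode = icode; m.ip = ipar.begin();
  for (int i = 0; i < 4; ++i) { m.rcode[i] = rcodes[i]; m.reps[i] = reps[i]; }
  m.a = rates[0]; m.b = rates[1]; m.c = rates[2]; m.k = rates[3];
  m.u = rates[4]; m.p = rates[5]; m.q = rates[6]; m.r = rates[7];
  m.h = rates[8];
  m.e1 = surv[0]; m.e2 = surv[1];
  for (int i = 0; i < 3; ++i) m.tau[i] = taus[i];

  Solver sol(m, h, nsteps, hist0, histf, const_hist);

  double y0[5];
  sol.history_at(0.0, y0);
  for (int i = 0; i < 5; ++i) sol.Y[i] = y0[i];
  double f0[5];
  sol.rhs(0.0, y0, f0);
  for (int i = 0; i < 5; ++i) sol.F[i] = f0[i];

  sol.retried = false;
  for (int nstep = 0; nstep < nsteps; ++nstep) {
    double t = nstep * h;
    const double *y = &sol.Y[5 * nstep];
    const double *k1 = &sol.F[5 * nstep];
    double ynew[5];
    if (!sol.advance(t, y, h, ynew, k1, 0))
      stop("positivity violation beyond -1e-6 persists at t = %g", t + h);
    for (int i = 0; i < 5; ++i) {
      if (!std::isfinite(ynew[i]))
        stop("state became non-finite at t = %g", t + h);
      if (ynew[i] < 0 && ynew[i] > -1e-6) ynew[i] = 0.0;
    }
    sol.idx = nstep + 1;
    double *dst = &sol.Y[5 * (nstep + 1)];
    for (int i = 0; i < 5; ++i) dst[i] = ynew[i];
    double fn[5];
    sol.rhs((nstep + 1) * h, ynew, fn);
    double *fd = &sol.F[5 * (nstep + 1)];
    for (int i = 0; i < 5; ++i) fd[i] = fn[i];
  }

  NumericMatrix Y(5, nsteps + 1), F(5, nsteps + 1);
  std::copy(sol.Y.begin(), sol.Y.end(), Y.begin());
  std::copy(sol.F.begin(), sol.F.end(), F.begin());
  return List::create(_["states"] = Y, _["derivs"] = F,
                      _["positivity_retry"] = sol.retried);
}
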
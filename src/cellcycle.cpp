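// Six-variable cell-cycle model and an adaptive Dormand-Prince 5(4)
// integrator.  State order: p21, Cd, E2Fa, Ce, Ca, Cb.
// Core parameter order (17):
//   Vsp Vsd Vse Vsa Vsb kx kdd kdd1 kde kda kdb kpi kpii kpiii IEn E2Ft GF

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void cc_rhs_core(const double* s, const double* p,
                               double dnoco, double dpalbo, double gf_scale,
                               double* d) {
  const double p21 = s[0], Cd = s[1], E2Fa = s[2],
               Ce = s[3], Ca = s[4], Cb = s[5];
  const double Vsp = p[0], Vsd = p[1], Vse = p[2], Vsa = p[3], Vsb = p[4],
               kx = p[5], kdd = p[6], kdd1 = p[7], kde = p[8], kda = p[9],
               kdb = p[10], kpi = p[11], kpii = p[12], kpiii = p[13],
               IEn = p[14], E2Ft = p[15], GF = p[16] * gf_scale;
  const double act = kpii / (kpii + p21); // CDK activity not blocked by p21

  d[0] = Vsp * E2Fa
       - Vsp * p21 * (Cb / (kx + Cb)) * (1.0 / (1.0 + IEn * dnoco));
  d[1] = Vsd * GF * E2Fa - Vsd * (Cd / (Cd + kdd));
  d[2] = (E2Ft - E2Fa) * (kpiii / (kpiii + Cb))
         * ((Cd / (Cd + kdd1)) * dpalbo + Ce * (kpi / (kpi + p21)))
       - E2Fa * Ca * act;
  d[3] = Vse * E2Fa - Vse * (Ce / (Ce + kde)) * Ca * act;
  d[4] = Vsa * E2Fa - Vsa * (Ca / (Ca + kda));
  d[5] = Vsb * Ca * act - Vsb * (Cb / (Cb + kdb));
}

// [[Rcpp::export(name = ".cc_rhs_cpp")]]
NumericVector cc_rhs_cpp(NumericVector state, NumericVector pars,
                         double dnoco, double dpalbo, double gf_scale) {
  NumericVector d(6);
  cc_rhs_core(REAL(state), REAL(pars), dnoco, dpalbo, gf_scale, REAL(d));
  return d;
}

// Dormand-Prince RK5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                    c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100,
                    e7 = -1.0 / 40;

struct StepWork {
  double k1[6], k2[6], k3[6], k4[6], k5[6], k6[6], k7[6], tmp[6], y5[6];
};

// One DP step from y over h; returns scaled error estimate (max-norm / tol)
static double dp_step(const double* y, double h, const double* p,
                      double dnoco, double dpalbo, double gf,
                      double rtol, double atol, StepWork& w,
                      bool have_k1) {
  int i;
  if (!have_k1) cc_rhs_core(y, p, dnoco, dpalbo, gf, w.k1);
  for (i = 0; i < 6; ++i) w.tmp[i] = y[i] + h * a21 * w.k1[i];
  cc_rhs_core(w.tmp, p, dnoco, dpalbo, gf, w.k2);
  for (i = 0; i < 6; ++i)
    w.tmp[i] = y[i] + h * (a31 * w.k1[i] + a32 * w.k2[i]);
  cc_rhs_core(w.tmp, p, dnoco, dpalbo, gf, w.k3);
  for (i = 0; i < 6; ++i)
    w.tmp[i] = y[i] + h * (a41 * w.k1[i] + a42 * w.k2[i] + a43 * w.k3[i]);
  cc_rhs_core(w.tmp, p, dnoco, dpalbo, gf, w.k4);
  for (i = 0; i < 6; ++i)
    w.tmp[i] = y[i] + h * (a51 * w.k1[i] + a52 * w.k2[i] + a53 * w.k3[i]
                           + a54 * w.k4[i]);
  cc_rhs_core(w.tmp, p, dnoco, dpalbo, gf, w.k5);
  for (i = 0; i < 6; ++i)
    w.tmp[i] = y[i] + h * (a61 * w.k1[i] + a62 * w.k2[i] + a63 * w.k3[i]
                           + a64 * w.k4[i] + a65 * w.k5[i]);
  cc_rhs_core(w.tmp, p, dnoco, dpalbo, gf, w.k6);
  for (i = 0; i < 6; ++i)
    w.y5[i] = y[i] + h * (b1 * w.k1[i] + b3 * w.k3[i] + b4 * w.k4[i]
                          + b5 * w.k5[i] + b6 * w.k6[i]);
  cc_rhs_core(w.y5, p, dnoco, dpalbo, gf, w.k7);
  double err = 0.0;
  for (i = 0; i < 6; ++i) {
    double ei = h * (e1 * w.k1[i] + e3 * w.k3[i] + e4 * w.k4[i]
                     + e5 * w.k5[i] + e6 * w.k6[i] + e7 * w.k7[i]);
    double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(w.y5[i]));
    double r = std::fabs(ei) / sc;
    if (r > err) err = r;
  }
  return err;
}

// Integrate from times[0] to times[n-1], landing exactly on every output
// time.  Returns an (n x 6) matrix; stops with an R error on failure.
// [[Rcpp::export(name = ".cc_integrate_cpp")]]
NumericMatrix cc_integrate_cpp(NumericVector init, NumericVector pars,
                               NumericVector times, double dnoco,
                               double dpalbo, double gf_scale,
                               double rtol, double atol,
                               double max_steps) {
  const int nt = times.size();
  NumericMatrix out(nt, 6);
  double y[6];
  for (int i = 0; i < 6; ++i) y[i] = init[i];
  for (int i = 0; i < 6; ++i) out(0, i) = y[i];
  const double* p = REAL(pars);
  StepWork w;
  double t = times[0];
  double h = 1e-2;
  long steps = 0;
  cc_rhs_core(y, p, dnoco, dpalbo, gf_scale, w.k1);
  for (int k = 1; k < nt; ++k) {
    const double tend = times[k];
    if (!(tend > t))
      stop("output times must be strictly increasing");
    while (t < tend) {
      if (++steps > (long)max_steps)
        stop("integration exceeded max_steps (%g): likely stiff or "
             "diverging trajectory", max_steps);
      bool hit = false;
      double hs = h;
      if (t + hs >= tend) { hs = tend - t; hit = true; }
      double err = dp_step(y, hs, p, dnoco, dpalbo, gf_scale, rtol, atol,
                           w, true);
      if (!std::isfinite(err))
        stop("non-finite state during integration at t = %g", t);
      if (err <= 1.0) {
        t += hs;
        for (int i = 0; i < 6; ++i) {
          y[i] = w.y5[i];
          // guard against materially negative states
          if (y[i] < -10.0 * atol - 1e-12)
            stop("state %d became negative (%g) at t = %g", i + 1, y[i], t);
          if (y[i] < 0) y[i] = 0.0;
          w.k1[i] = w.k7[i]; // FSAL
        }
        double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
        if (fac > 5.0) fac = 5.0;
        if (fac < 0.2) fac = 0.2;
        if (!hit) h = hs * fac; // keep the natural step when truncated
      } else {
        double fac = std::max(0.2, 0.9 * std::pow(err, -0.2));
        h = hs * fac;
        if (h < 1e-12)
          stop("step size underflow at t = %g", t);
      }
    }
    for (int i = 0; i < 6; ++i) out(k, i) = y[i];
    // FSAL slope may be stale after clipping at an output point; refresh
    cc_rhs_core(y, p, dnoco, dpalbo, gf_scale, w.k1);
  }
  return out;
}

// Endpoint-only integration for many initial conditions (arrested
// snapshots): inits is (n x 6); returns (n x 6) states at t_end.
// [[Rcpp::export(name = ".cc_endpoints_cpp")]]
NumericMatrix cc_endpoints_cpp(NumericMatrix inits, NumericVector pars,
                               double t_end, double dnoco, double dpalbo,
                               double gf_scale, double rtol, double atol,
                               double max_steps) {
  const int n = inits.nrow();
  NumericMatrix out(n, 6);
  NumericVector tv = NumericVector::create(0.0, t_end);
  for (int j = 0; j < n; ++j) {
    NumericVector y0(6);
    for (int i = 0; i < 6; ++i) y0[i] = inits(j, i);
    NumericMatrix tr = cc_integrate_cpp(y0, pars, tv, dnoco, dpalbo,
                                        gf_scale, rtol, atol, max_steps);
    for (int i = 0; i < 6; ++i) out(j, i) = tr(1, i);
  }
  return out;
}
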
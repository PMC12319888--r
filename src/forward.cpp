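// Two-compartment exchange forward models for PGSE diffusion MRI.
//
// State M = (M_i, M_e) evolves under dM/dt = (R - k(t)^2 D) M with
//   R = [[-k_ie, k_ei], [k_ie, -k_ei]],  k_ie = (1-f)/t_ex, k_ei = f/t_ex
//   D = diag(D_i u^2, D_e),  u = g.n the orientation cosine.
// NEXI uses the narrow-pulse solution expm((R - q^2 D) t_d) M(0);
// SMEX integrates through the rectangular gradient pulses, using the
// analytic matrix-exponential propagator on the constant plateau [delta,
// Delta] and an adaptive Dormand-Prince RK45 on the two pulse ramps.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// closed-form exp(A) for a real 2x2 matrix with real eigenvalues
// (guaranteed here: off-diagonal entries are non-negative).
static inline void expm2(const double A[4], double out[4]) {
  const double a = A[0], b = A[1], c = A[2], d = A[3];
  const double tr = a + d;
  const double disc2 = (a - d) * (a - d) + 4.0 * b * c;
  const double disc = std::sqrt(disc2 > 0.0 ? disc2 : 0.0);
  const double l1 = 0.5 * (tr + disc), l2 = 0.5 * (tr - disc);
  const double scale = std::fabs(l1) + std::fabs(l2);
  if (disc > 1e-12 * (scale > 0.0 ? scale : 1.0)) {
    // exp(A) = (e^{l1}(A - l2 I) - e^{l2}(A - l1 I)) / (l1 - l2)
    const double e1 = std::exp(l1), e2 = std::exp(l2), inv = 1.0 / (l1 - l2);
    out[0] = (e1 * (a - l2) - e2 * (a - l1)) * inv;
    out[1] = (e1 - e2) * b * inv;
    out[2] = (e1 - e2) * c * inv;
    out[3] = (e1 * (d - l2) - e2 * (d - l1)) * inv;
  } else {
    // degenerate eigenvalues: exp(A) = e^l (I + (A - l I))
    const double l = 0.5 * tr, e = std::exp(l);
    out[0] = e * (1.0 + (a - l));
    out[1] = e * b;
    out[2] = e * c;
    out[3] = e * (1.0 + (d - l));
  }
}

// [[Rcpp::export]]
NumericMatrix expm2_cpp(NumericMatrix A) {
  if (A.nrow() != 2 || A.ncol() != 2) stop("expm2_cpp expects a 2x2 matrix");
  double Ain[4] = {A(0, 0), A(0, 1), A(1, 0), A(1, 1)};
  double out[4];
  expm2(Ain, out);
  NumericMatrix res(2, 2);
  res(0, 0) = out[0]; res(0, 1) = out[1]; res(1, 0) = out[2]; res(1, 1) = out[3];
  return res;
}

// Karger kernel along one orientation: 1^T expm((R - q^2 D) t_d) M0.
// c0 = 1^T A M0 = -q^2 (f D_i u^2 + (1-f) D_e) since columns of R sum to 0.
static inline double nexi_kernel_1(double u2, double tex, double Di,
                                   double De, double f, double q2,
                                   double td) {
  const double kie = (1.0 - f) / tex, kei = f / tex;
  const double a = -kie - q2 * Di * u2;
  const double d = -kei - q2 * De;
  const double tr = a + d;
  const double disc2 = (a - d) * (a - d) + 4.0 * kei * kie;
  const double disc = std::sqrt(disc2 > 0.0 ? disc2 : 0.0);
  const double l1 = 0.5 * (tr + disc), l2 = 0.5 * (tr - disc);
  const double c0 = -q2 * (f * Di * u2 + (1.0 - f) * De);
  const double scale = std::fabs(l1) + std::fabs(l2);
  if (disc > 1e-12 * (scale > 0.0 ? scale : 1.0)) {
    return (std::exp(l1 * td) * (c0 - l2) - std::exp(l2 * td) * (c0 - l1)) /
           (l1 - l2);
  }
  const double l = 0.5 * tr;
  return std::exp(l * td) * (1.0 + (c0 - l) * td);
}

// [[Rcpp::export]]
NumericVector nexi_kernel_cpp(NumericVector u, double tex, double Di,
                              double De, double f, double q, double td) {
  const double q2 = q * q;
  NumericVector out(u.size());
  for (R_xlen_t i = 0; i < u.size(); ++i)
    out[i] = nexi_kernel_1(u[i] * u[i], tex, Di, De, f, q2, td);
  return out;
}

// Powder-averaged NEXI signals: rows = parameter sets [t_ex, D_i, D_e, f],
// columns = shells.  u, w: Gauss-Legendre nodes/weights on [0, 1].
// [[Rcpp::export]]
NumericMatrix nexi_curves_cpp(NumericMatrix params, NumericVector b,
                              NumericVector td, NumericVector u,
                              NumericVector w) {
  const int np = params.nrow(), ns = b.size(), nu = u.size();
  NumericMatrix out(np, ns);
  std::vector<double> u2(nu);
  for (int k = 0; k < nu; ++k) u2[k] = u[k] * u[k];
  for (int i = 0; i < np; ++i) {
    const double tex = params(i, 0), Di = params(i, 1), De = params(i, 2),
                 f = params(i, 3);
    for (int s = 0; s < ns; ++s) {
      if (b[s] == 0.0) { out(i, s) = 1.0; continue; }
      const double q2 = b[s] / td[s];
      double acc = 0.0;
      for (int k = 0; k < nu; ++k)
        acc += w[k] * nexi_kernel_1(u2[k], tex, Di, De, f, q2, td[s]);
      out(i, s) = acc;
    }
  }
  return out;
}

// ---- SMEX: adaptive RK45 through the gradient ramps ----------------------

struct PulseODE {
  // dM/dt = (R - w(s)^2 * diag(a1, a2)) M, with w the normalized gradient
  // amplitude profile on the segment (rise: s/delta, fall: 1 - s/delta).
  double kie, kei, a1, a2, delta;
  bool fall;
  inline void rhs(double s, const double m[2], double dm[2]) const {
    double wamp = fall ? (1.0 - s / delta) : (s / delta);
    if (wamp < 0.0) wamp = 0.0;
    if (wamp > 1.0) wamp = 1.0;
    const double w2 = wamp * wamp;
    dm[0] = -(kie + w2 * a1) * m[0] + kei * m[1];
    dm[1] = kie * m[0] - (kei + w2 * a2) * m[1];
  }
};

// Dormand-Prince 5(4) with FSAL, integrating m over [0, len].
// Returns false on step-size underflow.
static bool dp45(const PulseODE& ode, double len, double m[2], double rtol,
                 double atol) {
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
                      e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;

  double s = 0.0, h = len / 20.0;
  const double hmin = len * 1e-13;
  double k1[2], k2[2], k3[2], k4[2], k5[2], k6[2], k7[2], y[2], ynew[2];
  ode.rhs(0.0, m, k1);
  int iter = 0;
  while (s < len) {
    if (++iter > 100000) return false;
    if (s + h > len) h = len - s;
    y[0] = m[0] + h * a21 * k1[0];
    y[1] = m[1] + h * a21 * k1[1];
    ode.rhs(s + c2 * h, y, k2);
    y[0] = m[0] + h * (a31 * k1[0] + a32 * k2[0]);
    y[1] = m[1] + h * (a31 * k1[1] + a32 * k2[1]);
    ode.rhs(s + c3 * h, y, k3);
    y[0] = m[0] + h * (a41 * k1[0] + a42 * k2[0] + a43 * k3[0]);
    y[1] = m[1] + h * (a41 * k1[1] + a42 * k2[1] + a43 * k3[1]);
    ode.rhs(s + c4 * h, y, k4);
    y[0] = m[0] + h * (a51 * k1[0] + a52 * k2[0] + a53 * k3[0] + a54 * k4[0]);
    y[1] = m[1] + h * (a51 * k1[1] + a52 * k2[1] + a53 * k3[1] + a54 * k4[1]);
    ode.rhs(s + c5 * h, y, k5);
    y[0] = m[0] + h * (a61 * k1[0] + a62 * k2[0] + a63 * k3[0] + a64 * k4[0] +
                       a65 * k5[0]);
    y[1] = m[1] + h * (a61 * k1[1] + a62 * k2[1] + a63 * k3[1] + a64 * k4[1] +
                       a65 * k5[1]);
    ode.rhs(s + h, y, k6);
    ynew[0] = m[0] + h * (b1 * k1[0] + b3 * k3[0] + b4 * k4[0] + b5 * k5[0] +
                          b6 * k6[0]);
    ynew[1] = m[1] + h * (b1 * k1[1] + b3 * k3[1] + b4 * k4[1] + b5 * k5[1] +
                          b6 * k6[1]);
    ode.rhs(s + h, ynew, k7);
    double errn = 0.0;
    for (int j = 0; j < 2; ++j) {
      const double e = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] +
                            e5 * k5[j] + e6 * k6[j] + e7 * k7[j]);
      const double sc = atol + rtol * std::max(std::fabs(m[j]), std::fabs(ynew[j]));
      const double r = e / sc;
      errn += r * r;
    }
    errn = std::sqrt(0.5 * errn);
    if (errn <= 1.0) {
      s += h;
      m[0] = ynew[0];
      m[1] = ynew[1];
      k1[0] = k7[0];  // FSAL
      k1[1] = k7[1];
    }
    double fac = 0.9 * std::pow(errn > 1e-12 ? errn : 1e-12, -0.2);
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
    if (h < hmin) return false;
  }
  return true;
}

// Powder-averaged SMEX signal for one parameter set and shell list.
// The plateau segment [delta, Delta] uses the analytic propagator
// expm((Delta - delta)(R - q^2 D)); both ramps are integrated explicitly.
// [[Rcpp::export]]
NumericMatrix smex_curves_cpp(NumericMatrix params, NumericVector b,
                              NumericVector Delta, NumericVector delta,
                              NumericVector u, NumericVector w,
                              double rtol = 1e-8, double atol = 1e-10) {
  const int np = params.nrow(), ns = b.size(), nu = u.size();
  NumericMatrix out(np, ns);
  std::vector<double> u2(nu);
  for (int k = 0; k < nu; ++k) u2[k] = u[k] * u[k];
  for (int i = 0; i < np; ++i) {
    const double tex = params(i, 0), Di = params(i, 1), De = params(i, 2),
                 f = params(i, 3);
    const double kie = (1.0 - f) / tex, kei = f / tex;
    for (int s = 0; s < ns; ++s) {
      if (b[s] == 0.0) { out(i, s) = 1.0; continue; }
      const double td = Delta[s] - delta[s] / 3.0;
      const double q2 = b[s] / td;
      const double plateau = Delta[s] - delta[s];
      double acc = 0.0;
      for (int k = 0; k < nu; ++k) {
        const double a1 = q2 * Di * u2[k], a2 = q2 * De;
        double m[2] = {f, 1.0 - f};
        PulseODE rise = {kie, kei, a1, a2, delta[s], false};
        if (!dp45(rise, delta[s], m, rtol, atol))
          stop("SMEX ODE integration failed (rise ramp) at shell %d", s + 1);
        if (plateau > 0.0) {
          const double A[4] = {plateau * (-kie - a1), plateau * kei,
                               plateau * kie, plateau * (-kei - a2)};
          double P[4];
          expm2(A, P);
          const double m0 = P[0] * m[0] + P[1] * m[1];
          const double m1 = P[2] * m[0] + P[3] * m[1];
          m[0] = m0;
          m[1] = m1;
        }
        PulseODE fall = {kie, kei, a1, a2, delta[s], true};
        if (!dp45(fall, delta[s], m, rtol, atol))
          stop("SMEX ODE integration failed (fall ramp) at shell %d", s + 1);
        acc += w[k] * (m[0] + m[1]);
      }
      out(i, s) = acc;
    }
  }
  return out;
}
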
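#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Space-free forced kinetics:
//   du/dt = a + A sin(2 pi t / T) - u - 4 u v / (1 + u^2)
//   dv/dt = sigma b (u - u v / (1 + u^2))
static inline void rhs(double u, double v, double F, double sb,
                       double &du, double &dv) {
  double w = u * v / (1.0 + u * u);
  du = F - u - 4.0 * w;
  dv = sb * (u - w);
}

// Explicit-Euler integration of the forced space-free system, period by
// period, until the sampled period repeats in max norm.  Returns the last
// period's N+1 samples (left endpoints plus final point) and the residual
// history.
// [[Rcpp::export]]
List cpp_euler_orbit(double a, double b, double sigma, double c,
                     double A, double T, int N,
                     double u0, double v0,
                     double tol, int max_periods) {
  const double dt = T / N;
  const double sb = sigma * b;
  const double om = 2.0 * M_PI / T;
  NumericVector up(N + 1), vp(N + 1), up_prev(N + 1), vp_prev(N + 1);
  std::vector<double> res_hist;
  double u = u0, v = v0;
  bool converged = false;
  double residual = R_PosInf;
  int period = 0;
  for (period = 1; period <= max_periods; ++period) {
    for (int i = 0; i < N; ++i) {
      up[i] = u; vp[i] = v;
      double F = a + A * std::sin(om * (i * dt));
      double du, dv;
      rhs(u, v, F, sb, du, dv);
      u += dt * du;
      v += dt * dv;
      if (!std::isfinite(u) || !std::isfinite(v))
        stop("orbit integration diverged in period %d", period);
    }
    up[N] = u; vp[N] = v;
    if (period > 1) {
      residual = 0.0;
      for (int i = 0; i <= N; ++i) {
        residual = std::max(residual, std::fabs(up[i] - up_prev[i]));
        residual = std::max(residual, std::fabs(vp[i] - vp_prev[i]));
      }
      res_hist.push_back(residual);
      if (residual < tol) { converged = true; break; }
    }
    up_prev = clone(up);
    vp_prev = clone(vp);
  }
  return List::create(_["u_p"] = up, _["v_p"] = vp,
                      _["residual"] = residual,
                      _["periods"] = std::min(period, max_periods),
                      _["converged"] = converged,
                      _["residual_history"] = wrap(res_hist));
}

// Entries of L(t; k) given the orbit point (u, v); k enters only through
// the diagonal diffusion terms.
static inline void Lmat(double u, double v, double b, double sigma, double c,
                        double k2, double &l11, double &l12,
                        double &l21, double &l22) {
  double s = 1.0 + u * u;
  double q = v * (u * u - 1.0) / (s * s);
  l11 = -1.0 + 4.0 * q - k2;
  l12 = -4.0 * u / s;
  l21 = sigma * b * (1.0 + q);
  l22 = -sigma * (b * u / s + c * k2);
}

// Ordered Euler product P(k) = (I + dt L(t_{N-1})) ... (I + dt L(t_0)) for a
// single wavenumber; orbit samples are the left endpoints u_p[0..N-1].
// [[Rcpp::export]]
NumericMatrix cpp_poincare_map(NumericVector u_p, NumericVector v_p,
                               double b, double sigma, double c,
                               double k, double dt) {
  int N = u_p.size() - 1;
  double k2 = k * k;
  double p11 = 1, p12 = 0, p21 = 0, p22 = 1;
  for (int i = 0; i < N; ++i) {
    double l11, l12, l21, l22;
    Lmat(u_p[i], v_p[i], b, sigma, c, k2, l11, l12, l21, l22);
    double f11 = 1.0 + dt * l11, f12 = dt * l12;
    double f21 = dt * l21, f22 = 1.0 + dt * l22;
    double n11 = f11 * p11 + f12 * p21;
    double n12 = f11 * p12 + f12 * p22;
    double n21 = f21 * p11 + f22 * p21;
    double n22 = f21 * p12 + f22 * p22;
    p11 = n11; p12 = n12; p21 = n21; p22 = n22;
  }
  NumericMatrix P(2, 2);
  P(0, 0) = p11; P(0, 1) = p12; P(1, 0) = p21; P(1, 1) = p22;
  return P;
}

// Floquet multiplier moduli over a wavenumber grid: for each k the ordered
// product is accumulated and the eigenvalue moduli of the 2x2 map are taken
// from its trace and determinant (complex pairs via sqrt(det)).
// Returns a matrix with columns |lambda_1| >= |lambda_2|, det P, trace P.
// [[Rcpp::export]]
NumericMatrix cpp_stability_moduli(NumericVector u_p, NumericVector v_p,
                                   double b, double sigma, double c,
                                   NumericVector k_grid, double dt) {
  int N = u_p.size() - 1;
  int nk = k_grid.size();
  std::vector<double> p11(nk, 1.0), p12(nk, 0.0), p21(nk, 0.0), p22(nk, 1.0);
  std::vector<double> k2(nk);
  for (int j = 0; j < nk; ++j) k2[j] = k_grid[j] * k_grid[j];
  for (int i = 0; i < N; ++i) {
    double u = u_p[i], v = v_p[i];
    double s = 1.0 + u * u;
    double q = v * (u * u - 1.0) / (s * s);
    double b11 = -1.0 + 4.0 * q;           // minus k^2 still to come
    double b12 = -4.0 * u / s;
    double b21 = sigma * b * (1.0 + q);
    double b22 = -sigma * b * u / s;       // minus sigma c k^2 still to come
    for (int j = 0; j < nk; ++j) {
      double f11 = 1.0 + dt * (b11 - k2[j]);
      double f12 = dt * b12;
      double f21 = dt * b21;
      double f22 = 1.0 + dt * (b22 - sigma * c * k2[j]);
      double n11 = f11 * p11[j] + f12 * p21[j];
      double n12 = f11 * p12[j] + f12 * p22[j];
      double n21 = f21 * p11[j] + f22 * p21[j];
      double n22 = f21 * p12[j] + f22 * p22[j];
      p11[j] = n11; p12[j] = n12; p21[j] = n21; p22[j] = n22;
    }
  }
  NumericMatrix out(nk, 4);
  for (int j = 0; j < nk; ++j) {
    double tr = p11[j] + p22[j];
    double det = p11[j] * p22[j] - p12[j] * p21[j];
    double disc = tr * tr - 4.0 * det;
    double m1, m2;
    if (disc < 0.0) {
      m1 = m2 = std::sqrt(det);  // complex pair: |lambda|^2 = det
    } else {
      double sq = std::sqrt(disc);
      m1 = std::fabs((tr + sq) / 2.0);
      m2 = std::fabs((tr - sq) / 2.0);
      if (m2 > m1) std::swap(m1, m2);
    }
    out(j, 0) = m1; out(j, 1) = m2; out(j, 2) = det; out(j, 3) = tr;
  }
  colnames(out) = CharacterVector::create("lambda1_abs", "lambda2_abs",
                                          "det", "trace");
  return out;
}
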
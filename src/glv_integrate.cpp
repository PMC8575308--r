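// Adaptive Dormand-Prince 5(4) integration of the dispersal-coupled GLV
// equations on a periodic lattice.  State is an M x N matrix (grid-points x
// species).  The local term at every grid-point is
//   phi_i r_i (1 - phi_i / K_i) + sigma phi_i sum_j A_ij phi_j
// and the coupling term is D_i * discrete periodic Laplacian of species i's
// field divided by h^2 (three-point stencil on a ring, five-point on a torus).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

namespace {

struct Lattice {
  int ndim;
  arma::uvec nb_up, nb_dn, nb_lt, nb_rt; // periodic neighbour indices
  int M;
};

Lattice make_lattice(int ndim, const IntegerVector &extent) {
  Lattice g;
  g.ndim = ndim;
  if (ndim == 1) {
    int L = extent[0];
    g.M = L;
    g.nb_up.set_size(L);
    g.nb_dn.set_size(L);
    for (int i = 0; i < L; ++i) {
      g.nb_up[i] = (i + 1) % L;
      g.nb_dn[i] = (i - 1 + L) % L;
    }
  } else {
    int Lx = extent[0], Ly = extent[1];
    g.M = Lx * Ly;
    g.nb_up.set_size(g.M);
    g.nb_dn.set_size(g.M);
    g.nb_lt.set_size(g.M);
    g.nb_rt.set_size(g.M);
    for (int b = 0; b < Ly; ++b) {
      for (int a = 0; a < Lx; ++a) {
        int idx = a + Lx * b;
        g.nb_up[idx] = ((a + 1) % Lx) + Lx * b;
        g.nb_dn[idx] = ((a - 1 + Lx) % Lx) + Lx * b;
        g.nb_rt[idx] = a + Lx * ((b + 1) % Ly);
        g.nb_lt[idx] = a + Lx * ((b - 1 + Ly) % Ly);
      }
    }
  }
  return g;
}

// dP/dt for the full lattice system
arma::mat rhs(const arma::mat &P, const arma::mat &At, const arma::rowvec &r,
              const arma::rowvec &K, double sigma, const arma::rowvec &D,
              const Lattice &g, double inv_h2, bool coupled) {
  arma::mat interact = P * At; // (M x N): row g holds sum_j A_ij phi_{g,j}
  arma::mat out = P % (arma::ones<arma::colvec>(P.n_rows) * r) %
                      (1.0 - P.each_row() / K) +
                  sigma * (P % interact);
  if (coupled) {
    arma::mat lap = P.rows(g.nb_up) + P.rows(g.nb_dn) - 2.0 * g.ndim * P;
    if (g.ndim == 2) lap += P.rows(g.nb_lt) + P.rows(g.nb_rt);
    out += (lap.each_row() % D) * inv_h2;
  }
  return out;
}

} // namespace

// [[Rcpp::export(name = ".glv_integrate_cpp")]]
List glv_integrate_cpp(const arma::mat &phi0, const arma::mat &A,
                       const arma::vec &r, const arma::vec &K, double sigma,
                       const arma::vec &D, int ndim, IntegerVector extent,
                       double h, double t_end, double dt_out, double rtol,
                       double atol, double max_step, int max_steps) {
  const Lattice g = make_lattice(ndim, extent);
  const int M = g.M;
  const int N = A.n_rows;
  if ((int)phi0.n_rows != M || (int)phi0.n_cols != N)
    stop("phi0 has shape %d x %d, expected %d x %d", phi0.n_rows, phi0.n_cols,
         M, N);

  const arma::mat At = A.t();
  const arma::rowvec rr = r.t(), KK = K.t(), DD = D.t();
  const double inv_h2 = 1.0 / (h * h);
  const bool coupled = (M > 1) && arma::any(D != 0.0);

  // Dormand-Prince 5(4) tableau
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
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
  // embedded 4th-order weights
  static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                      e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                      e6 = 187.0 / 2100, e7 = 1.0 / 40;

  const int n_out = (int)std::floor(t_end / dt_out + 0.5) + 1;
  NumericVector out(((R_xlen_t)n_out) * M * N);
  NumericVector times(n_out);
  for (int k = 0; k < n_out; ++k) times[k] = k * dt_out;

  arma::mat y = phi0;
  double t = 0.0;
  int k_out = 0;
  bool diverged = false;
  long n_accept = 0, n_reject = 0;

  auto record = [&](const arma::mat &state, int k) {
    for (int s = 0; s < N; ++s)
      for (int gp = 0; gp < M; ++gp)
        out[k + (R_xlen_t)n_out * (gp + (R_xlen_t)M * s)] =
            std::max(state(gp, s), 0.0);
  };
  record(y, k_out++); // t = 0

  arma::mat f1 = rhs(y, At, rr, KK, sigma, DD, g, inv_h2, coupled);
  double dt = std::min(0.01, dt_out);
  if (max_step > 0) dt = std::min(dt, max_step);

  int steps = 0;
  while (k_out < n_out && steps < max_steps) {
    ++steps;
    double t_next = times[k_out];
    bool hit_out = false;
    double dt_try = dt;
    if (t + dt_try >= t_next - 1e-12) {
      dt_try = t_next - t;
      hit_out = true;
    }

    arma::mat k2 = rhs(y + dt_try * a21 * f1, At, rr, KK, sigma, DD, g, inv_h2,
                       coupled);
    arma::mat k3 = rhs(y + dt_try * (a31 * f1 + a32 * k2), At, rr, KK, sigma,
                       DD, g, inv_h2, coupled);
    arma::mat k4 = rhs(y + dt_try * (a41 * f1 + a42 * k2 + a43 * k3), At, rr,
                       KK, sigma, DD, g, inv_h2, coupled);
    arma::mat k5 = rhs(y + dt_try * (a51 * f1 + a52 * k2 + a53 * k3 + a54 * k4),
                       At, rr, KK, sigma, DD, g, inv_h2, coupled);
    arma::mat k6 =
        rhs(y + dt_try * (a61 * f1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5),
            At, rr, KK, sigma, DD, g, inv_h2, coupled);
    arma::mat y5 =
        y + dt_try * (b1 * f1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
    arma::mat k7 = rhs(y5, At, rr, KK, sigma, DD, g, inv_h2, coupled);
    arma::mat y4 = y + dt_try * (e1 * f1 + e3 * k3 + e4 * k4 + e5 * k5 +
                                 e6 * k6 + e7 * k7);

    if (!y5.is_finite()) {
      diverged = true;
      break;
    }

    arma::mat sc = atol + rtol * arma::max(arma::abs(y), arma::abs(y5));
    double err = (arma::abs(y5 - y4) / sc).eval().max();

    if (err <= 1.0) {
      t += dt_try;
      y = y5;
      // tiny negative undershoots are numerical; clamp them
      y.transform([](double v) { return v < 0.0 && v > -1e-9 ? 0.0 : v; });
      if (y.min() < -1e-9 || arma::abs(y).max() > 1e10) {
        diverged = true;
        break;
      }
      f1 = k7; // FSAL
      ++n_accept;
      if (hit_out) {
        record(y, k_out++);
      }
    } else {
      ++n_reject;
    }

    double fac = err > 0 ? 0.9 * std::pow(err, -0.2) : 5.0;
    fac = std::min(5.0, std::max(0.2, fac));
    dt = dt * fac;
    if (max_step > 0 && dt > max_step) dt = max_step;
    if (dt < 1e-12) {
      diverged = true;
      break;
    }
  }
  if (steps >= max_steps && k_out < n_out) diverged = true;

  out.attr("dim") = IntegerVector::create(n_out, M, N);
  return List::create(_["times"] = times, _["phi"] = out,
                      _["diverged"] = diverged, _["n_recorded"] = k_out,
                      _["n_accept"] = (double)n_accept,
                      _["n_reject"] = (double)n_reject);
}
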
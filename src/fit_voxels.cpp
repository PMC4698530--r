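// Per-voxel least-squares relaxometry from M complex spin-echo images.
//
// The criterion sum_k |y_k - f_k(theta) e^{i phi}|^2 is reduced before any
// numerical search: for fixed (T1, T2) the phase and the proton density
// have closed-form minimisers
//   phi*  = arg( sum_k y_k g_k )
//   rho*  = | sum_k y_k g_k | / sum_k g_k^2      (clamped to [0, rho_max])
// with g_k = exp(-TE_k/T2)(1 - exp(-TR_k/T1)).  What remains is a smooth
// 2D problem in (T1, T2), solved by a coarse log-spaced grid followed by
// Nelder-Mead refinement in box-mapped coordinates.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Problem {
  const std::complex<double>* y; // M observations of one voxel
  const double* te;
  const double* tr;
  int M;
  double sumy2;
  double rho_max;
};

// concentrated criterion at (t1, t2); also reports rho* and S = sum y_k g_k
inline double crit(const Problem& p, double t1, double t2,
                   double& rho_out, std::complex<double>& S_out) {
  double G = 0.0;
  std::complex<double> S(0.0, 0.0);
  for (int k = 0; k < p.M; ++k) {
    double g = std::exp(-p.te[k] / t2) * (1.0 - std::exp(-p.tr[k] / t1));
    G += g * g;
    S += p.y[k] * g;
  }
  double aS = std::abs(S);
  double rho = (G > 0.0) ? aS / G : 0.0;
  if (rho > p.rho_max) rho = p.rho_max;
  rho_out = rho;
  S_out = S;
  return p.sumy2 + rho * rho * G - 2.0 * rho * aS;
}

// logistic box map: u in R  ->  t in (lo, hi)
inline double box(double u, double lo, double hi) {
  return lo + (hi - lo) / (1.0 + std::exp(-u));
}
inline double unbox(double t, double lo, double hi) {
  double z = (t - lo) / (hi - lo);
  z = std::min(std::max(z, 1e-12), 1.0 - 1e-12);
  return std::log(z / (1.0 - z));
}

struct NMResult {
  double u1, u2, f;
  bool converged;
};

// 2D Nelder-Mead on the concentrated criterion in box coordinates
NMResult nelder_mead(const Problem& p, double u1_0, double u2_0,
                     double t1_lo, double t1_hi, double t2_lo, double t2_hi,
                     int max_iter, double tol) {
  double rho_tmp;
  std::complex<double> S_tmp;
  auto f = [&](double u1, double u2) {
    return crit(p, box(u1, t1_lo, t1_hi), box(u2, t2_lo, t2_hi),
                rho_tmp, S_tmp);
  };
  const double step = 0.35;
  double U[3][2] = {{u1_0, u2_0}, {u1_0 + step, u2_0}, {u1_0, u2_0 + step}};
  double F[3];
  for (int i = 0; i < 3; ++i) F[i] = f(U[i][0], U[i][1]);

  bool conv = false;
  for (int it = 0; it < max_iter; ++it) {
    // order: 0 best, 2 worst
    int ord[3] = {0, 1, 2};
    std::sort(ord, ord + 3, [&](int a, int b) { return F[a] < F[b]; });
    double Ub[3][2], Fb[3];
    for (int i = 0; i < 3; ++i) {
      Ub[i][0] = U[ord[i]][0];
      Ub[i][1] = U[ord[i]][1];
      Fb[i] = F[ord[i]];
    }
    std::memcpy(U, Ub, sizeof(U));
    std::memcpy(F, Fb, sizeof(F));

    double diam = 0.0;
    for (int i = 1; i < 3; ++i)
      diam = std::max(diam, std::max(std::fabs(U[i][0] - U[0][0]),
                                     std::fabs(U[i][1] - U[0][1])));
    if (diam < tol) { conv = true; break; }

    double c0 = 0.5 * (U[0][0] + U[1][0]);
    double c1 = 0.5 * (U[0][1] + U[1][1]);
    double xr0 = c0 + (c0 - U[2][0]), xr1 = c1 + (c1 - U[2][1]);
    double fr = f(xr0, xr1);
    if (fr < F[0]) {
      double xe0 = c0 + 2.0 * (c0 - U[2][0]), xe1 = c1 + 2.0 * (c1 - U[2][1]);
      double fe = f(xe0, xe1);
      if (fe < fr) { U[2][0] = xe0; U[2][1] = xe1; F[2] = fe; }
      else { U[2][0] = xr0; U[2][1] = xr1; F[2] = fr; }
    } else if (fr < F[1]) {
      U[2][0] = xr0; U[2][1] = xr1; F[2] = fr;
    } else {
      double xc0 = c0 + 0.5 * (U[2][0] - c0), xc1 = c1 + 0.5 * (U[2][1] - c1);
      double fc = f(xc0, xc1);
      if (fc < F[2]) { U[2][0] = xc0; U[2][1] = xc1; F[2] = fc; }
      else { // shrink toward best
        for (int i = 1; i < 3; ++i) {
          U[i][0] = U[0][0] + 0.5 * (U[i][0] - U[0][0]);
          U[i][1] = U[0][1] + 0.5 * (U[i][1] - U[0][1]);
          F[i] = f(U[i][0], U[i][1]);
        }
      }
    }
  }
  int best = 0;
  for (int i = 1; i < 3; ++i) if (F[i] < F[best]) best = i;
  NMResult r;
  r.u1 = U[best][0]; r.u2 = U[best][1]; r.f = F[best];
  r.converged = conv;
  return r;
}

} // namespace

// [[Rcpp::export]]
List cpp_fit_voxels(const arma::cx_mat& Y, const arma::vec& te,
                    const arma::vec& tr, double rho_max,
                    double t1_min, double t1_max,
                    double t2_min, double t2_max,
                    int n_grid, int n_starts, int max_iter, double tol) {
  const int n = Y.n_rows;
  const int M = Y.n_cols;
  if ((int)te.n_elem != M || (int)tr.n_elem != M)
    stop("protocol length does not match the number of images");

  // precompute g_k on the log-spaced (T1, T2) grid
  arma::vec t1g = arma::exp(arma::linspace(std::log(t1_min * 1.02),
                                           std::log(t1_max * 0.98), n_grid));
  arma::vec t2g = arma::exp(arma::linspace(std::log(t2_min * 1.02),
                                           std::log(t2_max * 0.98), n_grid));
  const int ng = n_grid * n_grid;
  arma::mat gk(ng, M);
  arma::vec Gg(ng);
  for (int i = 0; i < n_grid; ++i)
    for (int j = 0; j < n_grid; ++j) {
      int idx = i * n_grid + j;
      double G = 0.0;
      for (int k = 0; k < M; ++k) {
        double g = std::exp(-te[k] / t2g[j]) *
                   (1.0 - std::exp(-tr[k] / t1g[i]));
        gk(idx, k) = g;
        G += g * g;
      }
      Gg[idx] = G;
    }

  NumericVector rho(n), t1(n), t2(n), phi(n), resid(n);
  LogicalVector converged(n), background(n);
  std::vector<std::complex<double>> yrow(M);
  std::vector<double> fgrid(ng);

  for (int v = 0; v < n; ++v) {
    double sumy2 = 0.0;
    bool allzero = true;
    for (int k = 0; k < M; ++k) {
      yrow[k] = Y(v, k);
      double a2 = std::norm(yrow[k]);
      sumy2 += a2;
      if (a2 > 0.0) allzero = false;
    }
    if (allzero) {
      rho[v] = 0.0; t1[v] = NA_REAL; t2[v] = NA_REAL; phi[v] = 0.0;
      resid[v] = 0.0; converged[v] = true; background[v] = true;
      continue;
    }
    background[v] = false;
    Problem p;
    p.y = yrow.data(); p.te = te.memptr(); p.tr = tr.memptr();
    p.M = M; p.sumy2 = sumy2; p.rho_max = rho_max;

    // grid sweep with concentrated rho and phi
    for (int idx = 0; idx < ng; ++idx) {
      double Sr = 0.0, Si = 0.0;
      for (int k = 0; k < M; ++k) {
        Sr += yrow[k].real() * gk(idx, k);
        Si += yrow[k].imag() * gk(idx, k);
      }
      double aS = std::sqrt(Sr * Sr + Si * Si);
      double r0 = (Gg[idx] > 0.0) ? aS / Gg[idx] : 0.0;
      if (r0 > rho_max) r0 = rho_max;
      fgrid[idx] = sumy2 + r0 * r0 * Gg[idx] - 2.0 * r0 * aS;
    }

    // refine from the n_starts best grid cells
    std::vector<int> order(ng);
    std::iota(order.begin(), order.end(), 0);
    int ns = std::min(n_starts, ng);
    std::partial_sort(order.begin(), order.begin() + ns, order.end(),
                      [&](int a, int b) { return fgrid[a] < fgrid[b]; });
    double best_f = R_PosInf, best_t1 = t1g[0], best_t2 = t2g[0];
    bool best_conv = false;
    for (int s = 0; s < ns; ++s) {
      int idx = order[s];
      double u1 = unbox(t1g[idx / n_grid], t1_min, t1_max);
      double u2 = unbox(t2g[idx % n_grid], t2_min, t2_max);
      NMResult r = nelder_mead(p, u1, u2, t1_min, t1_max, t2_min, t2_max,
                               max_iter, tol);
      if (r.f < best_f) {
        best_f = r.f;
        best_t1 = box(r.u1, t1_min, t1_max);
        best_t2 = box(r.u2, t2_min, t2_max);
        best_conv = r.converged;
      }
    }
    double rho_hat;
    std::complex<double> S;
    double fv = crit(p, best_t1, best_t2, rho_hat, S);
    rho[v] = rho_hat;
    t1[v] = best_t1;
    t2[v] = best_t2;
    phi[v] = std::arg(S);
    resid[v] = std::sqrt(std::max(fv, 0.0));
    converged[v] = best_conv;
  }

  return List::create(_["rho"] = rho, _["t1"] = t1, _["t2"] = t2,
                      _["phi"] = phi, _["residual"] = resid,
                      _["converged"] = converged,
                      _["background"] = background);
}
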
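#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Lower weighted median: smallest value x_k with cumulative weight >= half the
// total. Values with non-positive weight are ignored by the caller.
static double weighted_median(std::vector<double>& x, std::vector<double>& w) {
  const int m = x.size();
  if (m == 0) return NA_REAL;
  if (m == 1) return x[0];
  std::vector<int> idx(m);
  for (int i = 0; i < m; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) { return x[a] < x[b]; });
  double total = 0.0;
  for (int i = 0; i < m; ++i) total += w[i];
  const double half = total / 2.0;
  double cum = 0.0;
  for (int i = 0; i < m; ++i) {
    cum += w[idx[i]];
    if (cum >= half) return x[idx[i]];
  }
  return x[idx[m - 1]];
}

static double median_of_positive(std::vector<double> w) {
  w.erase(std::remove_if(w.begin(), w.end(),
                         [](double x) { return x <= 0.0; }),
          w.end());
  if (w.empty()) return 0.0;
  std::sort(w.begin(), w.end());
  const size_t m = w.size();
  return m % 2 ? w[m / 2] : 0.5 * (w[m / 2 - 1] + w[m / 2]);
}

// One rank-one component of the robust SVD: alternating least-absolute-
// deviation regression of the residual matrix on v (for u) and on u (for v),
// each solved exactly by a weighted median over the observed cells.
//
// Identifiability guard: a coordinate is estimable only from the observed
// cells it shares with the current regressor. When the total regression
// weight available to a coordinate is negligible next to the typical
// coordinate's (below 5% of the median total weight), its ratio estimates
// are pure noise amplification — division by near-zero regressor entries —
// and the coordinate is set to 0 instead.
//
// res: p x n residual matrix; obs: logical matrix, true = cell participates;
// v0: starting right vector (need not be normalised).
// [[Rcpp::export(name = ".l1_component")]]
List l1_component(NumericMatrix res, LogicalMatrix obs, NumericVector v0,
                  double tol, int max_iter) {
  const int p = res.nrow(), n = res.ncol();
  std::vector<double> u(p, 0.0), v(n), u_old(p), v_old(n);
  std::vector<double> vals, wts, totw;
  vals.reserve(std::max(p, n));
  wts.reserve(std::max(p, n));

  double vnorm = 0.0;
  for (int j = 0; j < n; ++j) vnorm += v0[j] * v0[j];
  vnorm = std::sqrt(vnorm);
  if (vnorm <= 0.0) stop("starting vector has zero norm");
  for (int j = 0; j < n; ++j) v[j] = v0[j] / vnorm;

  double lambda = 0.0;
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    u_old = u;
    v_old = v;

    double vmax = 0.0;
    for (int j = 0; j < n; ++j) vmax = std::max(vmax, std::fabs(v[j]));
    const double v_eps = 1e-8 * vmax;
    totw.assign(p, 0.0);
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < n; ++j)
        if (obs(i, j) && std::fabs(v[j]) > v_eps) totw[i] += std::fabs(v[j]);
    const double u_minw = 0.05 * median_of_positive(totw);

    // u_i <- argmin sum_j |res_ij - u_i v_j| = wmedian(res_ij / v_j; |v_j|)
    for (int i = 0; i < p; ++i) {
      if (totw[i] <= u_minw) { u[i] = 0.0; continue; }
      vals.clear();
      wts.clear();
      for (int j = 0; j < n; ++j) {
        if (obs(i, j) && std::fabs(v[j]) > v_eps) {
          vals.push_back(res(i, j) / v[j]);
          wts.push_back(std::fabs(v[j]));
        }
      }
      u[i] = weighted_median(vals, wts);
    }
    double unorm = 0.0;
    for (int i = 0; i < p; ++i) unorm += u[i] * u[i];
    unorm = std::sqrt(unorm);
    if (unorm <= 0.0) { lambda = 0.0; break; }  // residual exhausted
    for (int i = 0; i < p; ++i) u[i] /= unorm;

    double umax = 0.0;
    for (int i = 0; i < p; ++i) umax = std::max(umax, std::fabs(u[i]));
    const double u_eps = 1e-8 * umax;
    totw.assign(n, 0.0);
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < n; ++j)
        if (obs(i, j) && std::fabs(u[i]) > u_eps) totw[j] += std::fabs(u[i]);
    const double v_minw = 0.05 * median_of_positive(totw);

    // v_j <- wmedian(res_ij / u_i; |u_i|); its norm is the component scale
    for (int j = 0; j < n; ++j) {
      if (totw[j] <= v_minw) { v[j] = 0.0; continue; }
      vals.clear();
      wts.clear();
      for (int i = 0; i < p; ++i) {
        if (obs(i, j) && std::fabs(u[i]) > u_eps) {
          vals.push_back(res(i, j) / u[i]);
          wts.push_back(std::fabs(u[i]));
        }
      }
      v[j] = weighted_median(vals, wts);
    }
    lambda = 0.0;
    for (int j = 0; j < n; ++j) lambda += v[j] * v[j];
    lambda = std::sqrt(lambda);
    if (lambda <= 0.0) break;
    for (int j = 0; j < n; ++j) v[j] /= lambda;

    // convergence on max absolute change, after aligning signs
    double du = 0.0, dv = 0.0, su = 0.0, sv = 0.0;
    for (int i = 0; i < p; ++i) su += u[i] * u_old[i];
    for (int j = 0; j < n; ++j) sv += v[j] * v_old[j];
    const double sgu = su < 0.0 ? -1.0 : 1.0, sgv = sv < 0.0 ? -1.0 : 1.0;
    for (int i = 0; i < p; ++i) du = std::max(du, std::fabs(sgu * u[i] - u_old[i]));
    for (int j = 0; j < n; ++j) dv = std::max(dv, std::fabs(sgv * v[j] - v_old[j]));
    if (iter > 1 && du < tol && dv < tol) { converged = true; break; }
  }
  if (iter > max_iter) iter = max_iter;

  // Final scale: one global LAD coefficient of the residual on the outer
  // product u v'. A single coefficient estimated from all observed cells
  // cannot co-adapt to noise the way the per-coordinate fits can, so noise
  // components keep honest (small) scales while exact low-rank structure is
  // reproduced to machine precision.
  if (lambda > 0.0) {
    double wmax = 0.0;
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < n; ++j)
        if (obs(i, j)) wmax = std::max(wmax, std::fabs(u[i] * v[j]));
    if (wmax > 0.0) {
      vals.clear();
      wts.clear();
      const double w_eps = 1e-8 * wmax;
      for (int i = 0; i < p; ++i) {
        if (u[i] == 0.0) continue;
        for (int j = 0; j < n; ++j) {
          const double w = std::fabs(u[i] * v[j]);
          if (obs(i, j) && w > w_eps) {
            vals.push_back(res(i, j) / (u[i] * v[j]));
            wts.push_back(w);
          }
        }
      }
      const double lam = weighted_median(vals, wts);
      lambda = lam > 0.0 ? lam : 0.0;
    } else {
      lambda = 0.0;
    }
  }

  return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["lambda"] = lambda,
                      _["iterations"] = iter,
                      _["converged"] = converged);
}
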
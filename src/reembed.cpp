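#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Out-of-sample placement for one chunk of frames.
//
// Dt: n_train x n_new KL distances (transposed so each new point's
// distances are contiguous). For each point: perplexity-calibrated
// Gaussian affinities restricted to its k_aff nearest training rows
// (weights farther out are negligible at small perplexity), gradient
// descent with momentum on the KL(p || q) placement cost from the
// best-affinity training position, with early stopping on the gradient
// norm. The cost is tracked over the last 10 steps for the monotonicity
// part of the convergence test.
// [[Rcpp::export]]
List reembed_chunk_cpp(const arma::mat& Dt, const arma::mat& Ytrain,
                       double perplexity, int n_iter, double eta,
                       double grad_tol, int k_aff) {
  const int n_tr = Dt.n_rows;
  const int n_new = Dt.n_cols;
  if (k_aff > n_tr) k_aff = n_tr;
  const double logU = std::log(perplexity);
  arma::mat Y(n_new, 2);
  arma::vec gnorm(n_new), costs(n_new);
  LogicalVector mono(n_new);
  const arma::vec ytr_x = Ytrain.col(0);
  const arma::vec ytr_y = Ytrain.col(1);

  arma::uvec idx(k_aff);
  arma::vec dk(k_aff), w(k_aff), p(k_aff);
  arma::vec wt(n_tr);

  for (int i = 0; i < n_new; ++i) {
    const arma::vec di = Dt.col(i);
    // k smallest distances
    arma::uvec ord = arma::sort_index(di);
    for (int j = 0; j < k_aff; ++j) {
      idx(j) = ord(j);
      dk(j) = di(ord(j));
    }
    // perplexity calibration by bisection on the k nearest
    double beta = 1.0, bmin = -arma::datum::inf, bmax = arma::datum::inf;
    for (int it = 0; it < 50; ++it) {
      double sw = 0.0;
      for (int j = 0; j < k_aff; ++j) { w(j) = std::exp(-dk(j) * beta); sw += w(j); }
      double H = 0.0;
      for (int j = 0; j < k_aff; ++j) {
        double pj = w(j) / sw;
        if (pj > 1e-300) H -= pj * std::log(pj);
      }
      if (std::fabs(H - logU) < 1e-5) break;
      if (H > logU) { bmin = beta; beta = std::isfinite(bmax) ? 0.5 * (beta + bmax) : beta * 2; }
      else { bmax = beta; beta = std::isfinite(bmin) ? 0.5 * (beta + bmin) : beta * 0.5; }
    }
    double sw = 0.0;
    for (int j = 0; j < k_aff; ++j) { w(j) = std::exp(-dk(j) * beta); sw += w(j); }
    for (int j = 0; j < k_aff; ++j) p(j) = w(j) / sw;

    // start at the highest-affinity training position
    double yx = ytr_x(idx(0)), yy = ytr_y(idx(0));
    double vx = 0.0, vy = 0.0;
    double prev_cost = arma::datum::inf, cost = 0.0;
    double gx = 0.0, gy = 0.0;
    int bad = 0;
    arma::vec dxv(n_tr), dyv(n_tr);
    for (int it = 0; it < n_iter; ++it) {
      // Student-t weights to every training position (vectorized);
      // repulsion = -2/Z * sum_j w_j^2 (y - y_j)
      dxv = yx - ytr_x;
      dyv = yy - ytr_y;
      wt = 1.0 / (1.0 + dxv % dxv + dyv % dyv);
      const double Z = arma::accu(wt);
      const arma::vec w2 = wt % wt;
      gx = -2.0 / Z * arma::dot(w2, dxv);
      gy = -2.0 / Z * arma::dot(w2, dyv);
      // attractive part over the affinity support, plus the cost
      cost = 0.0;
      for (int j = 0; j < k_aff; ++j) {
        int t = idx(j);
        double coef = 2.0 * p(j) * wt(t);
        gx += coef * dxv(t);
        gy += coef * dyv(t);
        double q = wt(t) / Z;
        if (p(j) > 1e-300) cost += p(j) * std::log(p(j) / std::max(q, 1e-300));
      }
      if (it >= n_iter - 10 && cost > prev_cost + 1e-9) ++bad;
      prev_cost = cost;
      double gn = std::sqrt(gx * gx + gy * gy);
      if (gn < grad_tol) break;   // converged; gradient recorded below
      vx = 0.6 * vx - eta * gx;
      vy = 0.6 * vy - eta * gy;
      yx += vx; yy += vy;
    }
    Y(i, 0) = yx; Y(i, 1) = yy;
    gnorm(i) = std::sqrt(gx * gx + gy * gy);
    costs(i) = cost;
    mono(i) = bad == 0;
  }
  return List::create(_["Y"] = Y, _["grad_norm"] = gnorm,
                      _["cost"] = costs, _["monotone"] = mono);
}
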
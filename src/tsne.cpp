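#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Exact t-SNE gradient descent on precomputed symmetric affinities.
// P: n x n joint affinities (symmetric, summing to 1); Y0: n x 2 init.
// Early exaggeration for the first exag_iter iterations; momentum switches
// from 0.5 to 0.8 at iteration 250 (standard schedule).
// [[Rcpp::export]]
List tsne_cpp(const arma::mat& P, const arma::mat& Y0, int n_iter,
              double eta, double exaggeration, int exag_iter) {
  const int n = P.n_rows;
  arma::mat Y = Y0;
  arma::mat dY(n, 2, arma::fill::zeros);
  arma::mat gains(n, 2, arma::fill::ones);
  arma::mat Pe = P * exaggeration;
  const double eps = 1e-12;

  for (int iter = 0; iter < n_iter; ++iter) {
    if (iter == exag_iter) Pe = P;
    double momentum = iter < 250 ? 0.5 : 0.8;
    // pairwise Student-t kernel
    arma::vec ss = arma::sum(Y % Y, 1);
    arma::mat D = -2.0 * (Y * Y.t());
    D.each_col() += ss;
    D.each_row() += ss.t();
    arma::mat W = 1.0 / (1.0 + D);
    W.diag().zeros();
    double Z = arma::accu(W);
    arma::mat PQ = (Pe - W / Z) % W;   // (p_ij - q_ij) * w_ij
    arma::vec rs = arma::sum(PQ, 1);
    arma::mat grad = 4.0 * (arma::diagmat(rs) * Y - PQ * Y);
    // adaptive gains as in the reference implementation
    for (int i = 0; i < n; ++i) {
      for (int d = 0; d < 2; ++d) {
        bool same = (grad(i, d) > 0) == (dY(i, d) > 0);
        gains(i, d) = same ? gains(i, d) * 0.8 : gains(i, d) + 0.2;
        if (gains(i, d) < 0.01) gains(i, d) = 0.01;
      }
    }
    dY = momentum * dY - eta * (gains % grad);
    Y += dY;
    Y.each_row() -= arma::mean(Y, 0);
  }
  // final cost KL(P || Q)
  arma::vec ss = arma::sum(Y % Y, 1);
  arma::mat D = -2.0 * (Y * Y.t());
  D.each_col() += ss;
  D.each_row() += ss.t();
  arma::mat W = 1.0 / (1.0 + D);
  W.diag().zeros();
  arma::mat Q = W / arma::accu(W);
  double cost = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (P(i, j) > eps) cost += P(i, j) * std::log(P(i, j) / std::max(Q(i, j), eps));
  return List::create(_["Y"] = Y, _["cost"] = cost);
}
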
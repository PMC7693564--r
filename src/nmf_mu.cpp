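#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Multiplicative-update NMF for ||X - WH||_F^2 + gamma*(sum W + sum H).
// The objective is recorded once per iteration, after the H half-update,
// from cached cross-products (no explicit WH residual is formed):
//   ||X - WH||^2 = ||X||^2 - 2<W'X, H> + <W'W, HH'>
// Every half-update is a descent step, so the trajectory is
// non-increasing up to floating-point round-off.
// [[Rcpp::export]]
Rcpp::List nmf_mu_cpp(const arma::mat& X, arma::mat W, arma::mat H,
                      int max_iter, double tol, double gamma) {
  const double eps = 1e-12;
  const double normX2 = accu(square(X));
  std::vector<double> loss;
  loss.reserve(max_iter);
  double prev = datum::inf;
  for (int it = 0; it < max_iter; ++it) {
    mat WtX = W.t() * X;
    mat WtW = W.t() * W;
    H %= (2.0 * WtX) / (2.0 * WtW * H + gamma + eps);
    mat HHt = H * H.t();
    double cur = normX2 - 2.0 * accu(WtX % H) + accu(WtW % HHt) +
                 gamma * (accu(W) + accu(H));
    mat XHt = X * H.t();
    W %= (2.0 * XHt) / (2.0 * W * HHt + gamma + eps);
    loss.push_back(cur);
    if (std::isfinite(prev) &&
        std::fabs(prev - cur) < tol * std::max(prev, eps)) break;
    prev = cur;
  }
  return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("H") = H,
                            Rcpp::Named("loss") = loss);
}
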
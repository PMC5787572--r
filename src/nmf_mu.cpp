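#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Lee-Seung multiplicative updates for the squared Frobenius objective.
// When update_w is false only the activation matrix C is updated (the
// fixed-weighting refit used on held-out gait cycles).  The epsilon floor
// in the denominators is the standard safeguard against division by zero;
// it also keeps exact zeros absorbing (a zero entry stays zero).
// [[Rcpp::export]]
List nmf_mu_cpp(const arma::mat& M, arma::mat W, arma::mat C,
                int max_iter, double tol, bool update_w, bool track_sse) {
  const double eps = 1e-12;
  double sse = arma::accu(arma::square(M - W * C));
  double sse_prev = sse;
  bool converged = false;
  int it = 0;
  std::vector<double> trace;
  if (track_sse) trace.reserve(max_iter);

  for (it = 1; it <= max_iter; ++it) {
    C %= (W.t() * M) / (W.t() * W * C + eps);
    if (update_w) {
      W %= (M * C.t()) / (W * (C * C.t()) + eps);
    }
    sse = arma::accu(arma::square(M - W * C));
    if (track_sse) trace.push_back(sse);
    double denom = std::max(sse_prev, eps);
    if ((sse_prev - sse) / denom < tol) {
      converged = true;
      break;
    }
    sse_prev = sse;
  }
  if (it > max_iter) it = max_iter;

  return List::create(
    _["W"] = W,
    _["C"] = C,
    _["residual_sse"] = sse,
    _["iterations"] = it,
    _["converged"] = converged,
    _["sse_trace"] = NumericVector(trace.begin(), trace.end()));
}
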
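// Multiplicative-update NMF under generalized Kullback-Leibler divergence.
// The inner loop lives here because consensus clustering multiplies single
// factorizations by (runs x ranks x seeds); everything else stays in R.
// Buffers are preallocated: the updates are memory-bound at these shapes
// (tall-skinny W, short-wide H), so avoiding per-iteration temporaries
// matters more than the flop count.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double kl_div(const mat& X, const mat& WH, const uvec& pos) {
  double s = accu(WH) - accu(X);
  s += accu(X.elem(pos) % log(X.elem(pos) / WH.elem(pos)));
  return s;
}

// [[Rcpp::export(name = ".nmf_mu_kl")]]
Rcpp::List nmf_mu_kl(const arma::mat& X, arma::mat W, arma::mat H,
                     int max_iter, double tol, bool track) {
  const double eps = datum::eps;
  const uvec pos = find(X > 0);
  std::vector<double> trace;
  double obj_prev = datum::inf, obj = datum::inf;
  int n_iter = max_iter;
  const int check_every = track ? 1 : 10;

  mat WH(X.n_rows, X.n_cols), V(X.n_rows, X.n_cols);
  WH = W * H;
  WH += eps;
  for (int it = 1; it <= max_iter; ++it) {
    V = X / WH;
    H %= (W.t() * V);
    H.each_col() /= (sum(W, 0).t() + eps);
    WH = W * H;
    WH += eps;
    V = X / WH;
    W %= (V * H.t());
    W.each_row() /= (sum(H, 1).t() + eps);
    WH = W * H;
    WH += eps;
    if (it % check_every == 0 || it == max_iter) {
      obj = kl_div(X, WH, pos);
      if (track) trace.push_back(obj);
      if (std::isfinite(obj_prev) &&
          std::fabs(obj_prev - obj) <=
              tol * std::max(std::fabs(obj_prev), eps)) {
        n_iter = it;
        break;
      }
      obj_prev = obj;
    }
  }
  obj = kl_div(X, WH, pos);
  return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("H") = H,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("n_iter") = n_iter,
                            Rcpp::Named("objective_trace") = trace);
}
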
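#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Generalized KL divergence D(V || WH); 0*log(0) terms contribute 0.
static double kl_div(const mat& V, const mat& WH, const uvec& nz) {
  double obj = accu(WH) - accu(V);
  const vec v = V.elem(nz);
  const vec wh = WH.elem(nz);
  obj += accu(v % log(v / (wh + 1e-300)));
  return obj;
}

// Brunet multiplicative updates for KL-divergence NMF.
// W and H are modified in place from the supplied initialization; the
// objective is recorded after every full (H then W) update.
// [[Rcpp::export]]
Rcpp::List nmf_kl_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol) {
  const double eps = 1e-16;
  const uvec nz = find(V > 0);
  std::vector<double> trace;
  trace.reserve(64);
  mat WH = W * H;
  double prev = kl_div(V, WH, nz);
  for (int it = 0; it < max_iter; ++it) {
    mat R = V / (WH + eps);
    H %= (W.t() * R);
    H.each_col() /= (sum(W, 0).t() + eps);
    WH = W * H;
    R = V / (WH + eps);
    W %= (R * H.t());
    W.each_row() /= (sum(H, 1).t() + eps);
    WH = W * H;
    const double obj = kl_div(V, WH, nz);
    trace.push_back(obj);
    if (std::abs(prev - obj) <= tol * std::max(1.0, std::abs(prev))) {
      prev = obj;
      break;
    }
    prev = obj;
  }
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("H") = H,
                            Rcpp::Named("trace") = trace);
}
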
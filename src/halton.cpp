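// Radical-inverse (Halton) sequence with optional digit permutations.
// Kept in compiled code: draw generation at 10^5+ points per individual is
// otherwise a bottleneck of the simulated-likelihood pipeline.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::mat halton_engine(int total, int drop, const arma::ivec& bases,
                        const Rcpp::List& perms) {
  const int D = bases.n_elem;
  arma::mat out(total, D);
  for (int d = 0; d < D; ++d) {
    const int p = bases(d);
    Rcpp::IntegerVector pv = perms[d];  // length 0 = identity
    const bool use_perm = pv.size() > 0;
    for (long i = 0; i < total; ++i) {
      long idx = i + 1 + drop;
      double f = 0.0, denom = 1.0 / p;
      while (idx > 0) {
        int dig = idx % p;
        if (use_perm) dig = pv[dig];
        f += dig * denom;
        idx /= p;
        denom /= p;
      }
      out(i, d) = f;
    }
  }
  return out;
}
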
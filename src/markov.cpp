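// Order-k Markov chain simulation over the {A,C,G,T} alphabet, used by the
// synthetic community generator. Bases are encoded 0..3; the context index
// is the base-4 encoding of the last `order` bases. Uses R's RNG.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector markov_chain_cpp(int n, NumericMatrix trans, int order,
                               IntegerVector init) {
  if (order < 0) stop("order must be >= 0");
  if (init.size() != order) stop("init must hold exactly `order` bases");
  int n_ctx = 1;
  for (int i = 0; i < order; ++i) n_ctx *= 4;
  if (trans.nrow() != n_ctx || trans.ncol() != 4)
    stop("transition matrix must be 4^order x 4");
  IntegerVector out(n);
  int ctx = 0;
  for (int i = 0; i < order && i < n; ++i) {
    out[i] = init[i];
    ctx = (ctx * 4 + init[i]) % n_ctx;
  }
  for (int i = order; i < n; ++i) {
    const double u = R::unif_rand();
    double acc = 0.0;
    int b = 3;
    for (int j = 0; j < 4; ++j) {
      acc += trans(ctx, j);
      if (u <= acc) { b = j; break; }
    }
    out[i] = b;
    if (order > 0) ctx = (ctx * 4 + b) % n_ctx;
  }
  return out;
}
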
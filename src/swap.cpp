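#include <Rcpp.h>
using namespace Rcpp;

// Trial-swap chain for binary presence matrices.  Each trial draws two
// distinct rows and two distinct columns uniformly; if the 2x2 submatrix is
// a checkerboard it is flipped, otherwise the state is unchanged.  Counting
// *trials* (not successful flips) makes the proposal symmetric, so the
// stationary distribution is uniform over all matrices with the observed
// row and column sums.  Uses the R RNG, so results follow set.seed().
// [[Rcpp::export]]
IntegerMatrix swap_chain_cpp(IntegerMatrix m, int n_trials) {
  IntegerMatrix out = clone(m);
  int nr = out.nrow(), nc = out.ncol();
  int successes = 0;
  if (nr < 2 || nc < 2) {
    out.attr("successes") = successes;
    return out;
  }
  for (int t = 0; t < n_trials; ++t) {
    int r1 = (int)(unif_rand() * nr);
    int r2 = (int)(unif_rand() * (nr - 1));
    if (r2 >= r1) ++r2;
    int c1 = (int)(unif_rand() * nc);
    int c2 = (int)(unif_rand() * (nc - 1));
    if (c2 >= c1) ++c2;
    int a = out(r1, c1), b = out(r1, c2), c = out(r2, c1), d = out(r2, c2);
    if (a == 1 && d == 1 && b == 0 && c == 0) {
      out(r1, c1) = 0; out(r2, c2) = 0; out(r1, c2) = 1; out(r2, c1) = 1;
      ++successes;
    } else if (a == 0 && d == 0 && b == 1 && c == 1) {
      out(r1, c1) = 1; out(r2, c2) = 1; out(r1, c2) = 0; out(r2, c1) = 0;
      ++successes;
    }
  }
  out.attr("successes") = successes;
  return out;
}
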
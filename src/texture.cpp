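#include <Rcpp.h>
using namespace Rcpp;

// Directed co-occurrence counts for one pixel offset (dr, dc).
// levels: integer grid, 1..ng inside the mask, anything elsewhere;
// mask: 0/1 grid of the same shape. A pair is counted only when both
// endpoints are in-mask. Symmetrization happens in R.
// [[Rcpp::export]]
IntegerMatrix glcm_counts_cpp(IntegerMatrix levels, IntegerMatrix mask,
                              int dr, int dc, int ng) {
  int nr = levels.nrow(), nc = levels.ncol();
  IntegerMatrix counts(ng, ng);
  for (int r = 0; r < nr; ++r) {
    int r2 = r + dr;
    if (r2 < 0 || r2 >= nr) continue;
    for (int c = 0; c < nc; ++c) {
      int c2 = c + dc;
      if (c2 < 0 || c2 >= nc) continue;
      if (mask(r, c) == 0 || mask(r2, c2) == 0) continue;
      int i = levels(r, c), j = levels(r2, c2);
      counts(i - 1, j - 1) += 1;
    }
  }
  return counts;
}

// Run-length counts along direction (dr, dc). A run is a maximal chain of
// in-mask pixels with equal level; leaving the mask or the grid ends it.
// Returns an ng x max(nr, nc) matrix R with R(i-1, len-1) = #runs.
// [[Rcpp::export]]
IntegerMatrix glrlm_counts_cpp(IntegerMatrix levels, IntegerMatrix mask,
                               int dr, int dc, int ng) {
  int nr = levels.nrow(), nc = levels.ncol();
  int lmax = nr > nc ? nr : nc;
  IntegerMatrix R(ng, lmax);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) == 0) continue;
      int lev = levels(r, c);
      // run start: predecessor out of grid, out of mask, or different level
      int pr = r - dr, pc = c - dc;
      bool start = pr < 0 || pr >= nr || pc < 0 || pc >= nc ||
                   mask(pr, pc) == 0 || levels(pr, pc) != lev;
      if (!start) continue;
      int len = 1, qr = r + dr, qc = c + dc;
      while (qr >= 0 && qr < nr && qc >= 0 && qc < nc &&
             mask(qr, qc) != 0 && levels(qr, qc) == lev) {
        ++len; qr += dr; qc += dc;
      }
      R(lev - 1, len - 1) += 1;
    }
  }
  return R;
}
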
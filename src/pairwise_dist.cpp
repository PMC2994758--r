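#include <Rcpp.h>
using namespace Rcpp;

// Pairwise percent divergence between aligned rows of an integer code
// matrix (sequences in rows, alignment columns in columns).
//
// Code convention (set in residue_codes() on the R side):
//   0  -> gap: the column is excluded from the comparison when either
//         sequence is gapped (pairwise deletion),
//  -1  -> unknown residue 'X': mismatches every code, including -1,
//  >0  -> amino-acid identity; equal codes match.
//
// Returns d as percent (100 * mismatches / compared columns) and the
// number of compared columns; d is NA when no column is comparable.
// The diagonal is 0 by convention (a sequence is at distance 0 from
// itself), with n_compared equal to its ungapped length.
// [[Rcpp::export]]
List dist_matrix_codes(IntegerMatrix codes) {
  const int n = codes.nrow();
  const int L = codes.ncol();
  NumericMatrix d(n, n);
  IntegerMatrix ncmp(n, n);

  for (int i = 0; i < n; ++i) {
    int self = 0;
    for (int k = 0; k < L; ++k) {
      if (codes(i, k) != 0) ++self;
    }
    ncmp(i, i) = self;
    d(i, i) = 0.0;
  }

  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int compared = 0, mismatch = 0;
      for (int k = 0; k < L; ++k) {
        const int a = codes(i, k);
        const int b = codes(j, k);
        if (a == 0 || b == 0) continue;
        ++compared;
        if (a == -1 || b == -1 || a != b) ++mismatch;
      }
      double dij = compared > 0 ?
        100.0 * (double)mismatch / (double)compared : NA_REAL;
      d(i, j) = dij;
      d(j, i) = dij;
      ncmp(i, j) = compared;
      ncmp(j, i) = compared;
    }
  }

  return List::create(_["d"] = d, _["n_compared"] = ncmp);
}
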
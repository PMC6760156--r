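#include <Rcpp.h>
using namespace Rcpp;

// Diagonal line-length and white vertical line-length histograms of a binary
// recurrence matrix.  For auto-recurrence matrices, diagonals with
// |i - j| < theiler are excluded entirely (Theiler window; theiler = 1 masks
// only the line of identity).  White vertical runs are gaps between
// recurrence points within a column: only runs bounded by recurrent cells on
// both ends are counted, and Theiler-masked cells count as recurrent so the
// masked band delimits gaps exactly as the LOI does.
// [[Rcpp::export]]
List line_histograms(const LogicalMatrix& R, int theiler, bool is_auto) {
  const int n = R.nrow(), m = R.ncol();
  const int maxlen = std::max(n, m);
  IntegerVector diag_counts(maxlen), white_counts(maxlen);

  for (int k = -(n - 1); k <= m - 1; ++k) {
    if (is_auto && std::abs(k) < theiler) continue;
    int i = k < 0 ? -k : 0;
    int j = k < 0 ? 0 : k;
    int run = 0;
    for (; i < n && j < m; ++i, ++j) {
      if (R(i, j)) {
        ++run;
      } else if (run > 0) {
        ++diag_counts[run - 1];
        run = 0;
      }
    }
    if (run > 0) ++diag_counts[run - 1];
  }

  for (int j = 0; j < m; ++j) {
    int gap = 0;
    bool seen = false;  // a recurrent cell above the current position
    for (int i = 0; i < n; ++i) {
      bool rec = R(i, j) || (is_auto && std::abs(i - j) < theiler);
      if (rec) {
        if (seen && gap > 0) ++white_counts[gap - 1];
        gap = 0;
        seen = true;
      } else if (seen) {
        ++gap;
      }
    }
  }

  return List::create(_["diagonal"] = diag_counts, _["white"] = white_counts);
}
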
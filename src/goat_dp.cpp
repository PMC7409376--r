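#include <Rcpp.h>
using namespace Rcpp;

// Semiglobal (free-end-gap) gene-order alignment.
//
// Sequences are 1-based integer indices into the substitution matrix M.
// Match/mismatch score = M(a_i, b_j); every internal gap position costs
// `gap` (linear model); leading and trailing gaps on both sequences are
// free: first row/column initialised to 0 and the optimum is the maximum
// over the last row and last column.

static inline int rot_index(const IntegerVector& v, int pos, int off, int n,
                            bool antisense) {
  // position pos (0-based) of the rotated (and possibly reversed) sequence
  int p = antisense ? (n - 1 - pos) : pos;
  return v[(p + off) % n];
}

// score-only DP on transformed sequences, rolling rows
static double dp_score_only(const IntegerVector& a, const IntegerVector& b,
                            int offa, int offb, bool antisense,
                            const NumericMatrix& M, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  double best = 0.0;  // empty alignment (all end gaps) scores 0
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0.0;
    const int ai = rot_index(a, i - 1, offa, n, false) - 1;
    for (int j = 1; j <= m; ++j) {
      const int bj = rot_index(b, j - 1, offb, m, antisense) - 1;
      double s = prev[j - 1] + M(ai, bj);
      double up = prev[j] - gap;
      double left = cur[j - 1] - gap;
      double h = s >= up ? s : up;
      if (left > h) h = left;
      cur[j] = h;
    }
    if (cur[m] > best) best = cur[m];  // last column
    std::swap(prev, cur);
  }
  for (int j = 0; j <= m; ++j)
    if (prev[j] > best) best = prev[j];  // last row
  return best;
}

// [[Rcpp::export]]
List goat_dp_full(IntegerVector a, IntegerVector b, NumericMatrix M,
                  double gap) {
  // full DP with deterministic traceback (diagonal, then gap-in-b
  // [consume a], then gap-in-a); start cell = boundary maximum,
  // ties to largest i then largest j.
  const int n = a.size(), m = b.size();
  NumericMatrix H(n + 1, m + 1);
  for (int i = 0; i <= n; ++i) H(i, 0) = 0.0;
  for (int j = 0; j <= m; ++j) H(0, j) = 0.0;
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      const int bj = b[j - 1] - 1;
      double s = H(i - 1, j - 1) + M(ai, bj);
      double up = H(i - 1, j) - gap;
      double left = H(i, j - 1) - gap;
      double h = s >= up ? s : up;
      if (left > h) h = left;
      H(i, j) = h;
    }
  }
  int si = n, sj = m;
  double best = H(n, m);
  for (int i = n; i >= 0; --i)
    if (H(i, m) > best) { best = H(i, m); si = i; sj = m; }
  for (int j = m; j >= 0; --j)
    if (H(n, j) > best) { best = H(n, j); si = n; sj = j; }
  // traceback
  std::vector<int> pa, pb;
  int i = si, j = sj;
  const double eps = 1e-9;
  while (i > 0 && j > 0) {
    double s = H(i - 1, j - 1) + M(a[i - 1] - 1, b[j - 1] - 1);
    if (std::abs(H(i, j) - s) <= eps) {
      pa.push_back(i); pb.push_back(j);
      --i; --j;
    } else if (std::abs(H(i, j) - (H(i - 1, j) - gap)) <= eps) {
      --i;
    } else {
      --j;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  IntegerMatrix pairs(pa.size(), 2);
  for (size_t k = 0; k < pa.size(); ++k) {
    pairs(k, 0) = pa[k];
    pairs(k, 1) = pb[k];
  }
  return List::create(_["score"] = best, _["pairs"] = pairs);
}

// [[Rcpp::export]]
List goat_best_search(IntegerVector a, IntegerVector b, NumericMatrix M,
                      double gap, bool rotate_a, bool rotate_b,
                      bool antisense) {
  // maximum semiglobal score over circular rotations of a and/or b and
  // both orientations of b; tie-break: smallest a-offset, then smallest
  // b-offset, then sense before antisense (loop order enforces this with
  // strict improvement).
  const int n = a.size(), m = b.size();
  const int na = rotate_a ? n : 1;
  const int nb = rotate_b ? m : 1;
  double best = R_NegInf;
  int boffa = 0, boffb = 0;
  bool banti = false;
  for (int ka = 0; ka < na; ++ka) {
    for (int kb = 0; kb < nb; ++kb) {
      for (int o = 0; o < (antisense ? 2 : 1); ++o) {
        double s = dp_score_only(a, b, ka, kb, o == 1, M, gap);
        if (s > best) {
          best = s; boffa = ka; boffb = kb; banti = (o == 1);
        }
      }
    }
  }
  return List::create(_["score"] = best, _["offset_a"] = boffa,
                      _["offset_b"] = boffb, _["antisense"] = banti);
}
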
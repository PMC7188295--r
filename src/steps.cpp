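#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Mutational steps between two sequences: substitution columns plus
// contiguous gap runs of the optimal global alignment (match +1,
// mismatch -2, gap open -4, gap extension -1; a gap of length L costs
// 4 + L).  Among score-optimal alignments the one with the fewest steps
// is taken.  Three-state affine Gotoh DP over (score, steps) pairs
// ordered lexicographically (max score, then min steps).
namespace {

struct Cell {
  int score;
  int steps;
};

const int NEG = -(1 << 28);

inline Cell worst() { return Cell{NEG, 0}; }

inline bool better(const Cell &a, const Cell &b) {
  return a.score > b.score || (a.score == b.score && a.steps < b.steps);
}

inline Cell best(const Cell &a, const Cell &b) { return better(a, b) ? a : b; }

inline Cell add(const Cell &c, int dscore, int dsteps) {
  if (c.score <= NEG) return worst();
  return Cell{c.score + dscore, c.steps + dsteps};
}

}  // namespace

// [[Rcpp::export(name = ".steps_dp")]]
int steps_dp(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  const int MATCH = 1, MISMATCH = -2, OPEN = 4, EXT = 1;
  std::vector<Cell> M(m + 1), X(m + 1), Y(m + 1);
  std::vector<Cell> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  Mp[0] = Cell{0, 0};
  Xp[0] = worst(); Yp[0] = worst();
  for (int j = 1; j <= m; ++j) {
    Mp[j] = worst();
    Xp[j] = Cell{-(OPEN + EXT * j), 1};   // leading gap in a: one run
    Yp[j] = worst();
  }
  for (int i = 1; i <= n; ++i) {
    M[0] = worst();
    X[0] = worst();
    Y[0] = Cell{-(OPEN + EXT * i), 1};    // leading gap in b: one run
    for (int j = 1; j <= m; ++j) {
      bool eq = a[i - 1] == b[j - 1];
      Cell diag = best(Mp[j - 1], best(Xp[j - 1], Yp[j - 1]));
      M[j] = add(diag, eq ? MATCH : MISMATCH, eq ? 0 : 1);
      X[j] = best(add(M[j - 1], -(OPEN + EXT), 1),      // open gap in a
                  best(add(X[j - 1], -EXT, 0),          // extend
                       add(Y[j - 1], -(OPEN + EXT), 1)));
      Y[j] = best(add(Mp[j], -(OPEN + EXT), 1),         // open gap in b
                  best(add(Yp[j], -EXT, 0),
                       add(Xp[j], -(OPEN + EXT), 1)));
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  if (n == 0 && m == 0) return 0;
  Cell fin = best(Mp[m], best(Xp[m], Yp[m]));
  return fin.steps;
}

// Bounded Levenshtein distance of `a` against each of `bs`: exact value
// when <= k, else k+1.  Banded DP (Ukkonen), O(len * k) per pair.
// [[Rcpp::export(name = ".lev_bounded")]]
IntegerVector lev_bounded(std::string a, std::vector<std::string> bs, int k) {
  const int n = a.size();
  IntegerVector out(bs.size());
  std::vector<int> prev, cur;
  for (size_t q = 0; q < bs.size(); ++q) {
    const std::string &b = bs[q];
    const int m = b.size();
    if (std::abs(n - m) > k) { out[q] = k + 1; continue; }
    const int BIG = k + 1;
    prev.assign(m + 1, BIG);
    for (int j = 0; j <= std::min(m, k); ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
      cur.assign(m + 1, BIG);
      int lo = std::max(1, i - k), hi = std::min(m, i + k);
      if (i - k <= 0) cur[0] = i <= k ? i : BIG;
      int rowmin = cur[0];
      for (int j = lo; j <= hi; ++j) {
        int d = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
        if (prev[j] + 1 < d) d = prev[j] + 1;
        if (cur[j - 1] + 1 < d) d = cur[j - 1] + 1;
        cur[j] = d > BIG ? BIG : d;
        if (cur[j] < rowmin) rowmin = cur[j];
      }
      if (rowmin >= BIG) { prev.assign(m + 1, BIG); break; }
      std::swap(prev, cur);
    }
    out[q] = prev[m] > k ? k + 1 : prev[m];
  }
  return out;
}
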
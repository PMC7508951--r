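#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap costs.
// Scoring: +match for identical residues, +mismatch otherwise, +gap per
// gapped base. Among score-optimal alignments the one with the most match
// columns, then the most aligned residue pairs (fewest columns), is
// returned; both secondary objectives are additive, so the lexicographic
// optimum is itself computable by dynamic programming. This makes percent
// identity (matches / columns) symmetric in the sequences. Remaining ties are
// broken deterministically at every traceback step: prefer the diagonal
// (match/mismatch) move, then a gap in `a` (consuming a residue of `b`),
// then a gap in `b`.

struct Cell {
  double score;
  int matches;
  int pairs;  // aligned residue pairs (diagonal moves)
};

static inline bool better(double s, int m, int p, const Cell &c) {
  if (s > c.score + 1e-12) return true;
  if (s < c.score - 1e-12) return false;
  if (m != c.matches) return m > c.matches;
  return p > c.pairs;
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<Cell> prev(m + 1), cur(m + 1);
  // traceback codes: 0 diag, 1 gap-in-a (left, consumes b), 2 gap-in-b (up)
  std::vector<unsigned char> tb((n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) {
    prev[j] = {j * gap, 0, 0};
    tb[j] = 1;
  }
  for (int i = 1; i <= n; ++i) {
    cur[0] = {i * gap, 0, 0};
    tb[i * (m + 1)] = 2;
    for (int j = 1; j <= m; ++j) {
      const bool is_match = a[i - 1] == b[j - 1];
      Cell best = {prev[j - 1].score + (is_match ? match : mismatch),
                   prev[j - 1].matches + (is_match ? 1 : 0),
                   prev[j - 1].pairs + 1};
      unsigned char code = 0;
      if (better(cur[j - 1].score + gap, cur[j - 1].matches,
                 cur[j - 1].pairs, best)) {
        best = {cur[j - 1].score + gap, cur[j - 1].matches, cur[j - 1].pairs};
        code = 1;
      }
      if (better(prev[j].score + gap, prev[j].matches, prev[j].pairs, best)) {
        best = {prev[j].score + gap, prev[j].matches, prev[j].pairs};
        code = 2;
      }
      cur[j] = best;
      tb[i * (m + 1) + j] = code;
    }
    std::swap(prev, cur);
  }
  double score = prev[m].score;

  std::string out_a, out_b;
  out_a.reserve(n + m);
  out_b.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char code = tb[i * (m + 1) + j];
    if (i > 0 && j > 0 && code == 0) {
      out_a.push_back(a[i - 1]);
      out_b.push_back(b[j - 1]);
      --i; --j;
    } else if (j > 0 && (code == 1 || i == 0)) {
      out_a.push_back('-');
      out_b.push_back(b[j - 1]);
      --j;
    } else {
      out_a.push_back(a[i - 1]);
      out_b.push_back('-');
      --i;
    }
  }
  std::reverse(out_a.begin(), out_a.end());
  std::reverse(out_b.begin(), out_b.end());
  return List::create(_["score"] = score,
                      _["aligned_a"] = out_a,
                      _["aligned_b"] = out_b);
}

// Score-only variant used for best-hit searches (no traceback allocation).
// [[Rcpp::export(name = ".nw_score_cpp")]]
double nw_score_cpp(std::string a, std::string b,
                    double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    for (int j = 1; j <= m; ++j) {
      double sdiag = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double sleft = cur[j - 1] + gap;
      double sup = prev[j] + gap;
      cur[j] = std::max(sdiag, std::max(sleft, sup));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
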
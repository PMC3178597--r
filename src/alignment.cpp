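#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Needleman-Wunsch with linear gap penalty. In overlap mode terminal gaps
// (leading/trailing runs in either sequence) score 0 and the alignment ends
// at the best cell of the last row/column. Ties in traceback prefer diagonal,
// then up (gap in b), then left (gap in a), so results are deterministic.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, double match, double mismatch,
                  double gap, bool overlap) {
  const int la = a.size(), lb = b.size();
  NumericMatrix F(la + 1, lb + 1);
  for (int i = 1; i <= la; ++i) F(i, 0) = overlap ? 0.0 : gap * i;
  for (int j = 1; j <= lb; ++j) F(0, j) = overlap ? 0.0 : gap * j;
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double best = F(i - 1, j - 1) + s;
      double up = F(i - 1, j) + gap;
      double left = F(i, j - 1) + gap;
      if (up > best) best = up;
      if (left > best) best = left;
      F(i, j) = best;
    }
  }
  // end cell: corner for global; best of last row/column for overlap,
  // preferring the corner, then larger i, then larger j on exact ties
  int ei = la, ej = lb;
  double score = F(la, lb);
  if (overlap) {
    for (int i = la - 1; i >= 0; --i)
      if (F(i, lb) > score) { score = F(i, lb); ei = i; ej = lb; }
    for (int j = lb - 1; j >= 0; --j)
      if (F(la, j) > score) { score = F(la, j); ei = la; ej = j; }
  }
  std::string ra, rb;
  ra.reserve(la + lb); rb.reserve(la + lb);
  // free tail (overlap mode only; ei==la or ej==lb otherwise)
  for (int i = la; i > ei; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = lb; j > ej; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  int i = ei, j = ej;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      if (F(i, j) == F(i - 1, j - 1) + s) {
        ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j; continue;
      }
      double gup = (overlap && j == 0) ? 0.0 : gap;  // j>0 here; kept for clarity
      if (F(i, j) == F(i - 1, j) + gup) {
        ra.push_back(a[i - 1]); rb.push_back('-'); --i; continue;
      }
      ra.push_back('-'); rb.push_back(b[j - 1]); --j; continue;
    }
    if (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
    else       { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}

static inline double pair_score(char x, char y, double match, double mismatch) {
  if (x == '-' || y == '-') return 0.0;
  return (x == y) ? match : mismatch;
}

// Profile-profile global alignment: column score is the mean pairwise
// residue score over all cross-profile residue pairs (existing gaps score 0);
// inserting a whole gap column costs the flat per-base gap penalty.
// [[Rcpp::export]]
List profile_align_cpp(CharacterVector rows_a, CharacterVector rows_b,
                       double match, double mismatch, double gap) {
  std::vector<std::string> A, B;
  for (int k = 0; k < rows_a.size(); ++k) A.push_back(as<std::string>(rows_a[k]));
  for (int k = 0; k < rows_b.size(); ++k) B.push_back(as<std::string>(rows_b[k]));
  const int ca = A[0].size(), cb = B[0].size();
  const int na = A.size(), nb = B.size();
  // precompute column-vs-column mean scores
  NumericMatrix S(ca, cb);
  for (int i = 0; i < ca; ++i) {
    for (int j = 0; j < cb; ++j) {
      double tot = 0.0;
      for (int x = 0; x < na; ++x)
        for (int y = 0; y < nb; ++y)
          tot += pair_score(A[x][i], B[y][j], match, mismatch);
      S(i, j) = tot / (na * nb);
    }
  }
  NumericMatrix F(ca + 1, cb + 1);
  for (int i = 1; i <= ca; ++i) F(i, 0) = gap * i;
  for (int j = 1; j <= cb; ++j) F(0, j) = gap * j;
  for (int i = 1; i <= ca; ++i) {
    for (int j = 1; j <= cb; ++j) {
      double best = F(i - 1, j - 1) + S(i - 1, j - 1);
      double up = F(i - 1, j) + gap;
      double left = F(i, j - 1) + gap;
      if (up > best) best = up;
      if (left > best) best = left;
      F(i, j) = best;
    }
  }
  // traceback: 0 = diag, 1 = up (consume A, gap B), 2 = left
  std::vector<int> ops;
  int i = ca, j = cb;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && F(i, j) == F(i - 1, j - 1) + S(i - 1, j - 1)) {
      ops.push_back(0); --i; --j;
    } else if (i > 0 && F(i, j) == F(i - 1, j) + gap) {
      ops.push_back(1); --i;
    } else {
      ops.push_back(2); --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  const int L = ops.size();
  CharacterVector out_a(na), out_b(nb);
  for (int x = 0; x < na; ++x) {
    std::string s; s.reserve(L); int p = 0;
    for (int k = 0; k < L; ++k)
      s.push_back(ops[k] == 2 ? '-' : A[x][p++]);
    out_a[x] = s;
  }
  for (int y = 0; y < nb; ++y) {
    std::string s; s.reserve(L); int p = 0;
    for (int k = 0; k < L; ++k)
      s.push_back(ops[k] == 1 ? '-' : B[y][p++]);
    out_b[y] = s;
  }
  return List::create(_["rows_a"] = out_a, _["rows_b"] = out_b,
                      _["score"] = F(ca, cb));
}

// Maximum-cardinality chain of anchors, strictly increasing in both the
// reference and query coordinate. Input must be sorted by (ref, query).
// Ties broken toward the leftmost (smallest-index) predecessor/endpoint.
// Returns 1-based indices of the chosen chain.
// [[Rcpp::export]]
IntegerVector chain_anchors_cpp(IntegerVector ref_pos, IntegerVector q_pos) {
  const int n = ref_pos.size();
  if (n == 0) return IntegerVector(0);
  std::vector<int> best(n, 1), pred(n, -1);
  int max_len = 1, max_at = 0;
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < i; ++j) {
      if (ref_pos[j] < ref_pos[i] && q_pos[j] < q_pos[i] &&
          best[j] + 1 > best[i]) {
        best[i] = best[j] + 1; pred[i] = j;
      }
    }
    if (best[i] > max_len) { max_len = best[i]; max_at = i; }
  }
  std::vector<int> chain;
  for (int i = max_at; i >= 0; i = pred[i]) {
    chain.push_back(i + 1);
    if (pred[i] < 0) break;
  }
  std::reverse(chain.begin(), chain.end());
  return wrap(chain);
}
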
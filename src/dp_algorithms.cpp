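#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Base-pair maximization over a DNA string with a minimum hairpin loop.
// Pairing is Watson-Crick (A-T, C-G), optionally G-T wobble. Traceback is
// deterministic: at every subinterval the 5'-most base is paired whenever an
// optimal structure allows it, with the smallest admissible partner.

static inline bool can_pair(char a, char b, bool wobble) {
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return true;
  if ((a == 'C' && b == 'G') || (a == 'G' && b == 'C')) return true;
  if (wobble && ((a == 'G' && b == 'T') || (a == 'T' && b == 'G'))) return true;
  return false;
}

// [[Rcpp::export(name = ".nussinov_fold")]]
std::string nussinov_fold(std::string seq, int min_loop, bool wobble) {
  int n = seq.size();
  std::string db(n, '.');
  if (n == 0) return db;
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k], wobble)) continue;
        int inner = (k - i - 1 > 0) ? M[i + 1][k - 1] : 0;
        int right = (k + 1 <= j) ? M[k + 1][j] : 0;
        int cand = inner + right + 1;
        if (cand > best) best = cand;
      }
      M[i][j] = best;
    }
  }
  // iterative traceback over a stack of intervals
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    int target = M[i][j];
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(seq[i], seq[k], wobble)) continue;
      int inner = (k - i - 1 > 0) ? M[i + 1][k - 1] : 0;
      int right = (k + 1 <= j) ? M[k + 1][j] : 0;
      if (inner + right + 1 == target) {
        db[i] = '(';
        db[k] = ')';
        if (k - i - 1 > 0) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k + 1 <= j) stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break; // smallest admissible partner
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }
  return db;
}

// Profile-profile global alignment by dynamic programming. Profiles are
// 4 x L frequency matrices over A,C,G,T; residual column mass (gaps) scores
// zero against everything. Terminal gaps are free when end_free is TRUE.
// Returns the move path 5'->3' (1 = diagonal, 2 = column from A only,
// 3 = column from B only) plus the optimal score. Ties prefer diagonal,
// then consuming A, so the traceback is deterministic.

// [[Rcpp::export(name = ".profile_align")]]
List profile_align(NumericMatrix A, NumericMatrix B, double match,
                   double mismatch, double gap, bool end_free) {
  int la = A.ncol(), lb = B.ncol();
  NumericMatrix S(la + 1, lb + 1);
  IntegerMatrix T(la + 1, lb + 1);
  double NEG = -1e18;
  for (int i = 1; i <= la; ++i) {
    S(i, 0) = end_free ? 0.0 : i * gap;
    T(i, 0) = 2;
  }
  for (int j = 1; j <= lb; ++j) {
    S(0, j) = end_free ? 0.0 : j * gap;
    T(0, j) = 3;
  }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double col = 0.0;
      for (int x = 0; x < 4; ++x)
        for (int y = 0; y < 4; ++y)
          col += A(x, i - 1) * B(y, j - 1) * (x == y ? match : mismatch);
      bool a_end = (i == la), b_end = (j == lb);
      double gap_up = (end_free && b_end) ? 0.0 : gap;   // consume A, gap in B
      double gap_left = (end_free && a_end) ? 0.0 : gap; // consume B, gap in A
      double d = S(i - 1, j - 1) + col;
      double u = S(i - 1, j) + gap_up;
      double l = S(i, j - 1) + gap_left;
      double best = NEG;
      int mv = 1;
      if (d >= best) { best = d; mv = 1; }
      if (u > best) { best = u; mv = 2; }
      if (l > best) { best = l; mv = 3; }
      S(i, j) = best;
      T(i, j) = mv;
    }
  }
  std::vector<int> path;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    int mv;
    if (i == 0) mv = 3;
    else if (j == 0) mv = 2;
    else mv = T(i, j);
    path.push_back(mv);
    if (mv == 1) { --i; --j; }
    else if (mv == 2) { --i; }
    else { --j; }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = S(la, lb), _["path"] = wrap(path));
}
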
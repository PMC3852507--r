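// Ordered tree edit distance (Zhang & Shasha) and Nussinov base-pair
// maximization. Both are small dense dynamic programs; C++ keeps the
// all-pairs structure comparisons and the synthetic-hairpin folding fast.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Zhang-Shasha. Trees arrive as postorder label vectors (integer codes) and
// lml[i] = postorder index (1-based) of the leftmost leaf descendant of node
// i. Unit costs: insert = delete = 1, relabel = 1 iff labels differ.
// ---------------------------------------------------------------------------

static std::vector<int> keyroots(const IntegerVector& lml) {
  int n = lml.size();
  std::vector<int> kr;
  for (int i = 0; i < n; ++i) {
    bool is_kr = true;
    for (int j = i + 1; j < n; ++j) {
      if (lml[j] == lml[i]) { is_kr = false; break; }
    }
    if (is_kr) kr.push_back(i + 1); // 1-based
  }
  return kr;
}

// [[Rcpp::export]]
double ted_cpp(IntegerVector lab1, IntegerVector lml1,
               IntegerVector lab2, IntegerVector lml2) {
  int n1 = lab1.size(), n2 = lab2.size();
  if (n1 == 0) return n2;
  if (n2 == 0) return n1;
  std::vector<int> kr1 = keyroots(lml1), kr2 = keyroots(lml2);
  std::vector<std::vector<double>> td(n1 + 1, std::vector<double>(n2 + 1, 0.0));
  std::vector<std::vector<double>> fd(n1 + 2, std::vector<double>(n2 + 2, 0.0));

  for (int ki : kr1) {
    for (int kj : kr2) {
      int li = lml1[ki - 1], lj = lml2[kj - 1];
      // forest distance over subforests l(ki)..i vs l(kj)..j
      fd[li - 1][lj - 1] = 0.0;
      for (int di = li; di <= ki; ++di) fd[di][lj - 1] = fd[di - 1][lj - 1] + 1.0;
      for (int dj = lj; dj <= kj; ++dj) fd[li - 1][dj] = fd[li - 1][dj - 1] + 1.0;
      for (int di = li; di <= ki; ++di) {
        for (int dj = lj; dj <= kj; ++dj) {
          if (lml1[di - 1] == li && lml2[dj - 1] == lj) {
            double rel = (lab1[di - 1] == lab2[dj - 1]) ? 0.0 : 1.0;
            fd[di][dj] = std::min({fd[di - 1][dj] + 1.0,
                                   fd[di][dj - 1] + 1.0,
                                   fd[di - 1][dj - 1] + rel});
            td[di][dj] = fd[di][dj];
          } else {
            fd[di][dj] = std::min({fd[di - 1][dj] + 1.0,
                                   fd[di][dj - 1] + 1.0,
                                   fd[lml1[di - 1] - 1][lml2[dj - 1] - 1] + td[di][dj]});
          }
        }
      }
    }
  }
  return td[n1][n2];
}

// ---------------------------------------------------------------------------
// Nussinov base-pair maximization with hairpin-loop constraint. Watson-Crick
// plus GU wobble. Deterministic traceback: at each interval prefer pairing
// position i (with the leftmost optimal partner) over leaving it unpaired.
// ---------------------------------------------------------------------------

static bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// [[Rcpp::export]]
std::string nussinov_cpp(std::string seq, int min_loop) {
  int n = seq.size();
  std::string out(n, '.');
  if (n == 0) return out;
  std::vector<std::vector<int>> M(n, std::vector<int>(n, 0));
  // M[i][j]: max pairs in seq[i..j], 0-based inclusive
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0;
        int right = (k + 1 <= j) ? M[k + 1][j] : 0;
        best = std::max(best, 1 + inner + right);
      }
      M[i][j] = best;
    }
  }
  // traceback with explicit stack of intervals
  std::vector<std::pair<int, int>> stack;
  stack.push_back({0, n - 1});
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    int target = M[i][j];
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(seq[i], seq[k])) continue;
      int inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0;
      int right = (k + 1 <= j) ? M[k + 1][j] : 0;
      if (1 + inner + right == target) {
        out[i] = '(';
        out[k] = ')';
        if (k - 1 > i + 1) stack.push_back({i + 1, k - 1});
        if (k + 1 < j) stack.push_back({k + 1, j});
        paired = true;
        break; // leftmost optimal partner
      }
    }
    if (!paired) stack.push_back({i + 1, j});
  }
  return out;
}
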
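#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Weighted base-pair maximization (Nussinov-style) with a minimum hairpin
// loop of 3 nt. Bases are encoded 0=A, 1=C, 2=G, 3=U. Positions flocked in
// `blocked` (e.g. a detected G-quadruplex span) are excluded from pairing.
// Pair weights approximate thermodynamic stability ordering: GC > AU > GU.

static const int MIN_LOOP = 3;

static inline int pair_w(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3; // GC
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2; // AU
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1; // GU
  return 0;
}

static void traceback(int i, int j,
                      const std::vector<std::vector<int> > &W,
                      const std::vector<int> &s,
                      const std::vector<bool> &blk,
                      std::vector<int> &pt) {
  while (i < j) {
    if (W[i][j] == W[i + 1][j]) { ++i; continue; }
    bool done = false;
    for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
      if (blk[i] || blk[k]) continue;
      int w = pair_w(s[i], s[k]);
      if (w == 0) continue;
      int inner = (k - i - 1 > MIN_LOOP) ? W[i + 1][k - 1] : 0;
      int outer = (k < j) ? W[k + 1][j] : 0;
      if (W[i][j] == w + inner + outer) {
        pt[i] = k + 1;  // 1-based
        pt[k] = i + 1;
        if (k - i - 1 > MIN_LOOP) traceback(i + 1, k - 1, W, s, blk, pt);
        i = k + 1;
        done = true;
        break;
      }
    }
    if (!done) ++i;  // defensive; should not happen
  }
}

// [[Rcpp::export(name = ".fold_cpp")]]
IntegerVector fold_cpp(IntegerVector seq_code, LogicalVector blocked) {
  int n = seq_code.size();
  IntegerVector out(n, 0);
  if (n < MIN_LOOP + 2) return out;
  std::vector<int> s(n);
  std::vector<bool> blk(n);
  for (int i = 0; i < n; ++i) { s[i] = seq_code[i]; blk[i] = blocked[i]; }

  std::vector<std::vector<int> > W(n, std::vector<int>(n, 0));
  for (int len = MIN_LOOP + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = W[i + 1][j];
      for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
        if (blk[i] || blk[k]) continue;
        int w = pair_w(s[i], s[k]);
        if (w == 0) continue;
        int inner = (k - i - 1 > MIN_LOOP) ? W[i + 1][k - 1] : 0;
        int outer = (k < j) ? W[k + 1][j] : 0;
        if (w + inner + outer > best) best = w + inner + outer;
      }
      W[i][j] = best;
    }
  }

  std::vector<int> pt(n, 0);
  traceback(0, n - 1, W, s, blk, pt);

  // drop helices shorter than MIN_HELIX stacked pairs (short stacks from
  // pure pair maximization are not stable structure); repeat until stable
  const int MIN_HELIX = 3;
  bool changed = true;
  while (changed) {
    changed = false;
    int i = 0;
    while (i < n) {
      int j1 = pt[i];
      if (j1 == 0 || j1 - 1 <= i) { ++i; continue; }
      int len = 1;
      while (i + len < n && pt[i + len] == j1 - len) ++len;
      if (len < MIN_HELIX) {
        for (int q = 0; q < len; ++q) { pt[pt[i + q] - 1] = 0; pt[i + q] = 0; }
        changed = true;
      }
      i += len;
    }
  }
  for (int i = 0; i < n; ++i) out[i] = pt[i];
  return out;
}
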
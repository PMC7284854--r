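// Base-pair maximization (Nussinov recursion) for short RNA sequences,
// plus two independent oracles used by the test suite: a memo-free
// exhaustive enumeration and an alternatively formulated DP.
//
// Pairing rules: Watson-Crick (A-U, C-G) plus G-U wobble; T is read as U.
// Loops must span at least min_loop unpaired bases (j - i > min_loop).
// Tie-break among maximal-pair structures: larger sum of paired indices
// (pushes the paired region 3'), resolved deterministically in traceback.

#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static inline bool can_pair(char a, char b) {
  if (a == 'T') a = 'U';
  if (b == 'T') b = 'U';
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'C' && b == 'G') || (a == 'G' && b == 'C') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

struct DP {
  int n;
  std::vector<int> P;   // max pairs on [i, j]
  std::vector<long long> S; // max index-sum among max-pair structures
  int idx(int i, int j) const { return i * n + j; }
};

static void fill_dp(const std::string& s, int min_loop, DP& dp) {
  int n = (int)s.size();
  dp.n = n;
  dp.P.assign((size_t)n * n, 0);
  dp.S.assign((size_t)n * n, 0);
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      // option: i unpaired
      int bp = dp.P[dp.idx(i + 1, j)];
      long long bs = dp.S[dp.idx(i + 1, j)];
      // option: i pairs with k
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(s[i], s[k])) continue;
        int p = 1;
        long long ss = i + k;
        if (k - i - 1 > min_loop) {
          p += dp.P[dp.idx(i + 1, k - 1)];
          ss += dp.S[dp.idx(i + 1, k - 1)];
        }
        if (k + 1 <= j) {
          p += dp.P[dp.idx(k + 1, j)];
          ss += dp.S[dp.idx(k + 1, j)];
        }
        if (p > bp || (p == bp && ss > bs)) { bp = p; bs = ss; }
      }
      dp.P[dp.idx(i, j)] = bp;
      dp.S[dp.idx(i, j)] = bs;
    }
  }
}

static void traceback(const std::string& s, int min_loop, const DP& dp,
                      int i, int j, std::vector<std::pair<int,int> >& out) {
  if (j - i < min_loop + 1) return;
  int bp = dp.P[dp.idx(i, j)];
  long long bs = dp.S[dp.idx(i, j)];
  // replicate the fill order: unpaired first, then k ascending; take the
  // first option achieving the stored optimum
  if (dp.P[dp.idx(i + 1, j)] == bp && dp.S[dp.idx(i + 1, j)] == bs) {
    traceback(s, min_loop, dp, i + 1, j, out);
    return;
  }
  for (int k = i + min_loop + 1; k <= j; ++k) {
    if (!can_pair(s[i], s[k])) continue;
    int p = 1;
    long long ss = i + k;
    if (k - i - 1 > min_loop) {
      p += dp.P[dp.idx(i + 1, k - 1)];
      ss += dp.S[dp.idx(i + 1, k - 1)];
    }
    if (k + 1 <= j) {
      p += dp.P[dp.idx(k + 1, j)];
      ss += dp.S[dp.idx(k + 1, j)];
    }
    if (p == bp && ss == bs) {
      out.push_back(std::make_pair(i, k));
      if (k - i - 1 > min_loop) traceback(s, min_loop, dp, i + 1, k - 1, out);
      if (k + 1 <= j) traceback(s, min_loop, dp, k + 1, j, out);
      return;
    }
  }
  Rcpp::stop("traceback failed"); // unreachable
}

// [[Rcpp::export]]
IntegerMatrix nussinov_pairs_cpp(std::string seq, int min_loop = 3) {
  int n = (int)seq.size();
  std::vector<std::pair<int,int> > pr;
  if (n > min_loop + 1) {
    DP dp;
    fill_dp(seq, min_loop, dp);
    traceback(seq, min_loop, dp, 0, n - 1, pr);
  }
  IntegerMatrix out((int)pr.size(), 2);
  for (size_t r = 0; r < pr.size(); ++r) {
    out(r, 0) = pr[r].first;
    out(r, 1) = pr[r].second;
  }
  return out;
}

// [[Rcpp::export]]
int nussinov_max_pairs_cpp(std::string seq, int min_loop = 3) {
  int n = (int)seq.size();
  if (n <= min_loop + 1) return 0;
  DP dp;
  fill_dp(seq, min_loop, dp);
  return dp.P[dp.idx(0, n - 1)];
}

// Memo-free exhaustive recursion: enumerates every nested structure.
static int brute_rec(const std::string& s, int min_loop, int i, int j) {
  if (j - i < min_loop + 1) return 0;
  int best = brute_rec(s, min_loop, i + 1, j);
  for (int k = i + min_loop + 1; k <= j; ++k) {
    if (!can_pair(s[i], s[k])) continue;
    int v = 1 + brute_rec(s, min_loop, i + 1, k - 1) +
            brute_rec(s, min_loop, k + 1, j);
    if (v > best) best = v;
  }
  return best;
}

// [[Rcpp::export]]
int brute_max_pairs_cpp(std::string seq, int min_loop = 3) {
  if (seq.size() < 2) return 0;
  return brute_rec(seq, min_loop, 0, (int)seq.size() - 1);
}

// Alternative DP, recursing on the right end instead of the left.
// [[Rcpp::export]]
int alt_max_pairs_cpp(std::string seq, int min_loop = 3) {
  int n = (int)seq.size();
  if (n <= min_loop + 1) return 0;
  std::vector<int> M((size_t)n * n, 0);
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i * n + (j - 1)]; // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!can_pair(seq[k], seq[j])) continue;
        int v = 1;
        if (k - 1 >= i) v += M[i * n + (k - 1)];
        if (j - 1 >= k + 1) v += M[(k + 1) * n + (j - 1)];
        if (v > best) best = v;
      }
      M[i * n + j] = best;
    }
  }
  return M[0 * n + (n - 1)];
}

// Full sweep: every sequence over {A,C,G,U} of each length 1..max_len,
// comparing the Nussinov DP against both oracles inside C++.
// Returns c(n_sequences_checked, n_disagreements).
// [[Rcpp::export]]
IntegerVector nussinov_sweep_cpp(int max_len, int min_loop = 3) {
  const char bases[4] = {'A', 'C', 'G', 'U'};
  long long checked = 0, bad = 0;
  for (int len = 1; len <= max_len; ++len) {
    std::vector<int> digits(len, 0);
    std::string s(len, 'A');
    bool done = false;
    while (!done) {
      for (int t = 0; t < len; ++t) s[t] = bases[digits[t]];
      int a = nussinov_max_pairs_cpp(s, min_loop);
      int b = brute_rec(s, min_loop, 0, len - 1);
      int c = alt_max_pairs_cpp(s, min_loop);
      ++checked;
      if (a != b || a != c) ++bad;
      int pos = len - 1;
      while (pos >= 0) {
        if (++digits[pos] < 4) break;
        digits[pos] = 0;
        --pos;
      }
      if (pos < 0) done = true;
    }
  }
  return IntegerVector::create((int)checked, (int)bad);
}
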
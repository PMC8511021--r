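#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Optimal-string-alignment Damerau-Levenshtein: unit-cost insertions,
// deletions, substitutions and adjacent transpositions, with the
// restriction that no substring is edited more than once.
static int osa_core(const int* a, int na, const int* b, int nb) {
  if (na == 0) return nb;
  if (nb == 0) return na;
  std::vector<int> d((na + 1) * (nb + 1));
  const int w = nb + 1;
  for (int i = 0; i <= na; ++i) d[i * w] = i;
  for (int j = 0; j <= nb; ++j) d[j] = j;
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      const int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int v = std::min(std::min(d[(i - 1) * w + j] + 1,
                                d[i * w + (j - 1)] + 1),
                       d[(i - 1) * w + (j - 1)] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        v = std::min(v, d[(i - 2) * w + (j - 2)] + 1);
      d[i * w + j] = v;
    }
  }
  return d[na * w + nb];
}

// [[Rcpp::export(name = ".cpp_osa_distance")]]
int cpp_osa_distance(IntegerVector a, IntegerVector b) {
  return osa_core(INTEGER(a), a.size(), INTEGER(b), b.size());
}

// Shared-prefix DP over the 9-ary pattern trie: for one window w of
// length n, walk all patterns of length n (lexicographic order,
// optionally skipping adjacent repeats) and accumulate 1/(distance+1)
// into the per-pattern accumulator.  Row i of `rows` is the DP row for
// the current pattern prefix of length i; rows for shared prefixes are
// computed once, which saves a factor ~n over per-pattern DP.
struct TrieCtx {
  const int* w;        // current window, length n
  int n;
  bool excl;           // skip patterns with adjacent equal digits
  int* rows;           // (n+1) x (n+1), row-major
  int* pc;             // pattern chars along the current trie path
  double* acc;         // per-pattern accumulator
  R_xlen_t leaf;       // running leaf index within this window
};

static void trie_walk(TrieCtx& C, int depth) {
  const int W = C.n + 1;
  if (depth == C.n) {
    C.acc[C.leaf++] += 1.0 / (C.rows[depth * W + C.n] + 1.0);
    return;
  }
  for (int c = 1; c <= 9; ++c) {
    if (C.excl && depth > 0 && c == C.pc[depth - 1]) continue;
    C.pc[depth] = c;
    const int i = depth + 1;
    int* cur = C.rows + i * W;
    const int* prev = C.rows + (i - 1) * W;
    cur[0] = i;
    for (int j = 1; j <= C.n; ++j) {
      const int cost = (c == C.w[j - 1]) ? 0 : 1;
      int v = std::min(std::min(prev[j] + 1, cur[j - 1] + 1),
                       prev[j - 1] + cost);
      if (i > 1 && j > 1 && c == C.w[j - 2] && C.pc[depth - 1] == C.w[j - 1]) {
        // transposition: pattern chars at i-1 (= c) and i-2 match the
        // window chars crossed over
        const int* pp = C.rows + (i - 2) * W;
        v = std::min(v, pp[j - 2] + 1);
      }
      cur[j] = v;
    }
    trie_walk(C, depth + 1);
  }
}

// [[Rcpp::export(name = ".cpp_score_space")]]
NumericVector cpp_score_space(IntegerVector z, int n, bool exclude_repeats) {
  const int L = z.size();
  if (n < 1 || n > L) stop("pattern length out of range for this sequence");
  R_xlen_t P = exclude_repeats ? 9 : 9;
  for (int k = 1; k < n; ++k) P *= exclude_repeats ? 8 : 9;
  NumericVector out(P);
  std::vector<int> rows((n + 1) * (n + 1));
  std::vector<int> pc(n);
  const int W = n + 1;
  for (int j = 0; j <= n; ++j) rows[j] = j;  // row 0: empty pattern prefix
  TrieCtx C;
  C.n = n;
  C.excl = exclude_repeats;
  C.rows = rows.data();
  C.pc = pc.data();
  C.acc = REAL(out);
  const int* zp = INTEGER(z);
  for (int start = 0; start + n <= L; ++start) {
    C.w = zp + start;
    C.leaf = 0;
    trie_walk(C, 0);
  }
  (void)W;
  for (R_xlen_t i = 0; i < P; ++i) C.acc[i] /= L;
  return out;
}
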
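#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Any comparison involving 'N' counts as a mismatch (conservative for
// primer design), so N vs N is a mismatch too.
static inline bool is_mismatch(char a, char b) {
  return a != b || a == 'N';
}

// Minimum Hamming distance of one window against every ungapped offset of a
// nuclear sequence, forward strand of the window only. Early exit per offset
// once the running count reaches the best seen so far.
// [[Rcpp::export]]
int min_hamming_one_strand(std::string window, std::string nuclear) {
  const int W = window.size(), L = nuclear.size();
  if (L < W) stop("nuclear sequence shorter than the window");
  int best = W;
  for (int off = 0; off + W <= L; ++off) {
    int d = 0;
    for (int k = 0; k < W; ++k) {
      if (is_mismatch(window[k], nuclear[off + k])) {
        if (++d >= best) break;
      }
    }
    if (d < best) {
      best = d;
      if (best == 0) return 0;
    }
  }
  return best;
}

// Sliding-window mismatch minima along every diagonal of the (pattern x
// text) comparison grid. `pattern` is the circular mt sequence extended by
// window-1 bases so that window i (0-based start, i < n_windows) is
// pattern[i..i+W-1]. For each diagonal shift the W-wide running mismatch sum
// is updated in O(1), giving the full profile in O(|pattern| * |text|).
// Updates `best` (length n_windows) in place with the minimum over offsets.
static void profile_one_text(const std::string& pat, const std::string& txt,
                             int W, int n_windows, IntegerVector& best) {
  const int P = pat.size(), T = txt.size();
  // diagonal d: pat[i] aligned with txt[i + d], d in [-(P - W), T - W]
  for (int d = -(P - W); d + W <= T; ++d) {
    int i0 = d < 0 ? -d : 0;               // first pattern index on diagonal
    int i1 = std::min(P, T - d);           // one past last pattern index
    if (i1 - i0 < W) continue;
    int run = 0;
    for (int i = i0; i < i0 + W; ++i)
      run += is_mismatch(pat[i], txt[i + d]);
    if (i0 < n_windows && run < best[i0]) best[i0] = run;
    for (int i = i0 + 1; i + W <= i1; ++i) {
      run += is_mismatch(pat[i + W - 1], txt[i + W - 1 + d]);
      run -= is_mismatch(pat[i - 1], txt[i - 1 + d]);
      if (i < n_windows && run < best[i]) best[i] = run;
    }
  }
}

// Full per-window-start minimum Hamming profile of an (extended) pattern
// against a nuclear text and its reverse complement.
// [[Rcpp::export]]
IntegerVector hamming_profile_cpp(std::string pattern_ext, std::string nuclear,
                                  std::string nuclear_rc, int window,
                                  int n_windows) {
  if ((int) nuclear.size() < window)
    stop("nuclear sequence shorter than the window");
  IntegerVector best(n_windows, window);
  profile_one_text(pattern_ext, nuclear, window, n_windows, best);
  if (nuclear_rc.size() > 0)
    profile_one_text(pattern_ext, nuclear_rc, window, n_windows, best);
  return best;
}
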
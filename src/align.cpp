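#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with linear gap penalty.
// Returns the single maximal-scoring local alignment (first maximum on ties,
// scanning row-major) with 1-based inclusive coordinates in both sequences.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string a, std::string b,
              int match = 1, int mismatch = -2, int gap = -3) {
  const int n = a.size(), m = b.size();
  // traceback codes: 0 stop, 1 diag, 2 up (gap in b), 3 left (gap in a)
  std::vector<signed char> tb((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      int up = prev[j] + gap;
      int left = cur[j - 1] + gap;
      int s = sub; signed char t = 1;
      if (up > s)  { s = up;  t = 2; }
      if (left > s){ s = left; t = 3; }
      if (s <= 0)  { s = 0;   t = 0; }
      cur[j] = s;
      tb[(size_t)i * (m + 1) + j] = t;
      if (s > best) { best = s; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  if (best == 0)
    return List::create(_["score"] = 0, _["found"] = false);
  int i = bi, j = bj, matches = 0, mism = 0, gapcols = 0;
  int ei = bi, ej = bj;
  while (i > 0 && j > 0) {
    signed char t = tb[(size_t)i * (m + 1) + j];
    if (t == 0) break;
    if (t == 1) {
      if (a[i - 1] == b[j - 1]) ++matches; else ++mism;
      --i; --j;
    } else if (t == 2) { ++gapcols; --i; }
    else { ++gapcols; --j; }
  }
  return List::create(
    _["score"] = best, _["found"] = true,
    _["a_start"] = i + 1, _["a_end"] = ei,
    _["b_start"] = j + 1, _["b_end"] = ej,
    _["matches"] = matches, _["mismatches"] = mism,
    _["gapcols"] = gapcols,
    _["aligned_length"] = matches + mism + gapcols);
}

// Needleman-Wunsch global alignment statistics with linear gap penalty.
// A gap column counts once toward "gapcols" whatever its length context.
// [[Rcpp::export(name = ".nw_stats")]]
List nw_stats(std::string a, std::string b,
              int match = 1, int mismatch = -1, int gap = -2) {
  const int n = a.size(), m = b.size();
  std::vector<signed char> tb((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) { prev[j] = j * gap; tb[j] = 3; }
  tb[0] = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    tb[(size_t)i * (m + 1)] = 2;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      int up = prev[j] + gap;
      int left = cur[j - 1] + gap;
      int s = sub; signed char t = 1;
      if (up > s)  { s = up;  t = 2; }
      if (left > s){ s = left; t = 3; }
      cur[j] = s;
      tb[(size_t)i * (m + 1) + j] = t;
    }
    std::swap(prev, cur);
  }
  int i = n, j = m, matches = 0, mism = 0, gapcols = 0;
  while (i > 0 || j > 0) {
    signed char t = tb[(size_t)i * (m + 1) + j];
    if (t == 1) {
      if (a[i - 1] == b[j - 1]) ++matches; else ++mism;
      --i; --j;
    } else if (t == 2) { ++gapcols; --i; }
    else { ++gapcols; --j; }
  }
  int aln = matches + mism + gapcols;
  return List::create(
    _["score"] = prev[m], _["matches"] = matches,
    _["mismatches"] = mism, _["gapcols"] = gapcols,
    _["aligned_length"] = aln,
    _["identity"] = aln > 0 ? (double)matches / aln : NA_REAL);
}

// Minimum Hamming distance of `read` over all full-length placements in
// `ref`; returns 1-based offset of the first minimizing placement.
// [[Rcpp::export(name = ".best_offset_mismatch")]]
List best_offset_mismatch(std::string read, std::string ref) {
  const int lr = read.size(), ls = ref.size();
  if (lr == 0 || lr > ls)
    return List::create(_["found"] = false);
  int best = lr + 1, best_off = -1;
  for (int off = 0; off + lr <= ls; ++off) {
    int mm = 0;
    for (int i = 0; i < lr; ++i) {
      if (read[i] != ref[off + i]) { ++mm; if (mm >= best) break; }
    }
    if (mm < best) { best = mm; best_off = off; if (best == 0) break; }
  }
  return List::create(_["found"] = true,
                      _["offset"] = best_off + 1,
                      _["mismatches"] = best);
}

// Hamming distance at every full-length placement of `pat` in `subj`.
// [[Rcpp::export(name = ".sliding_mismatch")]]
IntegerVector sliding_mismatch(std::string pat, std::string subj) {
  const int lp = pat.size(), ls = subj.size();
  if (lp == 0 || lp > ls) return IntegerVector(0);
  IntegerVector out(ls - lp + 1);
  for (int off = 0; off + lp <= ls; ++off) {
    int mm = 0;
    for (int i = 0; i < lp; ++i) if (pat[i] != subj[off + i]) ++mm;
    out[off] = mm;
  }
  return out;
}

// Longest k >= min_ov with suffix(a, k) == prefix(b, k); 0 when none.
// [[Rcpp::export(name = ".longest_overlap")]]
int longest_overlap(std::string a, std::string b, int min_ov) {
  const int la = a.size(), lb = b.size();
  int kmax = std::min(la, lb);
  for (int k = kmax; k >= min_ov; --k) {
    bool ok = true;
    const int off = la - k;
    for (int i = 0; i < k; ++i)
      if (a[off + i] != b[i]) { ok = false; break; }
    if (ok) return k;
  }
  return 0;
}

// 1-based position of the first exact occurrence of b within a; 0 if none.
// [[Rcpp::export(name = ".find_contained")]]
int find_contained(std::string a, std::string b) {
  if (b.size() == 0 || b.size() > a.size()) return 0;
  size_t p = a.find(b);
  return p == std::string::npos ? 0 : (int)(p + 1);
}
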
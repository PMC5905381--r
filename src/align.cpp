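#include <Rcpp.h>
#include <climits>
#include <cstdint>
#include <algorithm>
#include <unordered_map>
#include <unordered_set>
using namespace Rcpp;

// Pairwise alignment primitives shared by every stage of the pipeline:
// a Gotoh affine-gap aligner with optional free end gaps on either sequence
// and an optional diagonal band, plus a unit-cost semi-global edit-distance
// row used for locating short motifs (barcodes, primers, adapters) in reads.

static const int NEG = INT_MIN / 4;

static inline int max3(int a, int b, int c, int *arg) {
  // deterministic preference M (0) > X (1) > Y (2) on ties
  int m = a; *arg = 0;
  if (b > m) { m = b; *arg = 1; }
  if (c > m) { m = c; *arg = 2; }
  return m;
}

// Affine-gap pairwise alignment (Gotoh) with traceback.
//
// free_q: overhanging (unaligned) query ends are not penalised.
// free_r: overhanging reference ends are not penalised.
// band >= 0 restricts cells to j - i in [min(0,m-n)-band, max(0,m-n)+band];
// band_hit reports whether the optimal path touched the band boundary so the
// caller can widen and retry. Gap of length L costs gap_open + L * gap_ext.
//
// Returns 1-based aligned intervals [qstart,qend], [rstart,rend], per-class
// column counts and the gapped aligned strings.
// centered = true places the band around diagonal band_center instead of
// the default corner-to-corner spread (used when a k-mer prescreen has
// already localised the overlap).
// [[Rcpp::export]]
List cpp_align(std::string q, std::string r, int match, int mismatch,
               int gap_open, int gap_ext, bool free_q, bool free_r, int band,
               bool centered = false, int band_center = 0) {
  const int n = (int)q.size(), m = (int)r.size();
  const long W = (long)(m + 1);
  std::vector<int> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  std::vector<signed char> pM((n + 1) * W, -1), pX((n + 1) * W, -1), pY((n + 1) * W, -1);
  int lo = 0, hi = 0;
  bool banded = band >= 0;
  if (banded) {
    if (centered) {
      lo = band_center - band;
      hi = band_center + band;
    } else {
      lo = std::min(0, m - n) - band;
      hi = std::max(0, m - n) + band;
    }
    if (lo <= -n && hi >= m) banded = false; // band covers everything
  }
  M[0] = 0;
  for (int i = 1; i <= n; ++i) {
    if (banded && (0 - i) < lo) break;
    X[i * W] = free_q ? 0 : -(gap_open + i * gap_ext);
  }
  for (int j = 1; j <= m; ++j) {
    if (banded && j > hi) break;
    Y[j] = free_r ? 0 : -(gap_open + j * gap_ext);
  }
  const int go = gap_open + gap_ext, ge = gap_ext;
  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (banded) {
      jlo = std::max(1, i + lo);
      jhi = std::min(m, i + hi);
      if (jlo > jhi) continue;
    }
    for (int j = jlo; j <= jhi; ++j) {
      long c = (long)i * W + j, d = (long)(i - 1) * W + (j - 1),
           u = (long)(i - 1) * W + j, l = (long)i * W + (j - 1);
      int arg;
      int s = (q[i - 1] == r[j - 1]) ? match : mismatch;
      int best = max3(M[d], X[d], Y[d], &arg);
      if (best > NEG / 2) { M[c] = best + s; pM[c] = (signed char)arg; }
      best = max3(M[u] - go, X[u] - ge, Y[u] - go, &arg);
      if (best > NEG / 2) { X[c] = best; pX[c] = (signed char)arg; }
      best = max3(M[l] - go, X[l] - go, Y[l] - ge, &arg);
      if (best > NEG / 2) { Y[c] = best; pY[c] = (signed char)arg; }
    }
  }
  // termination: corner always; last column if free_q; last row if free_r
  int bi = n, bj = m, bstate = 0;
  int bscore = NEG;
  {
    long c = (long)n * W + m;
    int arg;
    bscore = max3(M[c], X[c], Y[c], &arg);
    bstate = arg;
  }
  if (free_q) {
    for (int i = 0; i <= n; ++i) {
      long c = (long)i * W + m;
      int arg;
      int sc = max3(M[c], X[c], Y[c], &arg);
      if (sc > bscore) { bscore = sc; bi = i; bj = m; bstate = arg; }
    }
  }
  if (free_r) {
    for (int j = 0; j <= m; ++j) {
      long c = (long)n * W + j;
      int arg;
      int sc = max3(M[c], X[c], Y[c], &arg);
      if (sc > bscore) { bscore = sc; bi = n; bj = j; bstate = arg; }
    }
  }
  // traceback
  std::string aq, ar;
  aq.reserve(n + m); ar.reserve(n + m);
  int i = bi, j = bj, state = bstate;
  int matches = 0, mismatches = 0, ins = 0, del = 0;
  bool hit = false;
  while (i > 0 || j > 0) {
    if (banded && i > 0 && j > 0 && (j - i == lo || j - i == hi)) hit = true;
    if (state == 0) {
      if (i == 0 || j == 0) break;
      long c = (long)i * W + j;
      aq.push_back(q[i - 1]); ar.push_back(r[j - 1]);
      if (q[i - 1] == r[j - 1]) ++matches; else ++mismatches;
      state = pM[c]; --i; --j;
    } else if (state == 1) { // gap in reference, query base consumed
      if (i == 0) break;
      if (j == 0 && free_q) break;
      long c = (long)i * W + j;
      aq.push_back(q[i - 1]); ar.push_back('-');
      ++ins;
      state = (j == 0) ? 1 : pX[c]; --i;
    } else { // gap in query, reference base consumed
      if (j == 0) break;
      if (i == 0 && free_r) break;
      long c = (long)i * W + j;
      aq.push_back('-'); ar.push_back(r[j - 1]);
      ++del;
      state = (i == 0) ? 2 : pY[c]; --j;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(ar.begin(), ar.end());
  return List::create(
    _["score"] = bscore,
    _["qstart"] = i + 1, _["qend"] = bi,
    _["rstart"] = j + 1, _["rend"] = bj,
    _["matches"] = matches, _["mismatches"] = mismatches,
    _["insertions"] = ins, _["deletions"] = del,
    _["aln_q"] = aq, _["aln_r"] = ar,
    _["band_hit"] = hit);
}

// Shared k-mer statistics between two sequences, for cheap overlap
// prescreening before alignment. Returns, for b's forward and
// reverse-complement strands, the number of distinct k-mers of b present in
// a, and the median alignment diagonal (position in a minus position in the
// oriented b) of those shared k-mers -- a band centre estimate for a
// subsequent banded alignment. k <= 15.
// [[Rcpp::export]]
IntegerVector cpp_kmer_share(std::string a, std::string b, int k) {
  auto code = [](char c) -> int {
    switch (c) { case 'A': return 0; case 'C': return 1;
                 case 'G': return 2; case 'T': return 3; default: return -1; }
  };
  std::unordered_map<uint64_t, int> pos_a; // k-mer -> first start in a
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  uint64_t h = 0; int run = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int c = code(a[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= k) pos_a.emplace(h, (int)i - k + 1);
  }
  uint64_t hf = 0, hr = 0; int runb = 0;
  std::unordered_set<uint64_t> seen_f, seen_r;
  std::vector<int> diag_f, diag_r;
  const int shift = 2 * (k - 1);
  const int nb = (int)b.size();
  for (int i = 0; i < nb; ++i) {
    int c = code(b[i]);
    if (c < 0) { runb = 0; hf = 0; hr = 0; continue; }
    hf = ((hf << 2) | (uint64_t)c) & mask;
    hr = (hr >> 2) | ((uint64_t)(3 - c) << shift); // reverse complement
    if (++runb >= k) {
      auto it = pos_a.find(hf);
      if (it != pos_a.end() && seen_f.insert(hf).second) {
        diag_f.push_back(it->second - (i - k + 1));
      }
      it = pos_a.find(hr);
      if (it != pos_a.end() && seen_r.insert(hr).second) {
        diag_r.push_back(it->second - (nb - 1 - i));
      }
    }
  }
  auto median = [](std::vector<int> &v) -> int {
    if (v.empty()) return 0;
    size_t m = v.size() / 2;
    std::nth_element(v.begin(), v.begin() + m, v.end());
    return v[m];
  };
  return IntegerVector::create((int)diag_f.size(), (int)diag_r.size(),
                               median(diag_f), median(diag_r));
}

// Semi-global unit-cost edit distance of a short pattern against a text:
// the pattern is aligned end to end, the text has free ends. Returns, for
// every end position j in the text (0..m), the minimal number of edits of a
// hit ending at j and the 0-based start position of that hit, so the caller
// can threshold, pick minima, and form coverage intervals.
// [[Rcpp::export]]
List cpp_edit_row(std::string p, std::string t) {
  const int n = (int)p.size(), m = (int)t.size();
  std::vector<int> prev(m + 1), cur(m + 1), sprev(m + 1), scur(m + 1);
  for (int j = 0; j <= m; ++j) { prev[j] = 0; sprev[j] = j; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i; scur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      int diag = prev[j - 1] + (p[i - 1] == t[j - 1] ? 0 : 1);
      int up = prev[j] + 1;   // gap in text (pattern base unmatched)
      int left = cur[j - 1] + 1; // gap in pattern (text base skipped)
      int best = diag, src = 0;
      if (up < best) { best = up; src = 1; }
      if (left < best) { best = left; src = 2; }
      cur[j] = best;
      scur[j] = (src == 0) ? sprev[j - 1] : (src == 1 ? sprev[j] : scur[j - 1]);
    }
    std::swap(prev, cur);
    std::swap(sprev, scur);
  }
  IntegerVector dist(m + 1), start(m + 1);
  for (int j = 0; j <= m; ++j) { dist[j] = prev[j]; start[j] = sprev[j]; }
  return List::create(_["dist"] = dist, _["start"] = start);
}
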
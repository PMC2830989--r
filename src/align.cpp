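#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// residue codes: A=0 C=1 G=2 T=3, anything else (incl. N) = 4.
// Code 4 never matches, not even itself.
static inline int rescode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static std::vector<int> encode(const std::string &s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = rescode(s[i]);
  return v;
}

// Smith-Waterman/Gotoh scan over target[t_from..t_to] (0-based, inclusive),
// score-only, linear memory. Masked target columns are hard barriers (all
// states reset to 0). Returns (best_score, best_t_end, best_q_end), ends
// 0-based within the full target; ties resolved to the smallest target end,
// then smallest query end.
// [[Rcpp::export]]
NumericVector cpp_best_local(std::string query, std::string target,
                             int t_from, int t_to, LogicalVector mask,
                             double match, double mismatch,
                             double gap_open, double gap_extend) {
  std::vector<int> q = encode(query);
  const int m = (int)q.size();
  const double open_ext = gap_open + gap_extend;  // cost of first gap base
  std::vector<double> H(m + 1, 0.0), E(m + 1, 0.0);
  // H[i]: best ending at (i, j) as we sweep; E: gap consuming target
  double best = 0.0; int bj = -1, bi = -1;
  const int *mp = LOGICAL(mask);
  const int *qv = q.data();
  double *Hv = H.data(), *Ev = E.data();
  for (int j = t_from; j <= t_to; ++j) {
    if (mp[j]) {
      std::fill(H.begin(), H.end(), 0.0);
      std::fill(E.begin(), E.end(), 0.0);
      continue;
    }
    const int tc = rescode(target[j]);
    double diag = 0.0;   // H[i-1] from previous column
    double F = 0.0;      // gap consuming query, within this column
    for (int i = 1; i <= m; ++i) {
      const double s = (qv[i - 1] == tc && qv[i - 1] != 4) ? match : mismatch;
      const double Hprev = Hv[i];  // H(i, j-1), before overwrite
      double e = Ev[i] - gap_extend;
      double eo = Hprev - open_ext;
      if (eo > e) e = eo;
      Ev[i] = e;
      double f = F - gap_extend;
      double fo = Hv[i - 1] - open_ext;  // H(i-1, j) already updated
      if (fo > f) f = fo;
      F = f;
      double h = diag + s;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0.0) h = 0.0;
      diag = Hprev;
      Hv[i] = h;
      if (h > best) { best = h; bj = j; bi = i; }
    }
  }
  return NumericVector::create(best, (double)bj, (double)bi);
}

// Full DP with traceback over target[t_from..t_to]; returns the best local
// alignment in the region (respecting masked columns as barriers):
// score, q_start, q_end (0-based), t_start, t_end (0-based, absolute),
// matches, columns (aligned columns including gap columns).
// [[Rcpp::export]]
NumericVector cpp_align_region(std::string query, std::string target,
                               int t_from, int t_to, LogicalVector mask,
                               double match, double mismatch,
                               double gap_open, double gap_extend) {
  std::vector<int> q = encode(query);
  const int m = (int)q.size();
  const int n = t_to - t_from + 1;
  const double open_ext = gap_open + gap_extend;
  // traceback byte per cell: bits 0-1 H origin (0 stop, 1 diag, 2 E, 3 F);
  // bit 2: E extended (vs opened); bit 3: F extended
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  std::vector<double> H(m + 1, 0.0), E(m + 1, 0.0);
  double best = 0.0; int bi = -1, bj = -1;
  const int *mp = LOGICAL(mask);
  const int *qv = q.data();
  double *Hv = H.data(), *Ev = E.data();
  for (int j = 1; j <= n; ++j) {
    const int tpos = t_from + j - 1;
    uint8_t *tbc = &tb[(size_t)j * (m + 1)];
    if (mp[tpos]) {
      std::fill(H.begin(), H.end(), 0.0);
      std::fill(E.begin(), E.end(), 0.0);
      continue;
    }
    const int tc = rescode(target[tpos]);
    double diag = 0.0, F = 0.0;
    for (int i = 1; i <= m; ++i) {
      const double s = (qv[i - 1] == tc && qv[i - 1] != 4) ? match : mismatch;
      const double Hprev = Hv[i];
      uint8_t cell = 0;
      double e = Ev[i] - gap_extend;
      double eo = Hprev - open_ext;
      if (e > eo) { cell |= 4; } else { e = eo; }
      Ev[i] = e;
      double f = F - gap_extend;
      double fo = Hv[i - 1] - open_ext;
      if (f > fo) { cell |= 8; } else { f = fo; }
      F = f;
      double h = diag + s; uint8_t org = 1;
      if (e > h) { h = e; org = 2; }
      if (f > h) { h = f; org = 3; }
      if (h <= 0.0) { h = 0.0; org = 0; }
      cell |= org;
      tbc[i] = cell;
      diag = Hprev;
      Hv[i] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (bi < 0) {
    return NumericVector::create(0, -1, -1, -1, -1, 0, 0);
  }
  // traceback
  int i = bi, j = bj, state = 0;  // 0 = in H
  int matches = 0, columns = 0;
  int qe = bi - 1, te = t_from + bj - 1;
  int qs = qe, ts = te;
  while (true) {
    uint8_t cell = tb[(size_t)j * (m + 1) + i];
    if (state == 0) {
      uint8_t org = cell & 3;
      if (org == 0) break;
      if (org == 1) {
        ++columns;
        const int tc = rescode(target[t_from + j - 1]);
        if (q[i - 1] == tc && q[i - 1] != 4) ++matches;
        qs = i - 1; ts = t_from + j - 1;
        --i; --j;
      } else if (org == 2) {
        state = 2;
      } else {
        state = 3;
      }
    } else if (state == 2) {  // E: gap consuming target
      ++columns;
      ts = t_from + j - 1;
      bool ext = (cell & 4) != 0;
      --j;
      if (!ext) state = 0;
    } else {  // F: gap consuming query
      ++columns;
      qs = i - 1;
      bool ext = (cell & 8) != 0;
      --i;
      if (!ext) state = 0;
    }
    if (i == 0 || j == 0) {
      if (state == 0) break;
      // gap runs cannot start at the border in a positive-scoring local
      // alignment; defensive stop
      break;
    }
  }
  return NumericVector::create(best, (double)qs, (double)qe, (double)ts,
                               (double)te, (double)matches, (double)columns);
}

// Candidate target windows sharing >= 1 exact k-mer with the query
// (case-insensitive; k-mers containing non-ACGT are skipped). Windows are
// padded by `pad` on each side and merged while overlapping/adjacent.
// Returns an integer matrix of 0-based inclusive [start, end] rows.
// [[Rcpp::export]]
IntegerMatrix cpp_kmer_windows(std::string query, std::string target,
                               int k, int pad) {
  std::vector<int> q = encode(query), t = encode(target);
  const int m = (int)q.size(), n = (int)t.size();
  if (m < k || n < k) return IntegerMatrix(0, 2);
  std::unordered_set<uint64_t> qk;
  uint64_t key = 0, bad = 0;
  const uint64_t msk = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (int i = 0; i < m; ++i) {
    key = ((key << 2) | (uint64_t)(q[i] & 3)) & msk;
    bad = ((bad << 1) | (q[i] == 4 ? 1ULL : 0ULL)) & ((1ULL << k) - 1);
    if (i >= k - 1 && bad == 0) qk.insert(key);
  }
  std::vector<int> hitpos;
  key = 0; bad = 0;
  for (int j = 0; j < n; ++j) {
    key = ((key << 2) | (uint64_t)(t[j] & 3)) & msk;
    bad = ((bad << 1) | (t[j] == 4 ? 1ULL : 0ULL)) & ((1ULL << k) - 1);
    if (j >= k - 1 && bad == 0 && qk.count(key)) {
      hitpos.push_back(j - k + 1);
    }
  }
  if (hitpos.empty()) return IntegerMatrix(0, 2);
  std::vector<std::pair<int,int>> win;
  int cs = hitpos[0] - pad, ce = hitpos[0] + k - 1 + pad;
  for (size_t a = 1; a < hitpos.size(); ++a) {
    int s = hitpos[a] - pad, e = hitpos[a] + k - 1 + pad;
    if (s <= ce + 1) {
      if (e > ce) ce = e;
    } else {
      win.push_back({std::max(0, cs), std::min(n - 1, ce)});
      cs = s; ce = e;
    }
  }
  win.push_back({std::max(0, cs), std::min(n - 1, ce)});
  IntegerMatrix out((int)win.size(), 2);
  for (size_t a = 0; a < win.size(); ++a) {
    out(a, 0) = win[a].first;
    out(a, 1) = win[a].second;
  }
  return out;
}
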
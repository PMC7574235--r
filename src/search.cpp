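#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Local protein alignment of a query against one translated reading frame,
// BLAST-style: k-mer seed detection (exact or neighborhood, i.e. any
// diagonal word scoring at least seed_thresh), then gapped extension by an
// exact affine-gap Smith-Waterman restricted to the stop-free segment that
// holds the seeds.  Gap of length L costs open + L*ext (both negative).
// In-frame stops bound the segments, so no reported hit ever crosses one.

static const double NEG = -1e18;

struct SwHit {
  int t_start, t_end, q_start, q_end;
  double score;
  std::string aq, at;
};

static inline int idx_of(const std::string &alpha, int table[256]) {
  for (int i = 0; i < 256; ++i) table[i] = -1;
  for (size_t i = 0; i < alpha.size(); ++i)
    table[(unsigned char)alpha[i]] = (int)i;
  return 0;
}

// Smith-Waterman with traceback over target window [t0,t1) of `tg`,
// skipping masked target columns; returns best local alignment.
static bool sw_best(const std::string &q, const std::string &tg,
                    int t0, int t1,
                    const std::vector<double> &mat, int A, const int *ai,
                    double go, double ge,
                    const std::vector<char> &maskv,
                    SwHit &out) {
  int Q = (int)q.size(), T = t1 - t0;
  if (T <= 0 || Q == 0) return false;
  // score lookup by residue index; unknown letters map to alphabet 'X' row
  std::vector<int> qi(Q), ti(T);
  for (int j = 0; j < Q; ++j) { int v = ai[(unsigned char)q[j]]; qi[j] = v; }
  for (int i = 0; i < T; ++i) { int v = ai[(unsigned char)tg[t0 + i]]; ti[i] = v; }
  size_t ncell = (size_t)(T + 1) * (Q + 1);
  std::vector<double> H(ncell, 0.0), E(ncell, NEG), F(ncell, NEG);
  std::vector<unsigned char> tb(ncell, 0), tbe(ncell, 0), tbf(ncell, 0);
  // tb: 0 stop, 1 diag, 2 useE (gap in query/target-consuming), 3 useF
  double best = 0; int bi = -1, bj = -1;
  for (int i = 1; i <= T; ++i) {
    bool masked = maskv[t0 + i - 1] != 0;
    size_t row = (size_t)i * (Q + 1), prow = (size_t)(i - 1) * (Q + 1);
    for (int j = 1; j <= Q; ++j) {
      if (masked) { H[row + j] = 0; E[row + j] = NEG; F[row + j] = NEG; continue; }
      // E: gap consuming target (query gap column)
      double eo = H[prow + j] + go + ge, ee = E[prow + j] + ge;
      if (eo >= ee) { E[row + j] = eo; tbe[row + j] = 1; }
      else          { E[row + j] = ee; tbe[row + j] = 0; }
      // F: gap consuming query (target gap column)
      double fo = H[row + j - 1] + go + ge, fe = F[row + j - 1] + ge;
      if (fo >= fe) { F[row + j] = fo; tbf[row + j] = 1; }
      else          { F[row + j] = fe; tbf[row + j] = 0; }
      double s = (qi[j - 1] >= 0 && ti[i - 1] >= 0)
        ? mat[(size_t)ti[i - 1] * A + qi[j - 1]] : -4.0;
      double d = H[prow + j - 1] + s;
      double h = 0; unsigned char t = 0;
      if (d > h) { h = d; t = 1; }
      if (E[row + j] > h) { h = E[row + j]; t = 2; }
      if (F[row + j] > h) { h = F[row + j]; t = 3; }
      H[row + j] = h; tb[row + j] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (bi < 0 || best <= 0) return false;
  // traceback
  std::string aq, at;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    size_t c = (size_t)i * (Q + 1) + j;
    unsigned char t = tb[c];
    if (t == 0) break;
    if (t == 1) { aq.push_back(q[j - 1]); at.push_back(tg[t0 + i - 1]); --i; --j; }
    else if (t == 2) {
      while (true) {
        size_t cc = (size_t)i * (Q + 1) + j;
        aq.push_back('-'); at.push_back(tg[t0 + i - 1]);
        bool open = tbe[cc] != 0; --i;
        if (open) break;
      }
    } else {
      while (true) {
        size_t cc = (size_t)i * (Q + 1) + j;
        aq.push_back(q[j - 1]); at.push_back('-');
        bool open = tbf[cc] != 0; --j;
        if (open) break;
      }
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(at.begin(), at.end());
  out.t_start = t0 + i; out.t_end = t0 + bi;
  out.q_start = j; out.q_end = bj;
  out.score = best; out.aq = aq; out.at = at;
  return true;
}

// [[Rcpp::export]]
List cpp_frame_search(std::string query, std::string frame_aa,
                      NumericMatrix smat, std::string alphabet,
                      int word, double seed_thresh,
                      double gap_open, double gap_ext,
                      double min_score, int max_hits, double x_drop) {
  int A = smat.nrow();
  std::vector<double> mat(A * A);
  for (int i = 0; i < A; ++i)
    for (int j = 0; j < A; ++j) mat[(size_t)i * A + j] = smat(i, j);
  int ai[256]; idx_of(alphabet, ai);
  double maxval = 0;
  for (size_t k = 0; k < mat.size(); ++k) if (mat[k] > maxval) maxval = mat[k];
  int Q = (int)query.size(), T = (int)frame_aa.size();
  std::vector<int> qi(Q), ti(T);
  for (int j = 0; j < Q; ++j) qi[j] = ai[(unsigned char)query[j]];
  for (int i = 0; i < T; ++i) ti[i] = ai[(unsigned char)frame_aa[i]];

  std::vector<char> maskv(T, 0);
  std::vector<SwHit> hits;

  // stop-free segments
  int s = 0;
  while (s < T) {
    while (s < T && frame_aa[s] == '*') ++s;
    int e = s;
    while (e < T && frame_aa[e] != '*') ++e;
    if (e - s >= word && Q >= word) {
      // neighborhood seeding: any diagonal word scoring >= seed_thresh
      int lo = -1, hi = -1;
      for (int t = s; t + word <= e; ++t) {
        bool seeded = false;
        for (int qpos = 0; qpos + word <= Q && !seeded; ++qpos) {
          double sc = 0;
          for (int k = 0; k < word; ++k) {
            int a = ti[t + k], b = qi[qpos + k];
            sc += (a >= 0 && b >= 0) ? mat[(size_t)a * A + b] : -4.0;
            if (sc < seed_thresh - maxval * (word - k - 1)) break; // cannot reach
          }
          if (sc >= seed_thresh) seeded = true;
        }
        if (seeded) { if (lo < 0) lo = t; hi = t + word; }
      }
      if (lo >= 0) {
        // X-drop bound: a surviving extension cannot carry a gap run longer
        // than (x_drop - |open|)/|ext| columns, so limit the window.
        int margin = Q + (int)((x_drop - (-gap_open)) / (-gap_ext)) + Q + 8;
        if (margin < Q + 8) margin = Q + 8;
        int w0 = std::max(s, lo - margin), w1 = std::min(e, hi + margin);
        for (int h = 0; h < max_hits; ++h) {
          SwHit hit;
          if (!sw_best(query, frame_aa, w0, w1, mat, A, ai,
                       gap_open, gap_ext, maskv, hit)) break;
          if (hit.score < min_score) break;
          for (int t = hit.t_start; t < hit.t_end; ++t) maskv[t] = 1;
          hits.push_back(hit);
        }
      }
    }
    s = e;
  }

  List out(hits.size());
  for (size_t k = 0; k < hits.size(); ++k) {
    out[k] = List::create(
      _["t_start"] = hits[k].t_start, _["t_end"] = hits[k].t_end,
      _["q_start"] = hits[k].q_start, _["q_end"] = hits[k].q_end,
      _["score"] = hits[k].score,
      _["aligned_query"] = hits[k].aq, _["aligned_target"] = hits[k].at);
  }
  return out;
}
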
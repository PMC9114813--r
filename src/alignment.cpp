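#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman, Gotoh three-state DP).
// Sequences arrive as 1-based integer codes indexing rows of the scoring
// matrix. A gap of length L costs gap_open + L * gap_extend.

struct SwResult {
  double score;
  int qs, qe, ss, se;
  int matches, columns;
};

// score-only pass: rolling rows, returns best score and its end cell
static double sw_score_only(const int *a, int m, const int *b, int n,
                            const double *S, int ncol,
                            double gapo, double gape,
                            int *best_i, int *best_j) {
  std::vector<double> H(n + 1, 0.0), Iy(n + 1, -1e30);
  std::vector<double> Hup(n + 1, 0.0), Ix(n + 1, -1e30);
  double best = 0.0;
  *best_i = 0; *best_j = 0;
  for (int i = 1; i <= m; ++i) {
    std::swap(H, Hup);                 // Hup now holds row i-1
    H[0] = 0.0;
    double iy = -1e30;                 // Iy for (i, j) built left-to-right
    const double *Srow = S + (size_t)(a[i - 1] - 1);
    for (int j = 1; j <= n; ++j) {
      double ix = Ix[j] - gape;
      double ox = Hup[j] - gapo - gape;
      if (ox > ix) ix = ox;
      Ix[j] = ix;
      double oy = H[j - 1] - gapo - gape;
      iy -= gape;
      if (oy > iy) iy = oy;
      double h = Hup[j - 1] + Srow[(size_t)(b[j - 1] - 1) * ncol];
      if (h < ix) h = ix;
      if (h < iy) h = iy;
      if (h < 0.0) h = 0.0;
      H[j] = h;
      if (h > best) { best = h; *best_i = i; *best_j = j; }
    }
  }
  return best;
}

// full DP with traceback over the [1..bi] x [1..bj] corner
static SwResult sw_traceback(const int *a, int bi, const int *b, int bj,
                             const double *S, int ncol,
                             double gapo, double gape) {
  const int W = bj + 1;
  std::vector<double> H((bi + 1) * W, 0.0);
  std::vector<double> Ix((bi + 1) * W, -1e30);
  std::vector<double> Iy((bi + 1) * W, -1e30);
  std::vector<unsigned char> tbH((bi + 1) * W, 0);
  std::vector<unsigned char> tbIx((bi + 1) * W, 0);
  std::vector<unsigned char> tbIy((bi + 1) * W, 0);
  double best = 0.0; int ei = 0, ej = 0;
  for (int i = 1; i <= bi; ++i) {
    const double *Srow = S + (size_t)(a[i - 1] - 1);
    for (int j = 1; j <= bj; ++j) {
      const int idx = i * W + j;
      double openx = H[(i - 1) * W + j] - gapo - gape;
      double extx = Ix[(i - 1) * W + j] - gape;
      if (openx >= extx) { Ix[idx] = openx; tbIx[idx] = 1; }
      else               { Ix[idx] = extx;  tbIx[idx] = 0; }
      double openy = H[i * W + (j - 1)] - gapo - gape;
      double exty = Iy[i * W + (j - 1)] - gape;
      if (openy >= exty) { Iy[idx] = openy; tbIy[idx] = 1; }
      else               { Iy[idx] = exty;  tbIy[idx] = 0; }
      double diag = H[(i - 1) * W + (j - 1)] +
        Srow[(size_t)(b[j - 1] - 1) * ncol];
      double h = 0.0; unsigned char tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (Ix[idx] > h) { h = Ix[idx]; tb = 2; }
      if (Iy[idx] > h) { h = Iy[idx]; tb = 3; }
      H[idx] = h; tbH[idx] = tb;
      if (h > best) { best = h; ei = i; ej = j; }
    }
  }
  SwResult res; res.score = best; res.matches = 0; res.columns = 0;
  if (best <= 0.0) { res.qs = res.qe = res.ss = res.se = 0; return res; }
  int i = ei, j = ej;
  int state = tbH[i * W + j];
  res.qe = ei; res.se = ej;
  while (i > 0 && j > 0 && state != 0) {
    if (state == 1) {
      res.columns++;
      if (a[i - 1] == b[j - 1]) res.matches++;
      --i; --j;
      state = tbH[i * W + j];
    } else if (state == 2) {
      res.columns++;
      int opened = tbIx[i * W + j];
      --i;
      state = opened ? tbH[i * W + j] : 2;
    } else {
      res.columns++;
      int opened = tbIy[i * W + j];
      --j;
      state = opened ? tbH[i * W + j] : 3;
    }
  }
  res.qs = i + 1; res.ss = j + 1;
  return res;
}

static SwResult sw_core(const int *a, int m, const int *b, int n,
                        const NumericMatrix &S, double gapo, double gape) {
  int bi, bj;
  const double *Sp = S.begin();
  const int ncol = S.nrow();
  double best = sw_score_only(a, m, b, n, Sp, ncol, gapo, gape, &bi, &bj);
  SwResult res;
  if (best <= 0.0) {
    res.score = 0.0; res.qs = res.qe = res.ss = res.se = 0;
    res.matches = 0; res.columns = 0;
    return res;
  }
  res = sw_traceback(a, bi, b, bj, Sp, ncol, gapo, gape);
  return res;
}

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_open, double gap_extend) {
  SwResult r = sw_core(INTEGER(a), a.size(), INTEGER(b), b.size(),
                       S, gap_open, gap_extend);
  return List::create(_["score"] = r.score,
                      _["q_start"] = r.qs, _["q_end"] = r.qe,
                      _["s_start"] = r.ss, _["s_end"] = r.se,
                      _["matches"] = r.matches, _["columns"] = r.columns);
}

// Seeded database scan: exact k-mer word matches, two distinct hits on one
// diagonal within `two_hit_dist` query positions trigger extension.
// Extension first runs a cheap score-only DP on a subject window spanning
// the seeded diagonals padded by the query length; only candidates whose
// score reaches `min_score` get the full traceback. k-mers containing codes
// above `max_seed_code` (ambiguity codes, stops) are never indexed.
// [[Rcpp::export]]
DataFrame search_db_cpp(IntegerVector query, List db, NumericMatrix S,
                        double gap_open, double gap_extend,
                        int k, int two_hit_dist, int max_seed_code,
                        double min_score) {
  const int m = query.size();
  const int *q = INTEGER(query);
  const double *Sp = S.begin();
  const int ncol = S.nrow();

  std::unordered_map<uint64_t, std::vector<int> > qindex;
  const uint64_t base = (uint64_t)max_seed_code + 1;
  uint64_t pw = 1;
  for (int t = 0; t < k; ++t) pw *= base;
  if (m >= k) {
    for (int i = 0; i + k <= m; ++i) {
      uint64_t key = 0; bool ok = true;
      for (int t = 0; t < k; ++t) {
        int c = q[i + t];
        if (c < 1 || c > max_seed_code) { ok = false; break; }
        key = key * base + (uint64_t)c;
      }
      if (ok) qindex[key].push_back(i);
    }
  }

  std::vector<int> out_idx, out_qs, out_qe, out_ss, out_se, out_match,
    out_cols;
  std::vector<double> out_score;
  if (!qindex.empty()) {
    const int ndb = db.size();
    for (int d = 0; d < ndb; ++d) {
      IntegerVector bv = db[d];
      const int n = bv.size();
      if (n < k) continue;
      const int *b = INTEGER(bv);
      std::unordered_map<int, int> last_on_diag;
      bool seeded = false;
      int smin = n, smax = -1;
      uint64_t key = 0; int run = 0;
      for (int j = 0; j < n; ++j) {
        int c = b[j];
        if (c < 1 || c > max_seed_code) { run = 0; key = 0; continue; }
        key = key * base + (uint64_t)c;
        if (run + 1 < k) { ++run; continue; }
        if (run + 1 > k) key %= pw;
        run = k;
        auto it = qindex.find(key);
        if (it != qindex.end()) {
          int spos = j - k + 1;
          for (int qpos : it->second) {
            int diag = spos - qpos;
            auto lit = last_on_diag.find(diag);
            if (lit != last_on_diag.end()) {
              // two-hit rule: a word overlapping the last recorded word on
              // its diagonal is skipped (and not recorded); two recorded
              // words within two_hit_dist trigger extension
              int delta = qpos - lit->second;
              if (delta >= k || delta <= -k) {
                if (delta >= k && delta <= two_hit_dist) {
                  seeded = true;
                  if (spos < smin) smin = spos;
                  if (spos + k - 1 > smax) smax = spos + k - 1;
                }
                lit->second = qpos;
              }
            } else {
              last_on_diag[diag] = qpos;
            }
            if (seeded) {
              if (spos < smin) smin = spos;
              if (spos + k - 1 > smax) smax = spos + k - 1;
            }
          }
        }
      }
      if (!seeded) continue;
      int ws = smin - m - 32; if (ws < 0) ws = 0;
      int we = smax + m + 32; if (we > n - 1) we = n - 1;
      const int wn = we - ws + 1;
      int bi, bj;
      double best = sw_score_only(q, m, b + ws, wn, Sp, ncol,
                                  gap_open, gap_extend, &bi, &bj);
      if (best < min_score || best <= 0.0) continue;
      SwResult r = sw_traceback(q, bi, b + ws, bj, Sp, ncol,
                                gap_open, gap_extend);
      if (r.columns == 0) continue;
      out_idx.push_back(d + 1);
      out_score.push_back(r.score);
      out_qs.push_back(r.qs); out_qe.push_back(r.qe);
      out_ss.push_back(r.ss + ws); out_se.push_back(r.se + ws);
      out_match.push_back(r.matches); out_cols.push_back(r.columns);
    }
  }

  return DataFrame::create(_["db_index"] = wrap(out_idx),
                           _["score"] = wrap(out_score),
                           _["q_start"] = wrap(out_qs),
                           _["q_end"] = wrap(out_qe),
                           _["s_start"] = wrap(out_ss),
                           _["s_end"] = wrap(out_se),
                           _["matches"] = wrap(out_match),
                           _["columns"] = wrap(out_cols));
}
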
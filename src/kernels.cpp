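#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Pairwise site counts under pairwise deletion.
//
// codes: L x n integer matrix (sites in rows, samples in columns),
//        A=0, C=1, G=2, T=3, anything else (gap, N, ambiguity) = -1.
// w:     per-site weights (all 1 for the plain matrix; bootstrap resamples
//        pass multinomial column counts so no reindexing is needed).
//
// With this coding a mismatch is a transition iff (a ^ b) == 2
// (A^G = 2, C^T = 2; all transversion pairs xor to 1 or 3).
// [[Rcpp::export]]
List pair_counts_cpp(const IntegerMatrix& codes, const NumericVector& w) {
  const int L = codes.nrow(), n = codes.ncol();
  NumericMatrix ts(n, n), tv(n, n), comp(n, n);
  for (int i = 0; i < n; ++i) {
    const int* ci = &codes[(R_xlen_t)i * L];
    for (int j = i + 1; j < n; ++j) {
      const int* cj = &codes[(R_xlen_t)j * L];
      double cts = 0.0, ctv = 0.0, cc = 0.0;
      for (int s = 0; s < L; ++s) {
        const int a = ci[s], b = cj[s];
        if (a < 0 || b < 0) continue;
        const double ww = w[s];
        cc += ww;
        if (a != b) {
          if ((a ^ b) == 2) cts += ww; else ctv += ww;
        }
      }
      ts(i, j) = ts(j, i) = cts;
      tv(i, j) = tv(j, i) = ctv;
      comp(i, j) = comp(j, i) = cc;
    }
  }
  return List::create(_["transitions"] = ts,
                      _["transversions"] = tv,
                      _["comparable"] = comp);
}

// Neighbor-joining agglomeration (Saitou & Nei).
//
// Iteratively joins the pair minimising Q = (N-2) d_ij - r_i - r_j until
// three nodes remain. Ties are broken by the first (row, column) pair in
// the current matrix ordering (strict '<' during the scan). Negative
// branch lengths are clamped to zero with the deficit moved to the sister
// edge. Returns the merge list (node ids: 1..n are input tips, new nodes
// numbered n+1, ...) plus the final three nodes and their star lengths.
// [[Rcpp::export]]
List nj_cpp(const NumericMatrix& dist) {
  const int n = dist.nrow();
  std::vector<std::vector<double> > d(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) d[i][j] = dist(i, j);
  std::vector<int> id(n);
  for (int i = 0; i < n; ++i) id[i] = i + 1;

  int N = n, next_id = n + 1, step = 0;
  const int n_merge = n > 3 ? n - 3 : 0;
  IntegerMatrix merges(n_merge, 3);
  NumericMatrix mlen(n_merge, 2);

  while (N > 3) {
    std::vector<double> r(N, 0.0);
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int j = 0; j < N; ++j) s += d[i][j];
      r[i] = s;
    }
    double best = R_PosInf;
    int bi = -1, bj = -1;
    for (int i = 0; i < N; ++i) {
      for (int j = i + 1; j < N; ++j) {
        const double q = (N - 2) * d[i][j] - r[i] - r[j];
        if (q < best) { best = q; bi = i; bj = j; }
      }
    }
    const double dij = d[bi][bj];
    double la = 0.5 * dij + (r[bi] - r[bj]) / (2.0 * (N - 2));
    double lb = dij - la;
    if (la < 0) { lb += la; la = 0; }
    if (lb < 0) { la += lb; lb = 0; }
    if (la < 0) la = 0;

    merges(step, 0) = id[bi];
    merges(step, 1) = id[bj];
    merges(step, 2) = next_id;
    mlen(step, 0) = la;
    mlen(step, 1) = lb;

    std::vector<double> du(N, 0.0);
    for (int k = 0; k < N; ++k)
      if (k != bi && k != bj) du[k] = 0.5 * (d[bi][k] + d[bj][k] - dij);
    for (int k = 0; k < N; ++k) {
      const double v = (k == bi) ? 0.0 : du[k];
      d[bi][k] = v;
      d[k][bi] = v;
    }
    id[bi] = next_id;
    const int last = N - 1;
    if (bj != last) {
      for (int k = 0; k < N; ++k) { d[bj][k] = d[last][k]; d[k][bj] = d[k][last]; }
      d[bj][bj] = 0.0;
      id[bj] = id[last];
    }
    --N; ++next_id; ++step;
  }

  NumericVector flen(3);
  IntegerVector fid(3);
  flen[0] = 0.5 * (d[0][1] + d[0][2] - d[1][2]);
  flen[1] = 0.5 * (d[0][1] + d[1][2] - d[0][2]);
  flen[2] = 0.5 * (d[0][2] + d[1][2] - d[0][1]);
  for (int i = 0; i < 3; ++i) {
    if (flen[i] < 0) flen[i] = 0;
    fid[i] = id[i];
  }
  return List::create(_["merges"] = merges, _["lengths"] = mlen,
                      _["final_ids"] = fid, _["final_lengths"] = flen);
}

// Sparse per-pair site index for fast bootstrap resampling.
//
// For every unordered pair (row-major i<j) records the sites where both
// samples are valid and differ (split into transitions and transversions)
// and the sites where at least one sample is missing. A resample with
// site weights w then gives, per pair:
//   transitions  = sum of w over that pair's ts sites
//   transversions= sum of w over that pair's tv sites
//   comparable   = sum(w) - sum of w over that pair's excluded sites
// so the O(n^2 L) scan is paid once, not per replicate.
// [[Rcpp::export]]
List pair_site_index_cpp(const IntegerMatrix& codes) {
  const int L = codes.nrow(), n = codes.ncol();
  std::vector<int> ts, tv, ex;
  const R_xlen_t npair = (R_xlen_t)n * (n - 1) / 2;
  IntegerVector ts_off(npair + 1), tv_off(npair + 1), ex_off(npair + 1);
  R_xlen_t k = 0;
  for (int i = 0; i < n; ++i) {
    const int* ci = &codes[(R_xlen_t)i * L];
    for (int j = i + 1; j < n; ++j, ++k) {
      const int* cj = &codes[(R_xlen_t)j * L];
      for (int s = 0; s < L; ++s) {
        const int a = ci[s], b = cj[s];
        if (a < 0 || b < 0) { ex.push_back(s); continue; }
        if (a != b) {
          if ((a ^ b) == 2) ts.push_back(s); else tv.push_back(s);
        }
      }
      ts_off[k + 1] = (int)ts.size();
      tv_off[k + 1] = (int)tv.size();
      ex_off[k + 1] = (int)ex.size();
    }
  }
  return List::create(_["n"] = n, _["L"] = L,
                      _["ts_sites"] = IntegerVector(ts.begin(), ts.end()),
                      _["tv_sites"] = IntegerVector(tv.begin(), tv.end()),
                      _["ex_sites"] = IntegerVector(ex.begin(), ex.end()),
                      _["ts_off"] = ts_off, _["tv_off"] = tv_off,
                      _["ex_off"] = ex_off);
}

// [[Rcpp::export]]
List pair_counts_indexed_cpp(const List& idx, const NumericVector& w) {
  const int n = as<int>(idx["n"]);
  IntegerVector ts_sites = idx["ts_sites"], tv_sites = idx["tv_sites"],
                ex_sites = idx["ex_sites"];
  IntegerVector ts_off = idx["ts_off"], tv_off = idx["tv_off"],
                ex_off = idx["ex_off"];
  double wtot = 0.0;
  for (R_xlen_t s = 0; s < w.size(); ++s) wtot += w[s];
  NumericMatrix ts(n, n), tv(n, n), comp(n, n);
  R_xlen_t k = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j, ++k) {
      double a = 0.0, b = 0.0, e = 0.0;
      for (int s = ts_off[k]; s < ts_off[k + 1]; ++s) a += w[ts_sites[s]];
      for (int s = tv_off[k]; s < tv_off[k + 1]; ++s) b += w[tv_sites[s]];
      for (int s = ex_off[k]; s < ex_off[k + 1]; ++s) e += w[ex_sites[s]];
      ts(i, j) = ts(j, i) = a;
      tv(i, j) = tv(j, i) = b;
      comp(i, j) = comp(j, i) = wtot - e;
    }
  }
  return List::create(_["transitions"] = ts,
                      _["transversions"] = tv,
                      _["comparable"] = comp);
}
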
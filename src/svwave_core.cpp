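#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double sq(double v) { return v * v; }

// Dynamic-time-warping distance between two series.
// Local cost is the squared pointwise difference; the returned value is the
// square root of the minimal cumulative cost over monotone warping paths
// anchored at both ends (steps: match, insert, delete). band < 0 disables the
// Sakoe-Chiba constraint.
// [[Rcpp::export]]
double cpp_dtw(NumericVector x, NumericVector y, int band = -1) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("dtw: empty input");
  const double INF = R_PosInf;
  std::vector<double> prev(m, INF), cur(m, INF);
  for (int i = 0; i < n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int jlo = 0, jhi = m - 1;
    if (band >= 0) {
      jlo = std::max(0, i - band);
      jhi = std::min(m - 1, i + band);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double c = sq(x[i] - y[j]);
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else {
        best = INF;
        if (i > 0) best = std::min(best, prev[j]);
        if (j > 0) best = std::min(best, cur[j - 1]);
        if (i > 0 && j > 0) best = std::min(best, prev[j - 1]);
      }
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return std::sqrt(prev[m - 1]);
}

// Optimal warping path (1-based index pairs), needed for barycenter averaging.
// [[Rcpp::export]]
IntegerMatrix cpp_dtw_path(NumericVector x, NumericVector y, int band = -1) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("dtw: empty input");
  const double INF = R_PosInf;
  NumericMatrix D(n, m);
  std::fill(D.begin(), D.end(), INF);
  for (int i = 0; i < n; ++i) {
    int jlo = 0, jhi = m - 1;
    if (band >= 0) { jlo = std::max(0, i - band); jhi = std::min(m - 1, i + band); }
    for (int j = jlo; j <= jhi; ++j) {
      double c = sq(x[i] - y[j]);
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else {
        best = INF;
        if (i > 0) best = std::min(best, D(i - 1, j));
        if (j > 0) best = std::min(best, D(i, j - 1));
        if (i > 0 && j > 0) best = std::min(best, D(i - 1, j - 1));
      }
      D(i, j) = c + best;
    }
  }
  // backtrack (prefer diagonal on ties)
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      double d = D(i - 1, j - 1), u = D(i - 1, j), l = D(i, j - 1);
      if (d <= u && d <= l) { --i; --j; }
      else if (u <= l) { --i; }
      else { --j; }
    }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  const int len = pi.size();
  IntegerMatrix path(len, 2);
  for (int s = 0; s < len; ++s) {
    path(s, 0) = pi[len - 1 - s];
    path(s, 1) = pj[len - 1 - s];
  }
  return path;
}

// DTW distances from each row of X to the series y.
// [[Rcpp::export]]
NumericVector cpp_dtw_many(NumericMatrix X, NumericVector y, int band = -1) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    NumericVector xi = X(i, _);
    out[i] = cpp_dtw(xi, y, band);
  }
  return out;
}

// Full symmetric pairwise DTW distance matrix over the rows of X.
// [[Rcpp::export]]
NumericMatrix cpp_dtw_pairwise(NumericMatrix X, int band = -1) {
  const int n = X.nrow();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    NumericVector xi = X(i, _);
    for (int j = i + 1; j < n; ++j) {
      NumericVector xj = X(j, _);
      double d = cpp_dtw(xi, xj, band);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

struct UnionFind {
  std::vector<int> parent, rank_;
  UnionFind(int n) : parent(n), rank_(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) ++rank_[a];
  }
};

// Reference-point-pruned single-linkage grouping of SAX segments.
//
// words: n x L matrix of 0-based symbols; cell2: alphabet x alphabet matrix of
// SQUARED per-symbol MINDIST cell values; scale: sqrt(original_length/L);
// S, C: precomputed distances of each word to the two reference words;
// thresh1d: 1D candidate window (eps plus any exactness slack); eps: linkage
// threshold on the full SAX distance. Pairs are enumerated through a sliding
// window over words sorted by S, so only pairs with |S_i - S_j| <= thresh1d
// are touched; of those, pairs with |C_i - C_j| <= thresh1d get a full SAX
// distance evaluation (with early abandoning at eps).
// Returns 0-based component labels and the number of full evaluations.
// [[Rcpp::export]]
List cpp_knn_groups(IntegerMatrix words, NumericMatrix cell2, double scale,
                    NumericVector S, NumericVector C,
                    double thresh1d, double eps) {
  const int n = words.nrow(), L = words.ncol();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return S[a] < S[b]; });

  UnionFind uf(n);
  long long neval = 0;
  // early-abandon bound, slightly relaxed; the decisive comparison below is
  // scale*sqrt(acc) <= eps so borderline ties round exactly as a plain
  // all-pairs evaluation would
  const double e = eps / std::max(scale, 1e-300);
  const double eps2 = e * e * (1.0 + 1e-9) + 1e-300;
  for (int a = 0; a < n; ++a) {
    const int i = ord[a];
    for (int b = a + 1; b < n; ++b) {
      const int j = ord[b];
      if (S[j] - S[i] > thresh1d) break;            // sorted by S
      if (std::fabs(C[i] - C[j]) > thresh1d) continue;
      if (uf.find(i) == uf.find(j)) {
        // already linked; still counts as avoided evaluation
        continue;
      }
      ++neval;
      double acc = 0.0;
      bool within = true;
      for (int p = 0; p < L; ++p) {
        acc += cell2(words(i, p), words(j, p));
        if (acc > eps2) { within = false; break; }
      }
      if (within && scale * std::sqrt(acc) <= eps) uf.unite(i, j);
    }
  }
  IntegerVector labels(n);
  std::vector<int> remap(n, -1);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    if (remap[r] < 0) remap[r] = next++;
    labels[i] = remap[r];
  }
  return List::create(_["labels"] = labels, _["n_eval"] = (double)neval,
                      _["n_groups"] = next);
}

// Sliding MINDIST of every length-L window of `word` against `motif`
// (both 0-based symbol vectors); scale applies the compression factor.
// [[Rcpp::export]]
NumericVector cpp_scan_word(IntegerVector word, IntegerVector motif,
                            NumericMatrix cell2, double scale) {
  const int L = motif.size();
  const int n = word.size() - L + 1;
  if (n < 1) return NumericVector(0);
  NumericVector out(n);
  for (int o = 0; o < n; ++o) {
    double acc = 0.0;
    for (int p = 0; p < L; ++p) acc += cell2(word[o + p], motif[p]);
    out[o] = scale * std::sqrt(acc);
  }
  return out;
}
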
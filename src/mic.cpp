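#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Maximal information coefficient (MIC) machinery.
//
// The characteristic matrix is explored with one axis equipartitioned by rank
// (ties kept together) and the other axis optimized exactly by dynamic
// programming over contiguous partitions of the value clumps.  Both
// orientations are searched and the per-cell maximum taken, so the statistic
// is symmetric in its arguments.  The grid bound is B(n) = max(n^alpha, 4):
// grids (nx, ny) with nx, ny >= 2 and nx * ny <= B are admissible.

// Rank-equipartition of v into q bins, keeping tied values in one bin.
// Returns 0-based bin ids aligned with the input order.
// [[Rcpp::export(name = ".micEquipartition")]]
IntegerVector mic_equipartition(NumericVector v, int q) {
  int n = v.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  IntegerVector bins(n);
  int bin = 0, count = 0, assignedBefore = 0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && v[idx[j]] == v[idx[i]]) ++j;
    int c = j - i;
    if (count > 0 && bin < q - 1) {
      double desired = (double)(n - assignedBefore) / (double)(q - bin);
      // close the current bin if that leaves it no farther from its target
      if (std::fabs(count + c - desired) >= std::fabs(count - desired)) {
        ++bin;
        assignedBefore += count;
        count = 0;
      }
    }
    for (int t = i; t < j; ++t) bins[idx[t]] = bin;
    count += c;
    i = j;
  }
  return bins;
}

// Exact DP over contiguous clump partitions of x (ties inseparable), given a
// fixed bin assignment of the other axis.  Returns, for each l = 2..lmax, the
// maximum mutual information (bits) over partitions into at most l bins.
// [[Rcpp::export(name = ".micOptimizeAxis")]]
NumericVector mic_optimize_axis(NumericVector x, IntegerVector ybins, int lmax) {
  int n = x.size();
  int q = 0;
  for (int i = 0; i < n; ++i) q = std::max(q, ybins[i] + 1);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return x[a] < x[b]; });

  // cumulative per-row counts at clump boundaries
  std::vector<std::vector<double> > cum;  // (m+1) x q
  std::vector<double> cumtot;             // (m+1)
  cum.push_back(std::vector<double>(q, 0.0));
  cumtot.push_back(0.0);
  int i = 0;
  while (i < n) {
    int j = i;
    std::vector<double> row = cum.back();
    double tot = cumtot.back();
    while (j < n && x[idx[j]] == x[idx[i]]) {
      row[ybins[idx[j]]] += 1.0;
      tot += 1.0;
      ++j;
    }
    cum.push_back(row);
    cumtot.push_back(tot);
    i = j;
  }
  int m = (int)cum.size() - 1;  // number of clumps
  std::vector<double> nq(q, 0.0);
  for (int r = 0; r < q; ++r) nq[r] = cum[m][r];
  double nn = (double)n;

  // contribution of one x-bin spanning clumps (a, b]
  auto w = [&](int a, int b) {
    double nb = cumtot[b] - cumtot[a];
    if (nb <= 0) return 0.0;
    double s = 0.0;
    for (int r = 0; r < q; ++r) {
      double nbq = cum[b][r] - cum[a][r];
      if (nbq > 0 && nq[r] > 0)
        s += nbq / nn * std::log2(nbq * nn / (nb * nq[r]));
    }
    return s;
  };

  int lcap = std::min(lmax, m);
  const double NEG = -1e100;
  // D[l][k]: best I over partitions of first k clumps into exactly l bins
  std::vector<std::vector<double> > D(lcap + 1,
                                      std::vector<double>(m + 1, NEG));
  for (int k = 1; k <= m; ++k) D[1][k] = w(0, k);
  for (int l = 2; l <= lcap; ++l)
    for (int k = l; k <= m; ++k) {
      double best = NEG;
      for (int j = l - 1; j < k; ++j) {
        double v = D[l - 1][j] + w(j, k);
        if (v > best) best = v;
      }
      D[l][k] = best;
    }

  NumericVector out(std::max(lmax - 1, 0));
  double run = (m >= 1) ? D[1][m] : 0.0;
  for (int l = 2; l <= lmax; ++l) {
    if (l <= lcap && D[l][m] > run) run = D[l][m];
    out[l - 2] = std::max(run, 0.0);
  }
  return out;
}

// [[Rcpp::export(name = ".micCpp")]]
double mic_cpp(NumericVector x, NumericVector y, double alpha) {
  int n = x.size();
  double B = std::max(std::pow((double)n, alpha), 4.0);
  double best = 0.0;
  for (int orient = 0; orient < 2; ++orient) {
    NumericVector a = orient ? y : x;
    NumericVector b = orient ? x : y;
    int qmax = (int)std::floor(B / 2.0);
    for (int q = 2; q <= qmax; ++q) {
      int lmax = (int)std::floor(B / (double)q);
      if (lmax < 2) continue;
      IntegerVector bb = mic_equipartition(b, q);
      NumericVector bi = mic_optimize_axis(a, bb, lmax);
      for (int l = 2; l <= lmax; ++l) {
        double v = bi[l - 2] / std::log2((double)std::min(l, q));
        if (v > best) best = v;
      }
    }
  }
  if (best < 0.0) best = 0.0;
  if (best > 1.0) best = 1.0;
  return best;
}
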
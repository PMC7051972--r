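#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

static double l1_dist_row(const NumericMatrix &X, int i, const NumericMatrix &C,
                          int c) {
  double d = 0.0;
  for (int j = 0; j < X.ncol(); ++j)
    d += std::fabs(X(i, j) - C(c, j));
  return d;
}

// coordinate-wise median; even-sized sets take the mean of the two middle
// values so updates are deterministic
static void col_medians(const NumericMatrix &X, const std::vector<int> &rows,
                        NumericMatrix &C, int c) {
  std::vector<double> v(rows.size());
  for (int j = 0; j < X.ncol(); ++j) {
    for (size_t r = 0; r < rows.size(); ++r)
      v[r] = X(rows[r], j);
    std::sort(v.begin(), v.end());
    size_t m = v.size();
    C(c, j) = (m % 2 == 1) ? v[m / 2] : 0.5 * (v[m / 2 - 1] + v[m / 2]);
  }
}

// k-means++ style seeding with Manhattan distances (D(x)^2 sampling),
// driven by R's RNG so results follow set.seed()
static void kpp_init(const NumericMatrix &X, int k, NumericMatrix &C) {
  int n = X.nrow(), p = X.ncol();
  std::vector<int> chosen;
  int first = (int)std::floor(unif_rand() * n);
  if (first >= n) first = n - 1;
  chosen.push_back(first);
  std::vector<double> d2(n);
  for (int c = 1; c < k; ++c) {
    double total = 0.0;
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      for (size_t s = 0; s < chosen.size(); ++s) {
        double d = 0.0;
        for (int j = 0; j < p; ++j)
          d += std::fabs(X(i, j) - X(chosen[s], j));
        if (d < best) best = d;
      }
      d2[i] = best * best;
      total += d2[i];
    }
    int pick;
    if (total <= 0.0) { // all remaining points coincide with a centre
      pick = (int)std::floor(unif_rand() * n);
      if (pick >= n) pick = n - 1;
    } else {
      double u = unif_rand() * total, acc = 0.0;
      pick = n - 1;
      for (int i = 0; i < n; ++i) {
        acc += d2[i];
        if (u <= acc) { pick = i; break; }
      }
    }
    chosen.push_back(pick);
  }
  for (int c = 0; c < k; ++c)
    for (int j = 0; j < p; ++j)
      C(c, j) = X(chosen[c], j);
}

// [[Rcpp::export]]
List kmedians_once_cpp(NumericMatrix X, int k, int max_iter) {
  RNGScope scope;
  int n = X.nrow(), p = X.ncol();
  NumericMatrix C(k, p);
  kpp_init(X, k, C);
  IntegerVector labels(n, 0);
  std::vector<double> cost_trace;
  bool changed = true;
  int iter = 0;
  double cost = 0.0;
  while (changed && iter < max_iter) {
    changed = false;
    ++iter;
    cost = 0.0;
    // assignment: nearest median, ties to the lowest cluster index
    for (int i = 0; i < n; ++i) {
      int best_c = 0;
      double best_d = l1_dist_row(X, i, C, 0);
      for (int c = 1; c < k; ++c) {
        double d = l1_dist_row(X, i, C, c);
        if (d < best_d) { best_d = d; best_c = c; }
      }
      if (labels[i] != best_c + 1) { labels[i] = best_c + 1; changed = true; }
      cost += best_d;
    }
    cost_trace.push_back(cost);
    // empty-cluster repair: reseed with the point farthest from its median
    std::vector<std::vector<int>> members(k);
    for (int i = 0; i < n; ++i)
      members[labels[i] - 1].push_back(i);
    for (int c = 0; c < k; ++c) {
      if (!members[c].empty()) continue;
      int far_i = 0;
      double far_d = -1.0;
      for (int i = 0; i < n; ++i) {
        double d = l1_dist_row(X, i, C, labels[i] - 1);
        if (d > far_d) { far_d = d; far_i = i; }
      }
      int old = labels[far_i] - 1;
      members[old].erase(
          std::find(members[old].begin(), members[old].end(), far_i));
      members[c].push_back(far_i);
      labels[far_i] = c + 1;
      changed = true;
    }
    for (int c = 0; c < k; ++c)
      if (!members[c].empty()) col_medians(X, members[c], C, c);
  }
  // final cost at the converged medians
  cost = 0.0;
  for (int i = 0; i < n; ++i)
    cost += l1_dist_row(X, i, C, labels[i] - 1);
  return List::create(_["labels"] = labels, _["medians"] = C,
                      _["cost"] = cost,
                      _["cost_trace"] = wrap(cost_trace),
                      _["iterations"] = iter);
}

// accumulate connectivity (M) and co-sampling (I) counts for one
// consensus run; idx is 0-based into the full cohort
// [[Rcpp::export]]
void consensus_accumulate_cpp(NumericMatrix M, NumericMatrix I,
                              IntegerVector idx, IntegerVector labels) {
  int m = idx.size();
  for (int a = 0; a < m; ++a) {
    for (int b = a; b < m; ++b) {
      int i = idx[a], j = idx[b];
      I(i, j) += 1.0;
      if (i != j) I(j, i) += 1.0;
      if (labels[a] == labels[b]) {
        M(i, j) += 1.0;
        if (i != j) M(j, i) += 1.0;
      }
    }
  }
}

// Regression ReliefF weight accumulation. X must be range-normalised
// upstream only for interpretability; diffs are divided by per-column
// ranges here so weights stay in [-1, 1] regardless.
// [[Rcpp::export]]
NumericVector rrelieff_cpp(NumericMatrix X, NumericVector y, int n_iter,
                           int k_neighbors, double sigma) {
  RNGScope scope;
  int n = X.nrow(), p = X.ncol();
  std::vector<double> rangeA(p);
  for (int j = 0; j < p; ++j) {
    double lo = X(0, j), hi = X(0, j);
    for (int i = 1; i < n; ++i) {
      if (X(i, j) < lo) lo = X(i, j);
      if (X(i, j) > hi) hi = X(i, j);
    }
    rangeA[j] = hi - lo;
  }
  double ylo = y[0], yhi = y[0];
  for (int i = 1; i < n; ++i) {
    if (y[i] < ylo) ylo = y[i];
    if (y[i] > yhi) yhi = y[i];
  }
  double rangeY = yhi - ylo;

  double NdC = 0.0;
  std::vector<double> NdA(p, 0.0), NdCdA(p, 0.0);
  std::vector<double> dist(n);
  std::vector<int> ord(n);
  // exponential distance-rank influence weights, normalised over the k
  // nearest neighbours of each sampled instance
  std::vector<double> w(k_neighbors);
  double wsum = 0.0;
  for (int r = 0; r < k_neighbors; ++r) {
    w[r] = std::exp(-std::pow((r + 1) / sigma, 2.0));
    wsum += w[r];
  }
  for (int r = 0; r < k_neighbors; ++r)
    w[r] /= wsum;

  for (int it = 0; it < n_iter; ++it) {
    int i = (int)std::floor(unif_rand() * n);
    if (i >= n) i = n - 1;
    for (int q = 0; q < n; ++q) {
      dist[q] = 0.0;
      for (int j = 0; j < p; ++j)
        dist[q] += std::fabs(X(i, j) - X(q, j));
      ord[q] = q;
    }
    dist[i] = R_PosInf; // exclude self
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return dist[a] < dist[b] || (dist[a] == dist[b] && a < b);
    });
    for (int r = 0; r < k_neighbors; ++r) {
      int q = ord[r];
      double dy = (rangeY > 0.0) ? std::fabs(y[i] - y[q]) / rangeY : 0.0;
      NdC += dy * w[r];
      for (int j = 0; j < p; ++j) {
        double da = (rangeA[j] > 0.0)
                        ? std::fabs(X(i, j) - X(q, j)) / rangeA[j]
                        : 0.0;
        NdA[j] += da * w[r];
        NdCdA[j] += dy * da * w[r];
      }
    }
  }
  NumericVector W(p);
  double m = (double)n_iter;
  for (int j = 0; j < p; ++j) {
    if (NdC <= 0.0 || NdC >= m) {
      W[j] = 0.0;
    } else {
      W[j] = NdCdA[j] / NdC - (NdA[j] - NdCdA[j]) / (m - NdC);
    }
  }
  return W;
}
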
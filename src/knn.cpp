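#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Points are passed in columns (d x n) so coordinates of one point are
// contiguous in memory.
static inline double sqdist(const double* A, int a, const double* B, int b,
                            int d) {
  const double* pa = A + (size_t)a * d;
  const double* pb = B + (size_t)b * d;
  double s = 0.0;
  for (int t = 0; t < d; ++t) {
    double diff = pa[t] - pb[t];
    s += diff * diff;
  }
  return s;
}

// Exact brute-force kNN of each query among the training columns.
// self_idx[q] is the 0-based training index of query q (excluded from its
// own neighbour list), or -1. Distance ties break towards the lower index
// via lexicographic (distance, index) ordering. Returns 1-based indices.
// [[Rcpp::export]]
IntegerMatrix knn_brute_cpp(NumericMatrix Xt_train, NumericMatrix Xt_query,
                            int k, IntegerVector self_idx) {
  const int d = Xt_train.nrow();
  const int n_train = Xt_train.ncol();
  const int n_query = Xt_query.ncol();
  if (d != Xt_query.nrow()) stop("dimension mismatch");
  if (k < 1) stop("k must be >= 1");
  IntegerMatrix out(n_query, k);
  const double* Tr = &Xt_train[0];
  const double* Qu = &Xt_query[0];
  std::vector<std::pair<double, int> > cand(n_train);
  for (int q = 0; q < n_query; ++q) {
    int m = 0;
    for (int j = 0; j < n_train; ++j) {
      if (self_idx[q] == j) continue;
      cand[m].first = sqdist(Tr, j, Qu, q, d);
      cand[m].second = j;
      ++m;
    }
    if (k > m) stop("k must be smaller than the number of candidates");
    std::partial_sort(cand.begin(), cand.begin() + k, cand.begin() + m);
    for (int t = 0; t < k; ++t) out(q, t) = cand[t].second + 1;
  }
  return out;
}

// One neighbour list per point, kept sorted by (distance, index).
struct NeighborHeap {
  std::vector<double> d;
  std::vector<int> idx;
  int k;
  void init(int k_) {
    k = k_;
    d.assign(k, R_PosInf);
    idx.assign(k, -1);
  }
  bool push(double dist, int j) {
    if (dist > d[k - 1] ||
        (dist == d[k - 1] && idx[k - 1] != -1 && j >= idx[k - 1]))
      return false;
    for (int t = 0; t < k; ++t) {
      if (idx[t] == j) return false;
    }
    int pos = k - 1;
    while (pos > 0 &&
           (d[pos - 1] > dist || (d[pos - 1] == dist && idx[pos - 1] > j))) {
      d[pos] = d[pos - 1];
      idx[pos] = idx[pos - 1];
      --pos;
    }
    d[pos] = dist;
    idx[pos] = j;
    return true;
  }
};

// NN-descent style approximate kNN: start from random neighbour lists and
// repeatedly propose neighbours-of-neighbours (forward and reverse) until
// the lists stop improving. init is an n x k matrix of 1-based random
// training indices. Returns 1-based indices.
// [[Rcpp::export]]
IntegerMatrix nn_descent_cpp(NumericMatrix Xt, IntegerMatrix init,
                             int max_iters) {
  const int d = Xt.nrow();
  const int n = Xt.ncol();
  const int k = init.ncol();
  const double* X = &Xt[0];
  std::vector<NeighborHeap> heaps(n);
  for (int i = 0; i < n; ++i) {
    heaps[i].init(k);
    for (int t = 0; t < k; ++t) {
      int j = init(i, t) - 1;
      if (j != i) heaps[i].push(sqdist(X, i, X, j, d), j);
    }
    // pad in case of collisions in the random init
    for (int j = 0; heaps[i].idx[k - 1] == -1 && j < n; ++j) {
      if (j != i) heaps[i].push(sqdist(X, i, X, j, d), j);
    }
  }
  std::vector<std::vector<int> > reverse_nb(n);
  for (int iter = 0; iter < max_iters; ++iter) {
    for (int i = 0; i < n; ++i) reverse_nb[i].clear();
    for (int i = 0; i < n; ++i)
      for (int t = 0; t < k; ++t) reverse_nb[heaps[i].idx[t]].push_back(i);
    long updates = 0;
    std::vector<int> cand;
    for (int i = 0; i < n; ++i) {
      cand.clear();
      for (int t = 0; t < k; ++t) {
        int j = heaps[i].idx[t];
        for (int s = 0; s < k; ++s) cand.push_back(heaps[j].idx[s]);
        for (size_t s = 0; s < reverse_nb[j].size(); ++s)
          cand.push_back(reverse_nb[j][s]);
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (size_t c = 0; c < cand.size(); ++c) {
        int j = cand[c];
        if (j == i) continue;
        double dist = sqdist(X, i, X, j, d);
        if (heaps[i].push(dist, j)) ++updates;
        if (heaps[j].push(dist, i)) ++updates;
      }
    }
    if (updates == 0) break;
  }
  IntegerMatrix out(n, k);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < k; ++t) out(i, t) = heaps[i].idx[t] + 1;
  return out;
}
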
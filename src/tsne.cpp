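#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Barnes-Hut quadtree over 2D points. Cells store their centre of mass and
// point count; a cell is treated as a single summary point when it is small
// relative to its distance from the query (size / distance < theta).
struct QuadTree {
  std::vector<double> cx, cy, hw;    // cell centre and half-width
  std::vector<double> mx, my;        // centre of mass
  std::vector<int> cnt;              // points in cell
  std::vector<int> child;            // 4 children per node, -1 if none
  std::vector<int> leaf_pt;          // point index for singleton leaves

  int new_node(double x, double y, double h) {
    cx.push_back(x); cy.push_back(y); hw.push_back(h);
    mx.push_back(0.0); my.push_back(0.0);
    cnt.push_back(0);
    for (int c = 0; c < 4; ++c) child.push_back(-1);
    leaf_pt.push_back(-1);
    return (int)cx.size() - 1;
  }

  int quadrant(int node, double x, double y) const {
    return (x >= cx[node] ? 1 : 0) + (y >= cy[node] ? 2 : 0);
  }

  void insert(int node, int p, const double* Y, int n, int depth) {
    double x = Y[p], y = Y[p + n];
    // update centre of mass
    double c = (double)cnt[node];
    mx[node] = (mx[node] * c + x) / (c + 1.0);
    my[node] = (my[node] * c + y) / (c + 1.0);
    cnt[node] += 1;
    if (cnt[node] == 1) {            // empty leaf takes the point
      leaf_pt[node] = p;
      return;
    }
    if (depth > 64) return;          // coincident points: keep aggregated
    if (leaf_pt[node] >= 0) {        // split occupied leaf
      int q = leaf_pt[node];
      leaf_pt[node] = -1;
      push_down(node, q, Y, n, depth);
    }
    push_down(node, p, Y, n, depth);
  }

  void push_down(int node, int p, const double* Y, int n, int depth) {
    double x = Y[p], y = Y[p + n];
    int q = quadrant(node, x, y);
    if (child[4 * node + q] < 0) {
      double h = hw[node] / 2.0;
      double nx = cx[node] + (q & 1 ? h : -h);
      double ny = cy[node] + (q & 2 ? h : -h);
      int idx = new_node(nx, ny, h);
      child[4 * node + q] = idx;
    }
    insert(child[4 * node + q], p, Y, n, depth + 1);
  }

  // Accumulate repulsive force on point p and the partition function Z.
  void force(int node, int p, const double* Y, int n, double theta,
             double* fx, double* fy, double* Z) const {
    if (cnt[node] == 0) return;
    if (cnt[node] == 1 && leaf_pt[node] == p) return;  // self
    double dx = Y[p] - mx[node];
    double dy = Y[p + n] - my[node];
    double d2 = dx * dx + dy * dy;
    bool is_summary = (leaf_pt[node] >= 0) ||
      (4.0 * hw[node] * hw[node] < theta * theta * d2);
    if (is_summary) {
      double w = 1.0 / (1.0 + d2);
      double m = (double)cnt[node];
      *Z += m * w;
      *fx += m * w * w * dx;
      *fy += m * w * w * dy;
      return;
    }
    bool has_child = false;
    for (int c = 0; c < 4; ++c) {
      int ch = child[4 * node + c];
      if (ch >= 0) {
        has_child = true;
        force(ch, p, Y, n, theta, fx, fy, Z);
      }
    }
    if (!has_child) {                // depth-capped aggregate of points
      double w = 1.0 / (1.0 + d2);
      double m = (double)cnt[node];
      *Z += m * w;
      *fx += m * w * w * dx;
      *fy += m * w * w * dy;
    }
  }
};

// t-SNE gradient descent on the KL divergence between a fixed sparse
// affinity matrix P (stored as 0-based triplets, both (i,j) and (j,i)
// present, summing to 1) and the Student-t kernel over 2D distances.
// The attractive term is multiplied by exaggeration[iter]; momentum and
// per-coordinate gains follow the standard optimizer. theta <= 0 selects
// exact O(n^2) repulsion, theta > 0 Barnes-Hut approximation.
// Returns the embedding and the KL trace: kl[t] is the (unexaggerated) KL
// at the start of iteration t, with one final entry for the end state.
// [[Rcpp::export]]
List tsne_run_cpp(IntegerVector Pi, IntegerVector Pj, NumericVector Pv,
                  NumericMatrix Y0, NumericVector exaggeration,
                  double learning_rate, NumericVector momentum,
                  double theta) {
  const int n = Y0.nrow();
  const int iters = exaggeration.size();
  const R_xlen_t nnz = Pv.size();
  if (momentum.size() != iters) stop("momentum length must match schedule");

  std::vector<double> Y(Y0.begin(), Y0.end());       // n x 2 column-major
  std::vector<double> uY(2 * n, 0.0), gains(2 * n, 1.0);
  std::vector<double> attr(2 * n), rep(2 * n), grad(2 * n);
  NumericVector kl(iters + 1);

  double sum_p_log_p = 0.0;
  for (R_xlen_t e = 0; e < nnz; ++e)
    if (Pv[e] > 0) sum_p_log_p += Pv[e] * std::log(Pv[e]);

  for (int iter = 0; iter <= iters; ++iter) {
    std::fill(attr.begin(), attr.end(), 0.0);
    std::fill(rep.begin(), rep.end(), 0.0);
    double Z = 0.0, sum_p_log_w = 0.0;

    // attractive forces over the sparse support
    for (R_xlen_t e = 0; e < nnz; ++e) {
      int i = Pi[e], j = Pj[e];
      double dx = Y[i] - Y[j];
      double dy = Y[i + n] - Y[j + n];
      double w = 1.0 / (1.0 + dx * dx + dy * dy);
      double coef = Pv[e] * w;
      attr[i] += coef * dx;
      attr[i + n] += coef * dy;
      sum_p_log_w += Pv[e] * std::log(w);
    }

    // repulsive forces and partition function
    if (theta <= 0.0) {
      for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
          double dx = Y[i] - Y[j];
          double dy = Y[i + n] - Y[j + n];
          double w = 1.0 / (1.0 + dx * dx + dy * dy);
          double w2 = w * w;
          Z += 2.0 * w;
          rep[i] += w2 * dx;
          rep[i + n] += w2 * dy;
          rep[j] -= w2 * dx;
          rep[j + n] -= w2 * dy;
        }
      }
    } else {
      double xmin = Y[0], xmax = Y[0], ymin = Y[n], ymax = Y[n];
      for (int i = 1; i < n; ++i) {
        xmin = std::min(xmin, Y[i]); xmax = std::max(xmax, Y[i]);
        ymin = std::min(ymin, Y[i + n]); ymax = std::max(ymax, Y[i + n]);
      }
      QuadTree qt;
      double h = std::max(xmax - xmin, ymax - ymin) / 2.0 + 1e-9;
      int root = qt.new_node((xmin + xmax) / 2.0, (ymin + ymax) / 2.0, h);
      qt.cx.reserve(4 * n); // avoid repeated reallocation
      for (int i = 0; i < n; ++i) qt.insert(root, i, Y.data(), n, 0);
      for (int i = 0; i < n; ++i) {
        double fx = 0.0, fy = 0.0;
        qt.force(root, i, Y.data(), n, theta, &fx, &fy, &Z);
        rep[i] = fx;
        rep[i + n] = fy;
      }
    }

    kl[iter] = sum_p_log_p - sum_p_log_w + std::log(Z);
    if (iter == iters) break;

    double rho = exaggeration[iter];
    double mom = momentum[iter];
    for (int c = 0; c < 2 * n; ++c) {
      grad[c] = 4.0 * (rho * attr[c] - rep[c] / Z);
      bool same_sign = (grad[c] > 0) == (uY[c] > 0);
      gains[c] = same_sign ? gains[c] * 0.8 : gains[c] + 0.2;
      if (gains[c] < 0.01) gains[c] = 0.01;
      uY[c] = mom * uY[c] - learning_rate * gains[c] * grad[c];
    }
    double mxm = 0.0, mym = 0.0;
    for (int i = 0; i < n; ++i) {
      Y[i] += uY[i];
      Y[i + n] += uY[i + n];
      mxm += Y[i];
      mym += Y[i + n];
    }
    mxm /= n; mym /= n;
    for (int i = 0; i < n; ++i) {  // keep the embedding centred
      Y[i] -= mxm;
      Y[i + n] -= mym;
    }
    if (iter % 100 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix Yout(n, 2);
  std::copy(Y.begin(), Y.end(), Yout.begin());
  return List::create(_["Y"] = Yout, _["kl"] = kl);
}
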
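#include <Rcpp.h>
using namespace Rcpp;

// Count, for every unordered pair of distinct genes, the number of molecule
// pairs closer than r (3D Euclidean). pts: n x 3 matrix (micrometres).
// gene: 1-based gene index per molecule. Returns ngene x ngene matrix with
// counts in the upper triangle (i < j); diagonal holds same-gene pair counts
// (callers exclude them by design).
// [[Rcpp::export]]
IntegerMatrix cpp_pair_counts(const NumericMatrix& pts, const IntegerVector& gene,
                              int ngene, double r) {
  const int n = pts.nrow();
  const double r2 = r * r;
  IntegerMatrix out(ngene, ngene);
  for (int i = 0; i < n - 1; ++i) {
    const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    const int gi = gene[i] - 1;
    for (int j = i + 1; j < n; ++j) {
      const double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      if (dx * dx + dy * dy + dz * dz <= r2) {
        int gj = gene[j] - 1;
        int a = gi < gj ? gi : gj, b = gi < gj ? gj : gi;
        out(a, b) += 1;
      }
    }
  }
  return out;
}

// Cumulative count of ordered point pairs with distance <= radii[k].
// radii must be sorted ascending. Used by the Ripley K estimator:
// K(r) = V / (n (n-1)) * count(r).
// [[Rcpp::export]]
NumericVector cpp_k_counts(const NumericMatrix& pts, const NumericVector& radii) {
  const int n = pts.nrow(), m = radii.size();
  NumericVector out(m);
  for (int i = 0; i < n - 1; ++i) {
    const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      // binary search for first radius >= d
      int lo = 0, hi = m;
      while (lo < hi) { int mid = (lo + hi) / 2; if (radii[mid] < d) lo = mid + 1; else hi = mid; }
      for (int k = lo; k < m; ++k) out[k] += 2.0; // ordered pairs
    }
  }
  return out;
}

// All pairwise 3D distances (upper triangle, row-major order), for small n.
// [[Rcpp::export]]
NumericVector cpp_pdist3(const NumericMatrix& pts) {
  const int n = pts.nrow();
  const R_xlen_t np = (R_xlen_t)n * (n - 1) / 2;
  NumericVector out(np);
  R_xlen_t k = 0;
  for (int i = 0; i < n - 1; ++i) {
    const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      out[k++] = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }
  return out;
}

static inline int nb(const LogicalMatrix& img, int x, int y) {
  return img(x, y) ? 1 : 0;
}

// Zhang-Suen thinning of a binary mask (first index x, second y, 1 px border
// assumed clear by caller padding). Returns the topological skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_zhang_suen(LogicalMatrix img) {
  const int nx = img.nrow(), ny = img.ncol();
  LogicalMatrix cur = clone(img);
  bool changed = true;
  std::vector<std::pair<int,int> > kill;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int x = 1; x < nx - 1; ++x) {
        for (int y = 1; y < ny - 1; ++y) {
          if (!cur(x, y)) continue;
          // neighbours P2..P9 clockwise from north (y-1)
          int p2 = nb(cur, x,     y - 1), p3 = nb(cur, x + 1, y - 1);
          int p4 = nb(cur, x + 1, y),     p5 = nb(cur, x + 1, y + 1);
          int p6 = nb(cur, x,     y + 1), p7 = nb(cur, x - 1, y + 1);
          int p8 = nb(cur, x - 1, y),     p9 = nb(cur, x - 1, y - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(x, y));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k) cur(kill[k].first, kill[k].second) = false;
    }
  }
  return cur;
}

// 8-connected component labeling of a logical matrix (flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& img) {
  const int nx = img.nrow(), ny = img.ncol();
  IntegerMatrix lab(nx, ny);
  int next = 0;
  std::vector<std::pair<int,int> > stack;
  for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y) {
    if (!img(x, y) || lab(x, y)) continue;
    ++next;
    stack.push_back(std::make_pair(x, y));
    lab(x, y) = next;
    while (!stack.empty()) {
      std::pair<int,int> p = stack.back(); stack.pop_back();
      for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy) {
        if (!dx && !dy) continue;
        int qx = p.first + dx, qy = p.second + dy;
        if (qx < 0 || qy < 0 || qx >= nx || qy >= ny) continue;
        if (img(qx, qy) && !lab(qx, qy)) {
          lab(qx, qy) = next;
          stack.push_back(std::make_pair(qx, qy));
        }
      }
    }
  }
  return lab;
}
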
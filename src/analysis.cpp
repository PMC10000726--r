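#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Marching-squares contour of img (nx x ny, pixel spacing `pitch` in mm) at
// level `iso`, with linear interpolation along cell edges. Returns total
// contour length and the mean distance of contour-segment midpoints to the
// reference point (cx, cy) given in the same mm frame (pixel (i,j) sits at
// (i*pitch, j*pitch), 0-based).
// [[Rcpp::export]]
List cpp_marching_squares(NumericMatrix img, double iso, double pitch,
                          double cx, double cy) {
  int nx = img.nrow(), ny = img.ncol();
  double per = 0.0, rsum = 0.0;
  int nseg = 0;
  auto interp = [&](double va, double vb) { return (iso - va) / (vb - va); };
  for (int j = 0; j < ny - 1; ++j) {
    for (int i = 0; i < nx - 1; ++i) {
      double v00 = img(i, j), v10 = img(i + 1, j);
      double v11 = img(i + 1, j + 1), v01 = img(i, j + 1);
      int c = (v00 > iso) | ((v10 > iso) << 1) | ((v11 > iso) << 2) |
              ((v01 > iso) << 3);
      if (c == 0 || c == 15) continue;
      // edge crossing points in mm (edges: bottom, right, top, left)
      double ex[4], ey[4];
      bool has[4] = {false, false, false, false};
      if ((v00 > iso) != (v10 > iso)) {
        has[0] = true;
        ex[0] = (i + interp(v00, v10)) * pitch;
        ey[0] = j * pitch;
      }
      if ((v10 > iso) != (v11 > iso)) {
        has[1] = true;
        ex[1] = (i + 1) * pitch;
        ey[1] = (j + interp(v10, v11)) * pitch;
      }
      if ((v01 > iso) != (v11 > iso)) {
        has[2] = true;
        ex[2] = (i + interp(v01, v11)) * pitch;
        ey[2] = (j + 1) * pitch;
      }
      if ((v00 > iso) != (v01 > iso)) {
        has[3] = true;
        ex[3] = i * pitch;
        ey[3] = (j + interp(v00, v01)) * pitch;
      }
      int pts[4], np = 0;
      for (int e = 0; e < 4; ++e)
        if (has[e]) pts[np++] = e;
      auto addseg = [&](int a, int b) {
        double dx = ex[a] - ex[b], dy = ey[a] - ey[b];
        per += std::sqrt(dx * dx + dy * dy);
        double mx = 0.5 * (ex[a] + ex[b]) - cx;
        double my = 0.5 * (ey[a] + ey[b]) - cy;
        rsum += std::sqrt(mx * mx + my * my);
        ++nseg;
      };
      if (np == 2) {
        addseg(pts[0], pts[1]);
      } else if (np == 4) { // saddle: split by cell-center value
        double vc = 0.25 * (v00 + v10 + v11 + v01);
        if ((vc > iso) == (v00 > iso)) {
          addseg(0, 1);
          addseg(2, 3);
        } else {
          addseg(0, 3);
          addseg(1, 2);
        }
      }
    }
  }
  return List::create(_["perimeter"] = per,
                      _["mean_radius"] = nseg ? rsum / nseg : NA_REAL,
                      _["n_segments"] = nseg);
}

// Exact weighted 1-D k-means by dynamic programming over sorted unique
// values. x must be sorted ascending, w > 0. Returns cluster index (1-based)
// per value, centroids, and total within-cluster weighted SSE.
// [[Rcpp::export]]
List cpp_kmeans1d(NumericVector x, NumericVector w, int k) {
  int n = x.size();
  if (k > n) stop("k exceeds number of distinct values");
  // prefix sums
  std::vector<double> cw(n + 1, 0.0), cwx(n + 1, 0.0), cwx2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cw[i + 1] = cw[i] + w[i];
    cwx[i + 1] = cwx[i] + w[i] * x[i];
    cwx2[i + 1] = cwx2[i] + w[i] * x[i] * x[i];
  }
  auto cost = [&](int a, int b) { // values a..b inclusive, 0-based
    double W = cw[b + 1] - cw[a];
    double S = cwx[b + 1] - cwx[a];
    double S2 = cwx2[b + 1] - cwx2[a];
    double c = S2 - S * S / W;
    return c > 0 ? c : 0.0;
  };
  std::vector<std::vector<double>> D(k + 1,
                                     std::vector<double>(n + 1, INFINITY));
  std::vector<std::vector<int>> B(k + 1, std::vector<int>(n + 1, 0));
  D[0][0] = 0.0;
  for (int m = 1; m <= k; ++m) {
    for (int i = m; i <= n; ++i) {
      // last cluster covers values j..i-1 (0-based), j >= m-1
      for (int j = m - 1; j <= i - 1; ++j) {
        double v = D[m - 1][j] + cost(j, i - 1);
        if (v < D[m][i]) {
          D[m][i] = v;
          B[m][i] = j;
        }
      }
    }
  }
  IntegerVector cl(n);
  NumericVector centers(k);
  int end = n;
  for (int m = k; m >= 1; --m) {
    int start = B[m][end];
    double W = cw[end] - cw[start];
    centers[m - 1] = (cwx[end] - cwx[start]) / W;
    for (int i = start; i < end; ++i) cl[i] = m;
    end = start;
  }
  return List::create(_["cluster"] = cl, _["centers"] = centers,
                      _["sse"] = D[k][n]);
}
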
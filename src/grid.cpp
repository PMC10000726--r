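#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Arrays are R arrays dim (nx, ny, nz), column-major, 0-based linear index
// idx = i + nx*(j + ny*k). World coords: x = origin + index * spacing
// (voxel-center convention, axis-aligned grids only).

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long)ny * k);
}

// ---------------------------------------------------------------------------
// separable Gaussian smoothing, reflected boundaries, sigma in voxels per axis
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector arr, IntegerVector dim,
                          NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(arr.begin(), arr.end());
  std::vector<double> b(a.size());
  int n[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 1e-8) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; ++t) {
      ker[t + r] = std::exp(-0.5 * t * t / (s * s));
      sum += ker[t + r];
    }
    for (auto &v : ker) v /= sum;
    int len = n[ax];
    for (long idx = 0; idx < (long)a.size(); ++idx) {
      int i = idx % nx, j = (idx / nx) % ny, k = idx / ((long)nx * ny);
      int pos[3] = {i, j, k};
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int p = pos[ax] + t;
        if (p < 0) p = -p - 1;            // reflect
        if (p >= len) p = 2 * len - p - 1;
        if (p < 0) p = 0;
        if (p >= len) p = len - 1;
        int q[3] = {i, j, k};
        q[ax] = p;
        acc += ker[t + r] * a[lin(q[0], q[1], q[2], nx, ny)];
      }
      b[idx] = acc;
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher) with
// feature (nearest seed voxel) tracking. mask: nonzero = seed set.
// Returns dist (mm) and 1-based linear index of nearest seed.

static void edt1d(const std::vector<double> &f, std::vector<double> &d,
                  std::vector<int> &arg, double step) {
  int n = f.size();
  // positions with finite parabola
  std::vector<int> pos;
  pos.reserve(n);
  for (int q = 0; q < n; ++q)
    if (std::isfinite(f[q])) pos.push_back(q);
  if (pos.empty()) {
    for (int q = 0; q < n; ++q) { d[q] = INFINITY; arg[q] = 0; }
    return;
  }
  std::vector<int> v(pos.size());
  std::vector<double> z(pos.size() + 1);
  int k = 0;
  v[0] = pos[0];
  z[0] = -INFINITY;
  z[1] = INFINITY;
  double st2 = step * step;
  for (size_t m = 1; m < pos.size(); ++m) {
    int q = pos[m];
    double s;
    while (true) {
      s = ((f[q] + (double)q * q * st2) -
           (f[v[k]] + (double)v[k] * v[k] * st2)) /
          (2.0 * st2 * (q - v[k]));
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    if (s <= z[k] && k == 0) {
      v[0] = q;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
    }
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]) * step;
    d[q] = dq * dq + f[v[k]];
    arg[q] = v[k];
  }
}

// [[Rcpp::export]]
List cpp_edt(IntegerVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long ntot = (long)nx * ny * nz;
  std::vector<double> D(ntot);
  std::vector<int> F(ntot); // linear index of nearest seed
  bool any = false;
  for (long idx = 0; idx < ntot; ++idx) {
    if (mask[idx]) { D[idx] = 0.0; F[idx] = idx; any = true; }
    else { D[idx] = INFINITY; F[idx] = -1; }
  }
  if (!any) {
    NumericVector dist(ntot, R_PosInf);
    dist.attr("dim") = dim;
    IntegerVector feat(ntot, NA_INTEGER);
    feat.attr("dim") = dim;
    return List::create(_["dist"] = dist, _["feature"] = feat);
  }
  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    std::vector<int> a(nx);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) f[i] = D[lin(i, j, k, nx, ny)];
        edt1d(f, d, a, spacing[0]);
        for (int i = 0; i < nx; ++i) {
          long idx = lin(i, j, k, nx, ny);
          D[idx] = d[i];
          F[idx] = (f[a[i]] == INFINITY) ? -1 : lin(a[i], j, k, nx, ny);
        }
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    std::vector<int> a(ny);
    std::vector<int> feat(ny);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) {
          long idx = lin(i, j, k, nx, ny);
          f[j] = D[idx];
          feat[j] = F[idx];
        }
        edt1d(f, d, a, spacing[1]);
        for (int j = 0; j < ny; ++j) {
          long idx = lin(i, j, k, nx, ny);
          D[idx] = d[j];
          F[idx] = feat[a[j]];
        }
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    std::vector<int> a(nz);
    std::vector<int> feat(nz);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k) {
          long idx = lin(i, j, k, nx, ny);
          f[k] = D[idx];
          feat[k] = F[idx];
        }
        edt1d(f, d, a, spacing[2]);
        for (int k = 0; k < nz; ++k) {
          long idx = lin(i, j, k, nx, ny);
          D[idx] = d[k];
          F[idx] = feat[a[k]];
        }
      }
  }
  NumericVector dist(ntot);
  IntegerVector feat(ntot);
  for (long idx = 0; idx < ntot; ++idx) {
    dist[idx] = std::sqrt(D[idx]);
    feat[idx] = F[idx] + 1; // 1-based for R
  }
  dist.attr("dim") = dim;
  feat.attr("dim") = dim;
  return List::create(_["dist"] = dist, _["feature"] = feat);
}

// ---------------------------------------------------------------------------
// trilinear sampling of a scalar volume at world points (N x 3, mm)
// outside: value `outside` (if finite) or clamped border sampling (clamp=TRUE)
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dim,
                                   NumericVector spacing, NumericVector origin,
                                   NumericMatrix pts, double outside,
                                   bool clamp) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int npt = pts.nrow();
  NumericVector out(npt);
  for (int p = 0; p < npt; ++p) {
    double x = (pts(p, 0) - origin[0]) / spacing[0];
    double y = (pts(p, 1) - origin[1]) / spacing[1];
    double z = (pts(p, 2) - origin[2]) / spacing[2];
    if (!clamp && (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 ||
                   z > nz - 1)) {
      out[p] = outside;
      continue;
    }
    if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
    if (x > nx - 1) x = nx - 1;
    if (y > ny - 1) y = ny - 1;
    if (z > nz - 1) z = nz - 1;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
        k0 = (int)std::floor(z);
    if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
    if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
    if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double acc = 0.0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                     (dk ? fz : 1 - fz);
          acc += w * vol[lin(i0 + di, j0 + dj, k0 + dk, nx, ny)];
        }
    out[p] = acc;
  }
  return out;
}

// nearest-voxel sampling of an integer volume (labels) at world points
// [[Rcpp::export]]
IntegerVector cpp_sample_nearest(IntegerVector vol, IntegerVector dim,
                                 NumericVector spacing, NumericVector origin,
                                 NumericMatrix pts, int outside) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int npt = pts.nrow();
  IntegerVector out(npt);
  for (int p = 0; p < npt; ++p) {
    int i = (int)std::lround((pts(p, 0) - origin[0]) / spacing[0]);
    int j = (int)std::lround((pts(p, 1) - origin[1]) / spacing[1]);
    int k = (int)std::lround((pts(p, 2) - origin[2]) / spacing[2]);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
      out[p] = outside;
    else
      out[p] = vol[lin(i, j, k, nx, ny)];
  }
  return out;
}

// ---------------------------------------------------------------------------
// displacement field (three arrays on one grid) evaluated at world points
// by trilinear interpolation; border-clamped outside.
static inline void field_at(const double *dx, const double *dy,
                            const double *dz, int nx, int ny, int nz,
                            const double *sp, const double *org, double px,
                            double py, double pz, double *out) {
  double x = (px - org[0]) / sp[0];
  double y = (py - org[1]) / sp[1];
  double z = (pz - org[2]) / sp[2];
  if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
  if (x > nx - 1) x = nx - 1;
  if (y > ny - 1) y = ny - 1;
  if (z > nz - 1) z = nz - 1;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
  if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
  if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  out[0] = out[1] = out[2] = 0.0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        double w =
            (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        long idx = lin(i0 + di, j0 + dj, k0 + dk, nx, ny);
        out[0] += w * dx[idx];
        out[1] += w * dy[idx];
        out[2] += w * dz[idx];
      }
}

// [[Rcpp::export]]
NumericMatrix cpp_field_at(NumericVector dx, NumericVector dy, NumericVector dz,
                           IntegerVector dim, NumericVector spacing,
                           NumericVector origin, NumericMatrix pts) {
  int npt = pts.nrow();
  NumericMatrix out(npt, 3);
  double d[3];
  for (int p = 0; p < npt; ++p) {
    field_at(dx.begin(), dy.begin(), dz.begin(), dim[0], dim[1], dim[2],
             spacing.begin(), origin.begin(), pts(p, 0), pts(p, 1), pts(p, 2),
             d);
    out(p, 0) = d[0];
    out(p, 1) = d[1];
    out(p, 2) = d[2];
  }
  return out;
}

// fixed-point inversion: find x with x + d(x) = q, start x0 = q
// [[Rcpp::export]]
List cpp_invert_field(NumericVector dx, NumericVector dy, NumericVector dz,
                      IntegerVector dim, NumericVector spacing,
                      NumericVector origin, NumericMatrix q, double tol,
                      int maxit) {
  int npt = q.nrow();
  NumericMatrix x(npt, 3);
  NumericVector resid(npt);
  IntegerVector iters(npt);
  double d[3];
  for (int p = 0; p < npt; ++p) {
    double xx = q(p, 0), xy = q(p, 1), xz = q(p, 2);
    double r = R_PosInf;
    int it = 0;
    for (it = 0; it < maxit; ++it) {
      field_at(dx.begin(), dy.begin(), dz.begin(), dim[0], dim[1], dim[2],
               spacing.begin(), origin.begin(), xx, xy, xz, d);
      double nx2 = q(p, 0) - d[0], ny2 = q(p, 1) - d[1], nz2 = q(p, 2) - d[2];
      r = std::sqrt((nx2 - xx) * (nx2 - xx) + (ny2 - xy) * (ny2 - xy) +
                    (nz2 - xz) * (nz2 - xz));
      xx = nx2; xy = ny2; xz = nz2;
      if (r < tol) break;
    }
    x(p, 0) = xx; x(p, 1) = xy; x(p, 2) = xz;
    // residual of the inverse contract |x + d(x) - q|
    field_at(dx.begin(), dy.begin(), dz.begin(), dim[0], dim[1], dim[2],
             spacing.begin(), origin.begin(), xx, xy, xz, d);
    double rx = xx + d[0] - q(p, 0), ry = xy + d[1] - q(p, 1),
           rz = xz + d[2] - q(p, 2);
    resid[p] = std::sqrt(rx * rx + ry * ry + rz * rz);
    iters[p] = it + 1;
  }
  return List::create(_["points"] = x, _["residual"] = resid,
                      _["iterations"] = iters);
}

// analytic sum-of-Gaussian-bumps displacement at world points
// centers K x 3, amps K x 3 (vector amplitudes, mm), scales length K (mm)
// [[Rcpp::export]]
NumericMatrix cpp_bumps_at(NumericMatrix pts, NumericMatrix centers,
                           NumericMatrix amps, NumericVector scales) {
  int npt = pts.nrow(), K = centers.nrow();
  NumericMatrix out(npt, 3);
  for (int p = 0; p < npt; ++p) {
    double ax = 0, ay = 0, az = 0;
    for (int k = 0; k < K; ++k) {
      double ddx = pts(p, 0) - centers(k, 0);
      double ddy = pts(p, 1) - centers(k, 1);
      double ddz = pts(p, 2) - centers(k, 2);
      double w = std::exp(-0.5 * (ddx * ddx + ddy * ddy + ddz * ddz) /
                          (scales[k] * scales[k]));
      ax += amps(k, 0) * w;
      ay += amps(k, 1) * w;
      az += amps(k, 2) * w;
    }
    out(p, 0) = ax; out(p, 1) = ay; out(p, 2) = az;
  }
  return out;
}

// fixed-point inversion of the analytic bump field
// [[Rcpp::export]]
NumericMatrix cpp_invert_bumps(NumericMatrix q, NumericMatrix centers,
                               NumericMatrix amps, NumericVector scales,
                               double tol, int maxit) {
  int npt = q.nrow(), K = centers.nrow();
  NumericMatrix x(npt, 3);
  for (int p = 0; p < npt; ++p) {
    double xx = q(p, 0), xy = q(p, 1), xz = q(p, 2);
    for (int it = 0; it < maxit; ++it) {
      double ax = 0, ay = 0, az = 0;
      for (int k = 0; k < K; ++k) {
        double ddx = xx - centers(k, 0), ddy = xy - centers(k, 1),
               ddz = xz - centers(k, 2);
        double w = std::exp(-0.5 * (ddx * ddx + ddy * ddy + ddz * ddz) /
                            (scales[k] * scales[k]));
        ax += amps(k, 0) * w; ay += amps(k, 1) * w; az += amps(k, 2) * w;
      }
      double nx2 = q(p, 0) - ax, ny2 = q(p, 1) - ay, nz2 = q(p, 2) - az;
      double r = std::sqrt((nx2 - xx) * (nx2 - xx) + (ny2 - xy) * (ny2 - xy) +
                           (nz2 - xz) * (nz2 - xz));
      xx = nx2; xy = ny2; xz = nz2;
      if (r < tol) break;
    }
    x(p, 0) = xx; x(p, 1) = xy; x(p, 2) = xz;
  }
  return x;
}

// ---------------------------------------------------------------------------
// 26-connected component labeling of a nonzero mask (BFS), labels 1..ncomp
// [[Rcpp::export]]
IntegerVector cpp_components26(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long ntot = (long)nx * ny * nz;
  IntegerVector lab(ntot, 0);
  lab.attr("dim") = dim;
  int next = 0;
  std::vector<long> stack;
  for (long s = 0; s < ntot; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      long c = stack.back();
      stack.pop_back();
      int i = c % nx, j = (c / nx) % ny, k = c / ((long)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            long n = lin(ii, jj, kk, nx, ny);
            if (mask[n] && !lab[n]) {
              lab[n] = next;
              stack.push_back(n);
            }
          }
    }
  }
  return lab;
}
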
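#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline long lin3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long)ny * k);
}

// Minimum-cost voxel path on the 26-neighborhood graph.
// cost: per-voxel nonnegative value (normalized intensity); edge cost entering
// voxel v from u = ||step_mm|| * (eps + cost[v]). start/goal are 0-based
// linear indices. Returns matrix of 0-based (i,j,k) voxel indices, start->goal.
// [[Rcpp::export]]
IntegerMatrix cpp_dijkstra_path(NumericVector cost, IntegerVector dim,
                                NumericVector spacing, int start, int goal,
                                double eps) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long ntot = (long)nx * ny * nz;
  std::vector<double> dist(ntot, INFINITY);
  std::vector<long> prev(ntot, -1);
  typedef std::pair<double, long> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  dist[start] = 0.0;
  pq.push({0.0, (long)start});
  // precompute neighbor offsets and step lengths
  int off[26][3];
  double slen[26];
  int m = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (!di && !dj && !dk) continue;
        off[m][0] = di; off[m][1] = dj; off[m][2] = dk;
        slen[m] = std::sqrt(di * di * spacing[0] * spacing[0] +
                            dj * dj * spacing[1] * spacing[1] +
                            dk * dk * spacing[2] * spacing[2]);
        ++m;
      }
  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    long u = top.second;
    if (top.first > dist[u]) continue;
    if (u == (long)goal) break;
    int i = u % nx, j = (u / nx) % ny, k = u / ((long)nx * ny);
    for (int t = 0; t < 26; ++t) {
      int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      long v = lin3(ii, jj, kk, nx, ny);
      double nd = dist[u] + slen[t] * (eps + cost[v]);
      if (nd < dist[v]) {
        dist[v] = nd;
        prev[v] = u;
        pq.push({nd, v});
      }
    }
  }
  if (!std::isfinite(dist[goal])) return IntegerMatrix(0, 3);
  std::vector<long> chain;
  for (long v = goal; v != -1; v = prev[v]) chain.push_back(v);
  int n = chain.size();
  IntegerMatrix out(n, 3);
  for (int r = 0; r < n; ++r) {
    long v = chain[n - 1 - r];
    out(r, 0) = v % nx;
    out(r, 1) = (v / nx) % ny;
    out(r, 2) = v / ((long)nx * ny);
  }
  return out;
}

// distance from arbitrary points to a polyline (point-to-segment), plus the
// arc-length position of the closest projection.
// path: n x 3 (mm), arc: cumulative arc length at each vertex (mm).
// [[Rcpp::export]]
List cpp_points_polyline(NumericMatrix pts, NumericMatrix path,
                         NumericVector arc) {
  int npt = pts.nrow(), n = path.nrow();
  NumericVector dist(npt), arcpos(npt);
  IntegerVector nearest(npt); // 1-based index of nearest vertex
  LogicalVector interior(npt); // FALSE when projection clamps at an end
  for (int p = 0; p < npt; ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double best = INFINITY, bestArc = 0.0;
    int bestV = 1;
    bool bestInt = true;
    for (int s = 0; s < n - 1; ++s) {
      double ax = path(s, 0), ay = path(s, 1), az = path(s, 2);
      double bx = path(s + 1, 0), by = path(s + 1, 1), bz = path(s + 1, 2);
      double ux = bx - ax, uy = by - ay, uz = bz - az;
      double L2 = ux * ux + uy * uy + uz * uz;
      double traw = 0.0;
      if (L2 > 0)
        traw = ((px - ax) * ux + (py - ay) * uy + (pz - az) * uz) / L2;
      double t = traw;
      if (t < 0) t = 0;
      if (t > 1) t = 1;
      double cx = ax + t * ux, cy = ay + t * uy, cz = az + t * uz;
      double d2 = (px - cx) * (px - cx) + (py - cy) * (py - cy) +
                  (pz - cz) * (pz - cz);
      if (d2 < best) {
        best = d2;
        bestArc = arc[s] + t * (arc[s + 1] - arc[s]);
        bestV = (t > 0.5) ? s + 2 : s + 1;
        bestInt = !((s == 0 && traw < -1e-12) ||
                    (s == n - 2 && traw > 1 + 1e-12));
      }
    }
    if (n == 1) {
      double d2 = (px - path(0, 0)) * (px - path(0, 0)) +
                  (py - path(0, 1)) * (py - path(0, 1)) +
                  (pz - path(0, 2)) * (pz - path(0, 2));
      best = d2;
      bestArc = 0.0;
      bestV = 1;
    }
    dist[p] = std::sqrt(best);
    arcpos[p] = bestArc;
    nearest[p] = bestV;
    interior[p] = bestInt;
  }
  return List::create(_["dist"] = dist, _["arc"] = arcpos,
                      _["nearest"] = nearest, _["interior"] = interior);
}

// same but over all voxel centers of a grid; returns dist / arc arrays
// [[Rcpp::export]]
List cpp_grid_polyline(IntegerVector dim, NumericVector spacing,
                       NumericVector origin, NumericMatrix path,
                       NumericVector arc) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = path.nrow();
  long ntot = (long)nx * ny * nz;
  NumericVector dist(ntot), arcpos(ntot);
  LogicalVector interior(ntot);
  // coarse culling: bounding boxes per segment chunk would help; plain loop
  // is fast enough at desk scale.
  for (int k = 0; k < nz; ++k) {
    double pz = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double py = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i) {
        double px = origin[0] + i * spacing[0];
        double best = INFINITY, bestArc = 0.0;
        bool bestInt = true;
        for (int s = 0; s < n - 1; ++s) {
          double ax = path(s, 0), ay = path(s, 1), az = path(s, 2);
          double ux = path(s + 1, 0) - ax, uy = path(s + 1, 1) - ay,
                 uz = path(s + 1, 2) - az;
          double L2 = ux * ux + uy * uy + uz * uz;
          double traw = 0.0;
          if (L2 > 0)
            traw = ((px - ax) * ux + (py - ay) * uy + (pz - az) * uz) / L2;
          double t = traw;
          if (t < 0) t = 0;
          if (t > 1) t = 1;
          double cx = ax + t * ux, cy = ay + t * uy, cz = az + t * uz;
          double d2 = (px - cx) * (px - cx) + (py - cy) * (py - cy) +
                      (pz - cz) * (pz - cz);
          if (d2 < best) {
            best = d2;
            bestArc = arc[s] + t * (arc[s + 1] - arc[s]);
            bestInt = !((s == 0 && traw < -1e-12) ||
                        (s == n - 2 && traw > 1 + 1e-12));
          }
        }
        long idx = lin3(i, j, k, nx, ny);
        dist[idx] = std::sqrt(best);
        arcpos[idx] = bestArc;
        interior[idx] = bestInt;
      }
    }
  }
  dist.attr("dim") = dim;
  arcpos.attr("dim") = dim;
  interior.attr("dim") = dim;
  return List::create(_["dist"] = dist, _["arc"] = arcpos,
                      _["interior"] = interior);
}
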
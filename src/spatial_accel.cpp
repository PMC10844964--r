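#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher 2012),
// squared distances in pixel units to the nearest TRUE ("feature") pixel.
// ---------------------------------------------------------------------------

static const double DT_INF = 1e30;

// 1-D squared distance transform under the lower envelope of parabolas.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix edt_sq(LogicalMatrix feature) {
  int nr = feature.nrow(), nc = feature.ncol();
  NumericMatrix out(nr, nc);
  int nmax = std::max(nr, nc);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass 1: along columns
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = feature(i, j) ? 0.0 : DT_INF;
    dt1d(f, d, v, z, nr);
    for (int i = 0; i < nr; ++i) out(i, j) = d[i];
  }
  // pass 2: along rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = out(i, j);
    dt1d(f, d, v, z, nc);
    for (int j = 0; j < nc; ++j) out(i, j) = d[j];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Uniform-grid spatial index over target points.
// ---------------------------------------------------------------------------

struct PointGrid {
  double x0, y0, h;
  int nx, ny;
  std::vector<int> start;   // CSR offsets, length nx*ny + 1
  std::vector<int> idx;     // target indices ordered by cell

  void build(const NumericVector &x, const NumericVector &y, double cell) {
    int n = x.size();
    double xmin = DT_INF, xmax = -DT_INF, ymin = DT_INF, ymax = -DT_INF;
    for (int i = 0; i < n; ++i) {
      if (x[i] < xmin) xmin = x[i];
      if (x[i] > xmax) xmax = x[i];
      if (y[i] < ymin) ymin = y[i];
      if (y[i] > ymax) ymax = y[i];
    }
    h = cell > 0 ? cell : 1.0;
    x0 = xmin; y0 = ymin;
    nx = std::max(1, (int)std::floor((xmax - xmin) / h) + 1);
    ny = std::max(1, (int)std::floor((ymax - ymin) / h) + 1);
    std::vector<int> count(nx * ny, 0);
    std::vector<int> cellof(n);
    for (int i = 0; i < n; ++i) {
      int cx = std::min(nx - 1, std::max(0, (int)std::floor((x[i] - x0) / h)));
      int cy = std::min(ny - 1, std::max(0, (int)std::floor((y[i] - y0) / h)));
      cellof[i] = cy * nx + cx;
      count[cellof[i]]++;
    }
    start.assign(nx * ny + 1, 0);
    for (int c = 0; c < nx * ny; ++c) start[c + 1] = start[c] + count[c];
    idx.assign(n, 0);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) idx[fill[cellof[i]]++] = i;
  }
};

// Nearest-neighbour distances from (xf, yf) to (xt, yt), excluding for each
// query the (1-based) target index in `exclude` (0 = none).  Exact: ring
// search stops only when no unvisited ring can beat the current best.
// [[Rcpp::export]]
NumericVector nn_dist_grid(NumericVector xf, NumericVector yf,
                           NumericVector xt, NumericVector yt,
                           IntegerVector exclude) {
  int nf = xf.size(), nt = xt.size();
  NumericVector out(nf);
  if (nt == 0) {
    std::fill(out.begin(), out.end(), R_PosInf);
    return out;
  }
  // heuristic cell size: ~2 points per cell on average
  double xmin = *std::min_element(xt.begin(), xt.end());
  double xmax = *std::max_element(xt.begin(), xt.end());
  double ymin = *std::min_element(yt.begin(), yt.end());
  double ymax = *std::max_element(yt.begin(), yt.end());
  double area = std::max(1e-9, (xmax - xmin) * (ymax - ymin));
  double h = std::sqrt(2.0 * area / nt);
  if (!(h > 0) || !std::isfinite(h)) h = 1.0;
  PointGrid g;
  g.build(xt, yt, h);

  int maxring = g.nx + g.ny + 2;
  for (int q = 0; q < nf; ++q) {
    double px = xf[q], py = yf[q];
    int excl = exclude.size() == nf ? exclude[q] - 1 : -1;
    int cx = std::min(g.nx - 1, std::max(0, (int)std::floor((px - g.x0) / g.h)));
    int cy = std::min(g.ny - 1, std::max(0, (int)std::floor((py - g.y0) / g.h)));
    double best = R_PosInf;
    for (int r = 0; r <= maxring; ++r) {
      if (R_FINITE(best) && r >= 2) {
        // any cell in ring r is at least (r-1)*h away from the query cell,
        // minus the query's offset inside its own cell (bounded by h)
        double lower = (double)(r - 2) * g.h;
        if (lower > 0 && lower * lower > best) break;
      }
      int jlo = cy - r, jhi = cy + r, ilo = cx - r, ihi = cx + r;
      for (int gy = jlo; gy <= jhi; ++gy) {
        if (gy < 0 || gy >= g.ny) continue;
        bool edge_row = (gy == jlo || gy == jhi);
        int step = edge_row ? 1 : (ihi - ilo == 0 ? 1 : ihi - ilo);
        for (int gx = ilo; gx <= ihi; gx += step) {
          if (gx < 0 || gx >= g.nx) continue;
          int c = gy * g.nx + gx;
          for (int s = g.start[c]; s < g.start[c + 1]; ++s) {
            int t = g.idx[s];
            if (t == excl) continue;
            double dx = xt[t] - px, dy = yt[t] - py;
            double d2 = dx * dx + dy * dy;
            if (d2 < best) best = d2;
          }
          if (step == 0) break;
        }
      }
    }
    out[q] = std::sqrt(best);
  }
  return out;
}

// Count, for each reference cell, the partner cells whose centroid distance
// is <= r_ref + r_partner + slack.  `exclude` as in nn_dist_grid.
// [[Rcpp::export]]
IntegerVector radius_count_grid(NumericVector xr, NumericVector yr,
                                NumericVector rr, NumericVector xp,
                                NumericVector yp, NumericVector rp,
                                double slack, IntegerVector exclude) {
  int nr = xr.size(), np = xp.size();
  IntegerVector out(nr);
  if (np == 0) return out;
  double rrmax = *std::max_element(rr.begin(), rr.end());
  double rpmax = *std::max_element(rp.begin(), rp.end());
  double tmax = rrmax + rpmax + slack;
  if (!(tmax > 0)) tmax = 1.0;
  PointGrid g;
  g.build(xp, yp, tmax);
  for (int q = 0; q < nr; ++q) {
    double px = xr[q], py = yr[q];
    int excl = exclude.size() == nr ? exclude[q] - 1 : -1;
    int cx = (int)std::floor((px - g.x0) / g.h);
    int cy = (int)std::floor((py - g.y0) / g.h);
    int cnt = 0;
    for (int gy = cy - 1; gy <= cy + 1; ++gy) {
      if (gy < 0 || gy >= g.ny) continue;
      for (int gx = cx - 1; gx <= cx + 1; ++gx) {
        if (gx < 0 || gx >= g.nx) continue;
        int c = gy * g.nx + gx;
        for (int s = g.start[c]; s < g.start[c + 1]; ++s) {
          int t = g.idx[s];
          if (t == excl) continue;
          double dx = xp[t] - px, dy = yp[t] - py;
          double thr = rr[q] + rp[t] + slack;
          if (dx * dx + dy * dy <= thr * thr) ++cnt;
        }
      }
    }
    out[q] = cnt;
  }
  return out;
}
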
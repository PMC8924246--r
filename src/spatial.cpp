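// Spatial primitives shared by the Ripley, DBSCAN and DoC modules.
// All routines use a uniform cell grid for fixed-radius neighbour queries,
// so costs stay near-linear in the number of localisations at STORM scale
// (tens of thousands of points per nucleus ROI).
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#include <queue>
using namespace Rcpp;

namespace {

struct CellGrid {
  double x0, y0, cell;
  int nx, ny;
  std::vector<std::vector<int>> bins;

  CellGrid(const NumericVector& x, const NumericVector& y, double cell_size) {
    cell = std::max(cell_size, 1e-12);
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    const int n = x.size();
    for (int i = 0; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
    }
    if (n == 0) { xmin = ymin = 0.0; xmax = ymax = 0.0; }
    x0 = xmin; y0 = ymin;
    nx = std::max(1, (int)std::floor((xmax - x0) / cell) + 1);
    ny = std::max(1, (int)std::floor((ymax - y0) / cell) + 1);
    // guard against degenerate huge grids when the radius is tiny
    const double max_cells = 4e6;
    if ((double)nx * (double)ny > max_cells) {
      double scale = std::sqrt(((double)nx * (double)ny) / max_cells);
      cell *= scale;
      nx = std::max(1, (int)std::floor((xmax - x0) / cell) + 1);
      ny = std::max(1, (int)std::floor((ymax - y0) / cell) + 1);
    }
    bins.assign((size_t)nx * ny, {});
    for (int i = 0; i < n; ++i) bins[index_of(x[i], y[i])].push_back(i);
  }

  inline size_t index_of(double px, double py) const {
    int ix = std::min(nx - 1, std::max(0, (int)std::floor((px - x0) / cell)));
    int iy = std::min(ny - 1, std::max(0, (int)std::floor((py - y0) / cell)));
    return (size_t)iy * nx + ix;
  }

  // collect candidate indices within `r` of (px, py): all points in cells
  // intersecting the bounding square of the disc
  void candidates(double px, double py, double r, std::vector<int>& out) const {
    out.clear();
    int ix0 = std::max(0, (int)std::floor((px - r - x0) / cell));
    int ix1 = std::min(nx - 1, (int)std::floor((px + r - x0) / cell));
    int iy0 = std::max(0, (int)std::floor((py - r - y0) / cell));
    int iy1 = std::min(ny - 1, (int)std::floor((py + r - y0) / cell));
    for (int iy = iy0; iy <= iy1; ++iy)
      for (int ix = ix0; ix <= ix1; ++ix) {
        const std::vector<int>& b = bins[(size_t)iy * nx + ix];
        out.insert(out.end(), b.begin(), b.end());
      }
  }
};

inline bool point_in_poly(double px, double py,
                          const NumericVector& vx, const NumericVector& vy) {
  // even-odd rule; boundary handling is irrelevant for arc midpoints
  const int m = vx.size();
  bool inside = false;
  for (int i = 0, j = m - 1; i < m; j = i++) {
    if (((vy[i] > py) != (vy[j] > py)) &&
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]))
      inside = !inside;
  }
  return inside;
}

// fraction of the circle centred at (cx, cy) with radius r lying inside the
// polygon: exact circle/edge intersection angles, then inside test per arc
double inside_circle_frac(double cx, double cy, double r,
                          const NumericVector& vx, const NumericVector& vy) {
  const int m = vx.size();
  std::vector<double> angs;
  for (int i = 0, j = m - 1; i < m; j = i++) {
    double x1 = vx[j], y1 = vy[j], x2 = vx[i], y2 = vy[i];
    double dx = x2 - x1, dy = y2 - y1;
    double fx = x1 - cx, fy = y1 - cy;
    double a = dx * dx + dy * dy;
    if (a <= 0) continue;
    double b = 2.0 * (fx * dx + fy * dy);
    double c = fx * fx + fy * fy - r * r;
    double disc = b * b - 4.0 * a * c;
    if (disc <= 0) continue;
    double sq = std::sqrt(disc);
    for (int s = -1; s <= 1; s += 2) {
      double t = (-b + s * sq) / (2.0 * a);
      if (t >= 0.0 && t <= 1.0)
        angs.push_back(std::atan2(fy + t * dy, fx + t * dx));
    }
  }
  if (angs.empty())
    return point_in_poly(cx + r, cy, vx, vy) ? 1.0 : 0.0;
  std::sort(angs.begin(), angs.end());
  angs.push_back(angs.front() + 2.0 * M_PI);
  double tot = 0.0;
  for (size_t k = 0; k + 1 < angs.size(); ++k) {
    double a0 = angs[k], a1 = angs[k + 1];
    if (a1 - a0 <= 0) continue;
    double mid = 0.5 * (a0 + a1);
    if (point_in_poly(cx + r * std::cos(mid), cy + r * std::sin(mid), vx, vy))
      tot += a1 - a0;
  }
  return tot / (2.0 * M_PI);
}

} // namespace

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_ripley_counts(NumericVector x, NumericVector y,
                                NumericVector radii,
                                NumericVector poly_x, NumericVector poly_y,
                                bool isotropic) {
  const int n = x.size(), nr = radii.size();
  const double rmax = radii[nr - 1];
  NumericVector counts(nr);
  CellGrid grid(x, y, rmax);
  std::vector<int> cand;
  for (int i = 0; i < n; ++i) {
    grid.candidates(x[i], y[i], rmax, cand);
    for (int j : cand) {
      if (j == i) continue;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d > rmax) continue;
      // smallest radius bin with radii[k] >= d
      int k = (int)(std::lower_bound(radii.begin(), radii.end(), d) - radii.begin());
      if (k >= nr) continue;
      double w = 1.0;
      if (isotropic) {
        double f = inside_circle_frac(x[i], y[i], d, poly_x, poly_y);
        if (f < 1e-3) f = 1e-3;  // cap the boundary weight
        w = 1.0 / f;
      }
      counts[k] += w;
    }
  }
  for (int k = 1; k < nr; ++k) counts[k] += counts[k - 1];
  return counts;
}

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericVector x, NumericVector y,
                         double eps, int min_pts) {
  const int n = x.size();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;
  CellGrid grid(x, y, eps);
  const double eps2 = eps * eps;

  // neighbour lists (excluding self), in ascending index order
  std::vector<std::vector<int>> nbr(n);
  std::vector<int> cand;
  for (int i = 0; i < n; ++i) {
    grid.candidates(x[i], y[i], eps, cand);
    std::sort(cand.begin(), cand.end());
    for (int j : cand) {
      if (j == i) continue;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      if (dx * dx + dy * dy <= eps2) nbr[i].push_back(j);
    }
  }
  std::vector<char> core(n, 0);
  for (int i = 0; i < n; ++i) core[i] = (int)nbr[i].size() >= min_pts;

  int cid = 0;
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (labels[i] != 0 || !core[i]) continue;
    ++cid;
    labels[i] = cid;
    q.push(i);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int v : nbr[u]) {
        if (labels[v] == 0) {
          labels[v] = cid;           // border or core, first cluster wins
          if (core[v]) q.push(v);
        }
      }
    }
  }
  return labels;
}

//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_radial_counts(NumericVector xq, NumericVector yq,
                                NumericVector xt, NumericVector yt,
                                NumericVector radii, int exclude_mode) {
  // exclude_mode: 0 none, 1 exclude same index (query set == target set),
  // 2 exclude zero-distance matches (cross-channel self-copy guard)
  const int nq = xq.size(), nr = radii.size();
  const double rmax = radii[nr - 1];
  IntegerMatrix out(nq, nr);
  CellGrid grid(xt, yt, rmax);
  std::vector<int> cand;
  for (int i = 0; i < nq; ++i) {
    grid.candidates(xq[i], yq[i], rmax, cand);
    std::vector<int> bins(nr, 0);
    for (int j : cand) {
      if (exclude_mode == 1 && j == i) continue;
      double dx = xt[j] - xq[i], dy = yt[j] - yq[i];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d > rmax) continue;
      if (exclude_mode == 2 && d == 0.0) continue;
      int k = (int)(std::lower_bound(radii.begin(), radii.end(), d) - radii.begin());
      if (k < nr) bins[k] += 1;
    }
    int acc = 0;
    for (int k = 0; k < nr; ++k) { acc += bins[k]; out(i, k) = acc; }
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericVector xq, NumericVector yq,
                          NumericVector xt, NumericVector yt) {
  // nearest target distance per query point via expanding ring search
  const int nq = xq.size(), nt = xt.size();
  NumericVector out(nq, NA_REAL);
  if (nt == 0) return out;
  // cell sized for ~1 target per cell
  double xmin = Rcpp::min(xt), xmax = Rcpp::max(xt);
  double ymin = Rcpp::min(yt), ymax = Rcpp::max(yt);
  double ext = std::max(xmax - xmin, ymax - ymin);
  double cell = (ext > 0) ? ext / std::max(1.0, std::sqrt((double)nt)) : 1.0;
  CellGrid grid(xt, yt, cell);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    int cxi = std::min(grid.nx - 1, std::max(0, (int)std::floor((xq[i] - grid.x0) / grid.cell)));
    int cyi = std::min(grid.ny - 1, std::max(0, (int)std::floor((yq[i] - grid.y0) / grid.cell)));
    int max_ring = std::max(grid.nx, grid.ny);
    for (int ring = 0; ring <= max_ring; ++ring) {
      // once a hit exists, stop after the ring that could still beat it
      if (best < R_PosInf && (double)(ring - 1) * grid.cell > best) break;
      bool any_cell = false;
      for (int iy = cyi - ring; iy <= cyi + ring; ++iy) {
        if (iy < 0 || iy >= grid.ny) continue;
        for (int ix = cxi - ring; ix <= cxi + ring; ++ix) {
          if (ix < 0 || ix >= grid.nx) continue;
          if (std::max(std::abs(ix - cxi), std::abs(iy - cyi)) != ring) continue;
          any_cell = true;
          for (int j : grid.bins[(size_t)iy * grid.nx + ix]) {
            double dx = xt[j] - xq[i], dy = yt[j] - yq[i];
            double d = std::sqrt(dx * dx + dy * dy);
            if (d < best) best = d;
          }
        }
      }
      if (!any_cell && ring > std::max(grid.nx, grid.ny)) break;
    }
    out[i] = best;
  }
  return out;
}
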
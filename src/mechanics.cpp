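// Particle mechanics kernels: spatial-hash neighbour search, pairwise
// shoving (overlap removal), adhesion, contact-graph components.
// Units: um. All randomness draws from R's RNG (deterministic under
// set.seed on the R side).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
#include <limits>
#include <memory>
using namespace Rcpp;

namespace {

struct Hash {
  double cell, width, height;
  int nx, ny;
  std::vector<std::vector<int>> bins;

  // cell size must be >= the largest interaction reach; default 2.5 rmax
  Hash(const NumericVector& x, const NumericVector& y,
       const NumericVector& r, double width_, double height_,
       double cellsize = -1.0)
      : width(width_), height(height_) {
    double rmax = 0.0;
    for (double ri : r) rmax = std::max(rmax, ri);
    if (width <= 0 || height <= 0) {  // derive bounds from the data
      double mx = 1.0, my = 1.0;
      for (int i = 0; i < x.size(); ++i) {
        mx = std::max(mx, x[i]); my = std::max(my, y[i]);
      }
      width = mx + rmax + 1.0;
      height = my + rmax + 1.0;
    }
    cell = cellsize > 0 ? cellsize : std::max(2.5 * rmax, 1e-6);
    nx = std::max(1, std::min(4096, (int)std::ceil(width / cell)));
    ny = std::max(1, std::min(4096, (int)std::ceil(height / cell)));
    bins.assign((size_t)nx * ny, {});
    for (int i = 0; i < x.size(); ++i) bins[index(x[i], y[i])].push_back(i);
  }
  int clampi(int v, int lo, int hi) const {
    return v < lo ? lo : (v > hi ? hi : v);
  }
  size_t index(double px, double py) const {
    int ix = clampi((int)(px / cell), 0, nx - 1);
    int iy = clampi((int)(py / cell), 0, ny - 1);
    return (size_t)iy * nx + ix;
  }
  template <class F> void for_pairs(const NumericVector& x,
                                    const NumericVector& y, F f) const {
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) {
        const auto& a = bins[(size_t)iy * nx + ix];
        if (a.empty()) continue;
        for (int dy = 0; dy <= 1; ++dy) {
          for (int dx = (dy == 0 ? 0 : -1); dx <= 1; ++dx) {
            int jx = ix + dx, jy = iy + dy;
            if (jx < 0 || jx >= nx || jy >= ny) continue;
            const auto& b = bins[(size_t)jy * nx + jx];
            if (dx == 0 && dy == 0) {
              for (size_t p = 0; p < a.size(); ++p)
                for (size_t q = p + 1; q < a.size(); ++q) f(a[p], a[q]);
            } else {
              for (int i : a)
                for (int j : b) f(i, j);
            }
          }
        }
      }
    }
  }
};

void reflect(NumericVector& x, NumericVector& y, const NumericVector& r,
             double width, double height) {
  for (int i = 0; i < x.size(); ++i) {
    double lo = std::min(r[i], width / 2);
    if (x[i] < lo) x[i] = lo;
    if (x[i] > width - lo) x[i] = width - lo;
    double loy = std::min(r[i], height / 2);
    if (y[i] < loy) y[i] = loy;
    if (y[i] > height - loy) y[i] = height - loy;
  }
}

// one shove pass on displacement accumulators; returns max displacement.
// `hash` may be a slightly stale neighbour table: pair distances are
// always recomputed from the current coordinates, so staleness can only
// miss pairs that drifted together across more than the hash margin.
double shove_accumulate(const NumericVector& x, const NumericVector& y,
                        const NumericVector& r, double k, double thresh_frac,
                        double width, double height, const Hash& h,
                        std::vector<double>& dx, std::vector<double>& dy) {
  int n = x.size();
  std::fill(dx.begin(), dx.end(), 0.0);
  std::fill(dy.begin(), dy.end(), 0.0);
  h.for_pairs(x, y, [&](int i, int j) {
    double ex = x[j] - x[i], ey = y[j] - y[i];
    double d2 = ex * ex + ey * ey;
    double contact = (r[i] + r[j]) * (1.0 + thresh_frac);
    if (d2 >= contact * contact) return;
    double d = std::sqrt(d2);
    if (d < 1e-9) {  // coincident centres: random unit direction
      double th = R::runif(0.0, 2.0 * M_PI);
      ex = std::cos(th); ey = std::sin(th); d = 1.0;
    }
    double overlap = contact - d;
    double move = 0.5 * k * overlap;  // each of the pair, equal and opposite
    double ux = ex / d, uy = ey / d;
    dx[i] -= move * ux; dy[i] -= move * uy;
    dx[j] += move * ux; dy[j] += move * uy;
  });
  double maxd = 0.0;
  for (int i = 0; i < n; ++i)
    maxd = std::max(maxd, std::sqrt(dx[i] * dx[i] + dy[i] * dy[i]));
  return maxd;
}

double adhesion_accumulate(const NumericVector& x, const NumericVector& y,
                           const NumericVector& r, const IntegerVector& sp,
                           double hom, double het, double range_frac,
                           double range_min, double thresh_frac,
                           std::vector<double>& dx, std::vector<double>& dy) {
  int n = x.size();
  std::fill(dx.begin(), dx.end(), 0.0);
  std::fill(dy.begin(), dy.end(), 0.0);
  if (hom == 0.0 && het == 0.0) return 0.0;
  double rmax = 0.0;
  for (double ri : r) rmax = std::max(rmax, ri);
  double cellsize = std::max(2.0 * rmax * (1.0 + range_frac) + range_min,
                             1e-6);
  Hash wh(x, y, r, -1.0, -1.0, cellsize);
  wh.for_pairs(x, y, [&](int i, int j) {
    double ex = x[j] - x[i], ey = y[j] - y[i];
    double d = std::sqrt(ex * ex + ey * ey);
    double contact = (r[i] + r[j]) * (1.0 + thresh_frac);
    // attraction reach: proportional to cell size with an absolute
    // floor (EPS appendages have a fixed length scale)
    double range = contact + std::max((r[i] + r[j]) * range_frac, range_min);
    if (d <= contact || d >= range) return;
    double s = (sp[i] == sp[j]) ? hom : het;
    if (s == 0.0) return;
    double move = 0.5 * s * (d - contact);
    double ux = ex / d, uy = ey / d;
    dx[i] += move * ux; dy[i] += move * uy;
    dx[j] -= move * ux; dy[j] -= move * uy;
  });
  double maxd = 0.0;
  for (int i = 0; i < n; ++i)
    maxd = std::max(maxd, std::sqrt(dx[i] * dx[i] + dy[i] * dy[i]));
  return maxd;
}

}  // namespace

// [[Rcpp::export]]
List shove_pass_cpp(NumericVector x, NumericVector y, NumericVector r,
                    double k, double thresh_frac, double width,
                    double height) {
  int n = x.size();
  NumericVector nx = clone(x), ny = clone(y);
  std::vector<double> dx(n), dy(n);
  Hash h(x, y, r, width, height);
  double maxd = shove_accumulate(x, y, r, k, thresh_frac, width, height,
                                 h, dx, dy);
  for (int i = 0; i < n; ++i) { nx[i] += dx[i]; ny[i] += dy[i]; }
  reflect(nx, ny, r, width, height);
  return List::create(_["x"] = nx, _["y"] = ny, _["max_disp"] = maxd,
                      _["dx"] = NumericVector(dx.begin(), dx.end()),
                      _["dy"] = NumericVector(dy.begin(), dy.end()));
}

// [[Rcpp::export]]
List adhesion_pass_cpp(NumericVector x, NumericVector y, NumericVector r,
                       IntegerVector species, double hom, double het,
                       double range_frac, double range_min,
                       double thresh_frac, double width, double height) {
  int n = x.size();
  NumericVector nx = clone(x), ny = clone(y);
  std::vector<double> dx(n), dy(n);
  double maxd = adhesion_accumulate(x, y, r, species, hom, het, range_frac,
                                    range_min, thresh_frac, dx, dy);
  for (int i = 0; i < n; ++i) { nx[i] += dx[i]; ny[i] += dy[i]; }
  reflect(nx, ny, r, width, height);
  return List::create(_["x"] = nx, _["y"] = ny, _["max_disp"] = maxd);
}

// [[Rcpp::export]]
List relax_cpp(NumericVector x, NumericVector y, NumericVector r,
               IntegerVector species, double k, double thresh_frac,
               double hom, double het, double range_frac, double range_min,
               double tol, int max_pass, double width, double height,
               bool use_adhesion) {
  int n = x.size();
  NumericVector cx = clone(x), cy = clone(y);
  std::vector<double> dx(n), dy(n);
  double maxd = 0.0;
  int pass = 0;
  bool capped = false;
  // one adhesion capture pass, then pure shoving to convergence --
  // iterating adhesion against shove would compress dense clusters
  // into persistent overlap
  if (use_adhesion && (hom > 0 || het > 0)) {
    adhesion_accumulate(cx, cy, r, species, hom, het, range_frac,
                        range_min, thresh_frac, dx, dy);
    for (int i = 0; i < n; ++i) { cx[i] += dx[i]; cy[i] += dy[i]; }
    reflect(cx, cy, r, width, height);
  }
  // the neighbour hash is rebuilt every few passes; its cell size has a
  // 0.5 rmax margin over the interaction reach, and per-pass moves are
  // bounded by k * overlap, so pairs cannot cross the margin between
  // rebuilds
  const int rebuild_every = 4;
  std::unique_ptr<Hash> h;
  for (pass = 1; pass <= max_pass; ++pass) {
    if (!h || (pass - 1) % rebuild_every == 0) {
      h.reset(new Hash(cx, cy, r, width, height));
    }
    maxd = shove_accumulate(cx, cy, r, k, thresh_frac, width, height, *h,
                            dx, dy);
    for (int i = 0; i < n; ++i) { cx[i] += dx[i]; cy[i] += dy[i]; }
    reflect(cx, cy, r, width, height);
    if (maxd < tol) break;
  }
  if (pass > max_pass) { pass = max_pass; capped = true; }
  return List::create(_["x"] = cx, _["y"] = cy, _["max_disp"] = maxd,
                      _["passes"] = pass, _["capped"] = capped);
}

// [[Rcpp::export]]
IntegerVector components_cpp(NumericVector x, NumericVector y,
                             NumericVector r, double slack_frac,
                             double reach_min) {
  int n = x.size();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  auto unite = [&](int i, int j) {
    int a = find(i), b = find(j);
    if (a != b) parent[a] = b;
  };
  if (n > 0) {
    Hash h(x, y, r, -1.0, -1.0);
    h.for_pairs(x, y, [&](int i, int j) {
      double ex = x[j] - x[i], ey = y[j] - y[i];
      double d2 = ex * ex + ey * ey;
      double reach = (r[i] + r[j]) * (1.0 + slack_frac) + reach_min;
      if (d2 <= reach * reach) unite(i, j);
    });
  }
  IntegerVector out(n);
  std::vector<int> label((size_t)n, -1);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int root = find(i);
    if (label[root] < 0) label[root] = next++;
    out[i] = label[root] + 1;
  }
  return out;
}

// all-pairs maximum overlap (um) beyond the shove threshold; brute force
// oracle helper for small n
// [[Rcpp::export]]
double max_overlap_cpp(NumericVector x, NumericVector y, NumericVector r,
                       double thresh_frac) {
  int n = x.size();
  double worst = -std::numeric_limits<double>::infinity();
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double ex = x[j] - x[i], ey = y[j] - y[i];
      double d = std::sqrt(ex * ex + ey * ey);
      double contact = (r[i] + r[j]) * (1.0 + thresh_frac);
      worst = std::max(worst, contact - d);
    }
  }
  return worst;
}
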
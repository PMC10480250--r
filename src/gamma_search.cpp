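// 3D gamma minimum search.  Two routes:
//  - gamma_engine_cpp: the production search on a coarse offset lattice
//    (step = dta / search_step_fraction) with an early radius cut-off.
//  - gamma_brute_cpp: the verification oracle on a dense lattice
//    (step = dta / 50), written independently.
// Both minimise Gamma^2 = |r|^2/dta^2 + (De(r_ref + r) - Dr(r_ref))^2/dd^2
// over offsets |r| <= max_mm, sampling the evaluated dose trilinearly, and
// sign the result by the dose difference at the reference voxel itself.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Offset {
  double ox, oy, oz, r2;
};

// Trilinear sample of vol at fractional 0-based index (fx, fy, fz).
// Returns false when the point lies outside the grid.
inline bool sample_trilinear(const double *vol, int nx, int ny, int nz,
                             double fx, double fy, double fz, double &out) {
  const double eps = 1e-9;
  if (fx < -eps || fx > nx - 1 + eps || fy < -eps || fy > ny - 1 + eps ||
      fz < -eps || fz > nz - 1 + eps)
    return false;
  int i0 = (int)std::floor(fx);
  int j0 = (int)std::floor(fy);
  int k0 = (int)std::floor(fz);
  if (i0 > nx - 2) i0 = nx - 2;
  if (j0 > ny - 2) j0 = ny - 2;
  if (k0 > nz - 2) k0 = nz - 2;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  double tx = fx - i0, ty = fy - j0, tz = fz - k0;
  const double *p = vol + (size_t)i0 + (size_t)nx * (j0 + (size_t)ny * k0);
  size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  double c00 = p[0] * (1 - tx) + p[sx] * tx;
  double c10 = p[sy] * (1 - tx) + p[sy + sx] * tx;
  double c01 = p[sz] * (1 - tx) + p[sz + sx] * tx;
  double c11 = p[sz + sy] * (1 - tx) + p[sz + sy + sx] * tx;
  out = (c00 * (1 - ty) + c10 * ty) * (1 - tz) +
        (c01 * (1 - ty) + c11 * ty) * tz;
  return true;
}

std::vector<Offset> offset_table(double step, double max_mm) {
  int n = (int)std::floor(max_mm / step + 1e-9);
  std::vector<Offset> offs;
  offs.reserve((size_t)(2 * n + 1) * (2 * n + 1) * (2 * n + 1) / 2 + 8);
  double max2 = max_mm * max_mm * (1 + 1e-12);
  for (int a = -n; a <= n; ++a)
    for (int b = -n; b <= n; ++b)
      for (int c = -n; c <= n; ++c) {
        double ox = a * step, oy = b * step, oz = c * step;
        double r2 = ox * ox + oy * oy + oz * oz;
        if (r2 <= max2) offs.push_back({ox, oy, oz, r2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset &u, const Offset &v) { return u.r2 < v.r2; });
  return offs;
}

} // namespace

// [[Rcpp::export]]
NumericVector gamma_engine_cpp(NumericVector ref, NumericVector evl,
                               LogicalVector mask, IntegerVector dims,
                               NumericVector spacing, NumericVector dd_abs,
                               double dta_mm, double step_mm, double max_mm,
                               double threshold) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n, NA_REAL);
  std::vector<Offset> offs = offset_table(step_mm, max_mm);
  double inv_dta2 = 1.0 / (dta_mm * dta_mm);
  const double *rp = REAL(ref), *ep = REAL(evl), *ddp = REAL(dd_abs);
  const int *mp = LOGICAL(mask);
  for (size_t idx = 0; idx < n; ++idx) {
    if (!mp[idx] || !(rp[idx] > threshold)) continue;
    double dd = ddp[idx];
    if (!(dd > 0)) continue; // zero-dose local points never reach here
    int i = (int)(idx % nx);
    int j = (int)((idx / nx) % ny);
    int k = (int)(idx / ((size_t)nx * ny));
    double rd = rp[idx];
    double best = R_PosInf;
    double bx = 0, by = 0, bz = 0;
    for (const Offset &o : offs) {
      double dist2 = o.r2 * inv_dta2;
      if (dist2 >= best) break; // offsets sorted by radius
      double ev;
      if (!sample_trilinear(ep, nx, ny, nz, i + o.ox / spacing[0],
                            j + o.oy / spacing[1], k + o.oz / spacing[2], ev))
        continue;
      double dnorm = (ev - rd) / dd;
      double g2 = dist2 + dnorm * dnorm;
      if (g2 < best) {
        best = g2;
        bx = o.ox;
        by = o.oy;
        bz = o.oz;
      }
    }
    // refinement pass: fine lattice (step/5) over +/- two coarse steps
    // around the coarse minimiser
    double fs = step_mm / 5.0;
    double max2 = max_mm * max_mm * (1 + 1e-12);
    for (int a = -10; a <= 10; ++a)
      for (int b = -10; b <= 10; ++b)
        for (int c = -10; c <= 10; ++c) {
          double ox = bx + a * fs, oy = by + b * fs, oz = bz + c * fs;
          double r2 = ox * ox + oy * oy + oz * oz;
          if (r2 > max2) continue;
          double dist2 = r2 * inv_dta2;
          if (dist2 >= best) continue;
          double ev;
          if (!sample_trilinear(ep, nx, ny, nz, i + ox / spacing[0],
                                j + oy / spacing[1], k + oz / spacing[2],
                                ev))
            continue;
          double dnorm = (ev - rd) / dd;
          double g2 = dist2 + dnorm * dnorm;
          if (g2 < best) best = g2;
        }
    double sgn = (ep[idx] - rp[idx] >= 0) ? 1.0 : -1.0;
    out[idx] = sgn * std::sqrt(best);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector gamma_brute_cpp(NumericVector ref, NumericVector evl,
                              LogicalVector mask, IntegerVector dims,
                              NumericVector spacing, NumericVector dd_abs,
                              double dta_mm, double max_mm,
                              double threshold) {
  // Dense exhaustive lattice, step fixed at dta/50.  Kept separate from the
  // engine on purpose: its own interpolation and its own loop structure.
  const double step = dta_mm / 50.0;
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n, NA_REAL);
  const double *rp = REAL(ref), *ep = REAL(evl), *ddp = REAL(dd_abs);
  const int *mp = LOGICAL(mask);

  // enumerate and radius-sort the dense lattice once
  int m = (int)std::floor(max_mm / step + 1e-9);
  std::vector<double> ox, oy, oz, r2v;
  for (int a = -m; a <= m; ++a)
    for (int b = -m; b <= m; ++b)
      for (int c = -m; c <= m; ++c) {
        double x = a * step, y = b * step, z = c * step;
        double r2 = x * x + y * y + z * z;
        if (r2 <= max_mm * max_mm * (1 + 1e-12)) {
          ox.push_back(x);
          oy.push_back(y);
          oz.push_back(z);
          r2v.push_back(r2);
        }
      }
  std::vector<size_t> order(r2v.size());
  for (size_t t = 0; t < order.size(); ++t) order[t] = t;
  std::sort(order.begin(), order.end(),
            [&](size_t u, size_t v) { return r2v[u] < r2v[v]; });

  double inv_dta2 = 1.0 / (dta_mm * dta_mm);
  for (size_t idx = 0; idx < n; ++idx) {
    if (!mp[idx] || !(rp[idx] > threshold)) continue;
    double dd = ddp[idx];
    if (!(dd > 0)) continue;
    int i = (int)(idx % nx);
    int j = (int)((idx / nx) % ny);
    int k = (int)(idx / ((size_t)nx * ny));
    double rd = rp[idx];
    double best = R_PosInf;
    for (size_t t = 0; t < order.size(); ++t) {
      size_t u = order[t];
      double dist2 = r2v[u] * inv_dta2;
      if (dist2 >= best) break; // exact: later offsets only get farther
      double fx = i + ox[u] / spacing[0];
      double fy = j + oy[u] / spacing[1];
      double fz = k + oz[u] / spacing[2];
      // independent trilinear sampler
      const double eps = 1e-9;
      if (fx < -eps || fx > nx - 1 + eps || fy < -eps ||
          fy > ny - 1 + eps || fz < -eps || fz > nz - 1 + eps)
        continue;
      int i0 = std::min(std::max((int)std::floor(fx), 0), nx - 2);
      int j0 = std::min(std::max((int)std::floor(fy), 0), ny - 2);
      int k0 = std::min(std::max((int)std::floor(fz), 0), nz - 2);
      double tx = fx - i0, ty = fy - j0, tz = fz - k0;
      double ev = 0.0;
      for (int dz = 0; dz <= 1; ++dz)
        for (int dy = 0; dy <= 1; ++dy)
          for (int dx = 0; dx <= 1; ++dx) {
            double w = (dx ? tx : 1 - tx) * (dy ? ty : 1 - ty) *
                       (dz ? tz : 1 - tz);
            ev += w * ep[(size_t)(i0 + dx) +
                         (size_t)nx * ((j0 + dy) + (size_t)ny * (k0 + dz))];
          }
      double dnorm = (ev - rd) / dd;
      double g2 = dist2 + dnorm * dnorm;
      if (g2 < best) best = g2;
    }
    double sgn = (ep[idx] - rp[idx] >= 0) ? 1.0 : -1.0;
    out[idx] = sgn * std::sqrt(best);
  }
  return out;
}
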
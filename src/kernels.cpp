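#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---- exact Euclidean distance transform (separable lower-envelope method) --
// 1D squared-distance transform with sample spacing h.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double h, std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  const double h2 = h * h;
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Distance (mm) from every voxel to the nearest TRUE voxel of `mask`.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // large finite sentinel: infinity breaks the lower-envelope arithmetic
  // when a whole scan line is background
  const double INF = 1e30;
  std::vector<double> g((size_t)nx * ny * nz);
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    g[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)k * nx * ny + (size_t)j * nx;
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = g[base + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      f.resize(nx); d.resize(nx);
      dt1d(f, d, spacing[0], v, z);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
      f.resize(nmax); d.resize(nmax);
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (size_t)j * nx];
      f.resize(ny); d.resize(ny);
      dt1d(f, d, spacing[1], v, z);
      for (int j = 0; j < ny; ++j) g[base + (size_t)j * nx] = d[j];
      f.resize(nmax); d.resize(nmax);
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = g[base + (size_t)k * nx * ny];
      f.resize(nz); d.resize(nz);
      dt1d(f, d, spacing[2], v, z);
      for (int k = 0; k < nz; ++k) g[base + (size_t)k * nx * ny] = d[k];
      f.resize(nmax); d.resize(nmax);
    }

  NumericVector out((R_xlen_t)nx * ny * nz);
  for (R_xlen_t i = 0; i < out.size(); ++i)
    out[i] = (g[i] >= 1e29) ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}

// ---- connected-component labelling (6- or 26-connectivity) ----------------
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab((R_xlen_t)nx * ny * nz);
  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back(dx); offs.push_back(dy); offs.push_back(dz);
      }
  int next = 0;
  std::vector<int64_t> queue_;
  for (int64_t s = 0; s < (int64_t)nx * ny * nz; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    queue_.clear();
    queue_.push_back(s);
    while (!queue_.empty()) {
      int64_t cur = queue_.back(); queue_.pop_back();
      int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / ((int64_t)nx * ny);
      for (size_t o = 0; o < offs.size(); o += 3) {
        int i2 = ci + offs[o], j2 = cj + offs[o + 1], k2 = ck + offs[o + 2];
        if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz) continue;
        int64_t t = (int64_t)k2 * nx * ny + (int64_t)j2 * nx + i2;
        if (mask[t] && lab[t] == 0) { lab[t] = next; queue_.push_back(t); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---- Dijkstra path through a voxel graph -----------------------------------
// cost: per-voxel node cost (NA/Inf = blocked); edge weight =
// euclidean step length (mm) * mean of endpoint costs; 26-neighbourhood.
// Returns 1-based linear indices of the path from start to end (inclusive),
// or an empty vector when unreachable.
// [[Rcpp::export(name = ".dijkstra_grid")]]
IntegerVector dijkstra_grid(NumericVector cost, IntegerVector dim,
                            NumericVector spacing, int start, int end) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int64_t n = (int64_t)nx * ny * nz;
  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  std::vector<int64_t> prev(n, -1);
  typedef std::pair<double, int64_t> QN;
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;
  int64_t s0 = start - 1, e0 = end - 1;
  dist[s0] = 0.0;
  pq.push(QN(0.0, s0));

  std::vector<int> offs;
  std::vector<double> len;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        offs.push_back(dx); offs.push_back(dy); offs.push_back(dz);
        double lx = dx * spacing[0], ly = dy * spacing[1], lz = dz * spacing[2];
        len.push_back(std::sqrt(lx * lx + ly * ly + lz * lz));
      }

  while (!pq.empty()) {
    QN top = pq.top(); pq.pop();
    int64_t u = top.second;
    if (top.first > dist[u]) continue;
    if (u == e0) break;
    int ci = u % nx, cj = (u / nx) % ny, ck = u / ((int64_t)nx * ny);
    for (size_t o = 0, e = 0; o < offs.size(); o += 3, ++e) {
      int i2 = ci + offs[o], j2 = cj + offs[o + 1], k2 = ck + offs[o + 2];
      if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz) continue;
      int64_t v = (int64_t)k2 * nx * ny + (int64_t)j2 * nx + i2;
      double cu = cost[u], cv = cost[v];
      if (!R_finite(cv)) continue;
      double w = len[e] * 0.5 * (cu + cv);
      if (dist[u] + w < dist[v]) {
        dist[v] = dist[u] + w;
        prev[v] = u;
        pq.push(QN(dist[v], v));
      }
    }
  }
  if (!R_finite(dist[e0])) return IntegerVector(0);
  std::vector<int> path;
  for (int64_t cur = e0; cur != -1; cur = prev[cur]) path.push_back((int)(cur + 1));
  std::reverse(path.begin(), path.end());
  return wrap(path);
}

// ---- trilinear interpolation ------------------------------------------------
// vol indexed 0-based; pts are continuous 0-based voxel coordinates (N x 3).
// Out-of-grid points get `fill`.
// [[Rcpp::export(name = ".interp_trilinear")]]
NumericVector interp_trilinear(NumericVector vol, IntegerVector dim,
                               NumericMatrix pts, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[p] = fill; continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) --i0;
    if (j0 == ny - 1) --j0;
    if (k0 == nz - 1) --k0;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    #define V(I, J, K) vol[(int64_t)(K) * nx * ny + (int64_t)(J) * nx + (I)]
    double c00 = V(i0, j0, k0) * (1 - fx) + V(i1, j0, k0) * fx;
    double c10 = V(i0, j1, k0) * (1 - fx) + V(i1, j1, k0) * fx;
    double c01 = V(i0, j0, k1) * (1 - fx) + V(i1, j0, k1) * fx;
    double c11 = V(i0, j1, k1) * (1 - fx) + V(i1, j1, k1) * fx;
    #undef V
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// ---- phantom voxel classification ------------------------------------------
// For every voxel centre, find the nearest sample of a densely sampled
// centerline curve, then classify against the tube radius profile and the
// calcified wedges defined in the curve's transported frame.
//
// curve: N x 3 sample points (mm); s: arclength per sample; radius: tube
// radius per sample; U, V: transported in-plane frame per sample;
// wedges: W x 6 matrix (s_start, s_end, theta_center_deg, arc_width_deg,
// thickness_mm, gap_mm); search_mm: capture radius around the curve.
// Returns integer codes: 0 background, 1 lumen, 2 calcification, and the
// wedge id (1-based) per voxel.
// [[Rcpp::export(name = ".classify_phantom_voxels")]]
List classify_phantom_voxels(IntegerVector dim, NumericVector spacing,
                             NumericVector origin, NumericMatrix curve,
                             NumericVector s, NumericVector radius,
                             NumericMatrix T, NumericMatrix U, NumericMatrix V,
                             NumericMatrix wedges, double search_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int64_t n = (int64_t)nx * ny * nz;
  const int ns = curve.nrow();
  std::vector<double> best(n, std::numeric_limits<double>::infinity());
  std::vector<int> arg(n, -1);

  // splat pass: nearest curve sample per voxel within the capture radius
  for (int q = 0; q < ns; ++q) {
    double cx = curve(q, 0), cy = curve(q, 1), cz = curve(q, 2);
    int i0 = (int)std::floor((cx - search_mm - origin[0]) / spacing[0]);
    int i1 = (int)std::ceil((cx + search_mm - origin[0]) / spacing[0]);
    int j0 = (int)std::floor((cy - search_mm - origin[1]) / spacing[1]);
    int j1 = (int)std::ceil((cy + search_mm - origin[1]) / spacing[1]);
    int k0 = (int)std::floor((cz - search_mm - origin[2]) / spacing[2]);
    int k1 = (int)std::ceil((cz + search_mm - origin[2]) / spacing[2]);
    i0 = std::max(i0, 0); j0 = std::max(j0, 0); k0 = std::max(k0, 0);
    i1 = std::min(i1, nx - 1); j1 = std::min(j1, ny - 1); k1 = std::min(k1, nz - 1);
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * spacing[2] - cz;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * spacing[1] - cy;
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * spacing[0] - cx;
          double d2 = dx * dx + dy * dy + dz * dz;
          int64_t idx = (int64_t)k * nx * ny + (int64_t)j * nx + i;
          if (d2 < best[idx]) { best[idx] = d2; arg[idx] = q; }
        }
      }
    }
  }

  IntegerVector cls(n), wid(n);
  const int nw = wedges.nrow();
  for (int64_t idx = 0; idx < n; ++idx) {
    int q = arg[idx];
    if (q < 0) continue;
    int i = idx % nx, j = (idx / nx) % ny, k = idx / ((int64_t)nx * ny);
    double px = origin[0] + i * spacing[0] - curve(q, 0);
    double py = origin[1] + j * spacing[1] - curve(q, 1);
    double pz = origin[2] + k * spacing[2] - curve(q, 2);
    // remove the along-tangent component: radial position in the slice plane
    double at = px * T(q, 0) + py * T(q, 1) + pz * T(q, 2);
    // flat end caps: beyond the first/last sample is outside the tube
    if (q == 0 && at < 0) continue;
    if (q == ns - 1 && at > 0) continue;
    double rx = px - at * T(q, 0), ry = py - at * T(q, 1), rz = pz - at * T(q, 2);
    double rho = std::sqrt(rx * rx + ry * ry + rz * rz);
    double r_here = radius[q];
    if (rho <= r_here) { cls[idx] = 1; continue; }
    if (nw == 0) continue;
    double uu = rx * U(q, 0) + ry * U(q, 1) + rz * U(q, 2);
    double vv = rx * V(q, 0) + ry * V(q, 1) + rz * V(q, 2);
    double th = std::atan2(vv, uu) * 180.0 / M_PI;
    if (th < 0) th += 360.0;
    for (int w = 0; w < nw; ++w) {
      if (s[q] < wedges(w, 0) || s[q] > wedges(w, 1)) continue;
      double half = wedges(w, 3) / 2.0;
      double dth = std::fabs(th - wedges(w, 2));
      if (dth > 180.0) dth = 360.0 - dth;
      if (dth > half) continue;
      double rin = r_here + wedges(w, 5);
      double rout = rin + wedges(w, 4);
      if (rho >= rin && rho <= rout) { cls[idx] = 2; wid[idx] = w + 1; break; }
    }
  }
  cls.attr("dim") = dim;
  wid.attr("dim") = dim;
  return List::create(_["class"] = cls, _["wedge"] = wid);
}
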
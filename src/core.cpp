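// Low-level 3D voxel primitives: separable Gaussian blur, anisotropic
// squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// topology-preserving curve thinning, 26-connected component labeling,
// capsule/sphere rasterization and trilinear sampling.
//
// All arrays are R numeric/logical vectors with a dim attribute (nx, ny, nz),
// column-major; physical coordinates are micrometres with the origin at the
// volume corner and voxel centres at (i - 0.5) * spacing.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <queue>
using namespace Rcpp;

static inline R_xlen_t vidx(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

static void get_dims(const RObject &a, int &nx, int &ny, int &nz) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  nx = d[0]; ny = d[1]; nz = d[2];
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, reflective boundary.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3d(NumericVector arr, NumericVector sigma_vox) {
  int nx, ny, nz; get_dims(arr, nx, ny, nz);
  if (sigma_vox.size() != 3) stop("sigma_vox must have length 3");
  std::vector<double> cur(arr.begin(), arr.end()), nxt(cur.size());
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * rad + 1);
    double ksum = 0;
    for (int i = -rad; i <= rad; ++i) { k[i + rad] = std::exp(-0.5 * i * i / (s * s)); ksum += k[i + rad]; }
    for (double &v : k) v /= ksum;
    int len = n[ax];
    R_xlen_t st = stride[ax];
    // iterate over all lines along axis ax
    int a1 = (ax == 0) ? 1 : 0;
    int a2 = (ax == 2) ? 1 : 2;
    for (int j2 = 0; j2 < n[a2]; ++j2) {
      for (int j1 = 0; j1 < n[a1]; ++j1) {
        R_xlen_t base = stride[a1] * j1 + stride[a2] * j2;
        for (int i = 0; i < len; ++i) {
          double acc = 0;
          for (int t = -rad; t <= rad; ++t) {
            int ii = i + t;
            if (ii < 0) ii = -ii - 1;            // reflect
            if (ii >= len) ii = 2 * len - ii - 1;
            if (ii < 0) ii = 0; if (ii >= len) ii = len - 1;
            acc += k[t + rad] * cur[base + st * ii];
          }
          nxt[base + st * i] = acc;
        }
      }
    }
    cur.swap(nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = arr.attr("dim");
  return out;
}

// ---------------------------------------------------------------------------
// 1D squared distance transform (lower envelope of parabolas).
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n, double w2) {
  static thread_local std::vector<int> v;
  static thread_local std::vector<double> zz;
  v.assign(n, 0); zz.assign(n + 1, 0.0);
  int kk = 0;
  v[0] = 0; zz[0] = -std::numeric_limits<double>::infinity();
  zz[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[kk];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= zz[kk]) { --kk; } else break;
    }
    ++kk; v[kk] = q; zz[kk] = s; zz[kk + 1] = std::numeric_limits<double>::infinity();
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[kk + 1] < q) ++kk;
    int p = v[kk];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// Squared EDT of foreground (distance to nearest background voxel), anisotropic.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, NumericVector spacing) {
  int nx, ny, nz; get_dims(mask, nx, ny, nz);
  if (spacing.size() != 3) stop("spacing must have length 3");
  R_xlen_t N = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> cur(N);
  for (R_xlen_t i = 0; i < N; ++i) cur[i] = mask[i] ? INF : 0.0;
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  std::vector<double> f, d;
  for (int ax = 0; ax < 3; ++ax) {
    int len = n[ax];
    double w2 = spacing[ax] * spacing[ax];
    R_xlen_t st = stride[ax];
    int a1 = (ax == 0) ? 1 : 0;
    int a2 = (ax == 2) ? 1 : 2;
    f.assign(len, 0.0); d.assign(len, 0.0);
    for (int j2 = 0; j2 < n[a2]; ++j2) {
      for (int j1 = 0; j1 < n[a1]; ++j1) {
        R_xlen_t base = stride[a1] * j1 + stride[a2] * j2;
        bool any_fin = false, any_inf = false;
        for (int i = 0; i < len; ++i) {
          f[i] = cur[base + st * i];
          if (std::isinf(f[i])) any_inf = true; else any_fin = true;
        }
        if (!any_fin) continue;          // all INF: stays INF
        if (!any_inf) {
          bool all0 = true;
          for (int i = 0; i < len; ++i) if (f[i] != 0.0) { all0 = false; break; }
          if (all0) continue;
        }
        // replace INF by large finite (envelope needs finite inputs)
        double big = 1e30;
        for (int i = 0; i < len; ++i) if (std::isinf(f[i])) f[i] = big;
        dt1d(f, d, len, w2);
        for (int i = 0; i < len; ++i) cur[base + st * i] = d[i];
      }
    }
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = mask.attr("dim");
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected component labeling (BFS).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask) {
  int nx, ny, nz; get_dims(mask, nx, ny, nz);
  R_xlen_t N = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(N, 0);
  lab.attr("dim") = mask.attr("dim");
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.clear(); stack.push_back(s); lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t c = stack.back(); stack.pop_back();
      int z = (int)(c / ((R_xlen_t)nx * ny));
      R_xlen_t rem = c - (R_xlen_t)z * nx * ny;
      int y = (int)(rem / nx), x = (int)(rem % nx);
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        R_xlen_t q = vidx(xx, yy, zz, nx, ny);
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Simple-point test on a 3x3x3 neighborhood (Bertrand & Malandain):
// p is simple iff exactly one 26-component of object voxels in N26*(p)
// and exactly one 6-component of background voxels in N18(p) 6-adjacent to p.
static const int N6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};

static bool is_simple(const bool nb[27]) {
  // nb indexed as (dx+1) + 3*(dy+1) + 9*(dz+1); center = 13
  // --- C*: 26-components of object in the 26 neighbors
  int comp[27]; for (int i = 0; i < 27; ++i) comp[i] = -1;
  int ncomp_obj = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || comp[i] >= 0) continue;
    // BFS in 26-connectivity over object voxels (excluding center)
    std::vector<int> st; st.push_back(i); comp[i] = ncomp_obj;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int xx = cx + dx, yy = cy + dy, zz = cz + dz;
        if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
        int q = xx + 3 * yy + 9 * zz;
        if (q == 13 || !nb[q] || comp[q] >= 0) continue;
        comp[q] = ncomp_obj; st.push_back(q);
      }
    }
    ++ncomp_obj;
  }
  if (ncomp_obj != 1) return false;
  // --- C^bar: 6-components of background within the 18-neighborhood,
  //     counting only components 6-adjacent to the center.
  auto in18 = [](int x, int y, int z) {
    int ad = std::abs(x - 1) + std::abs(y - 1) + std::abs(z - 1);
    return ad >= 1 && ad <= 2;
  };
  int comp2[27]; for (int i = 0; i < 27; ++i) comp2[i] = -1;
  int ncomp_bg = 0;
  for (int i = 0; i < 27; ++i) {
    int ix = i % 3, iy = (i / 3) % 3, iz = i / 9;
    if (!in18(ix, iy, iz) || nb[i] || comp2[i] >= 0) continue;
    bool touches_center = false;
    std::vector<int> st; st.push_back(i); comp2[i] = ncomp_bg;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      if (std::abs(cx - 1) + std::abs(cy - 1) + std::abs(cz - 1) == 1) touches_center = true;
      for (int d = 0; d < 6; ++d) {
        int xx = cx + N6[d][0], yy = cy + N6[d][1], zz = cz + N6[d][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
        if (!in18(xx, yy, zz)) continue;
        int q = xx + 3 * yy + 9 * zz;
        if (nb[q] || comp2[q] >= 0) continue;
        comp2[q] = ncomp_bg; st.push_back(q);
      }
    }
    if (touches_center) ++ncomp_bg; else { /* component not 6-adjacent: ignore */ }
  }
  return ncomp_bg == 1;
}

// Topology-preserving curve thinning: sequentially delete simple, non-endpoint
// border points, cycling through the six border directions until stable.
// Assumes (approximately) isotropic voxels.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask) {
  int nx, ny, nz; get_dims(mask, nx, ny, nz);
  R_xlen_t N = (R_xlen_t)nx * ny * nz;
  std::vector<char> m(N);
  for (R_xlen_t i = 0; i < N; ++i) m[i] = mask[i] ? 1 : 0;
  auto at = [&](int x, int y, int z) -> char {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
    return m[vidx(x, y, z, nx, ny)];
  };
  auto fill_nb = [&](int x, int y, int z, bool nb[27]) {
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx)
      nb[(dx + 1) + 3 * (dy + 1) + 9 * (dz + 1)] = at(x + dx, y + dy, z + dz) != 0;
  };
  auto n26 = [&](int x, int y, int z) {
    int c = 0;
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
      if (!dx && !dy && !dz) continue;
      if (at(x + dx, y + dy, z + dz)) ++c;
    }
    return c;
  };
  bool changed = true;
  std::vector<R_xlen_t> cand;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      cand.clear();
      for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
        R_xlen_t i = vidx(x, y, z, nx, ny);
        if (!m[i]) continue;
        if (at(x + N6[dir][0], y + N6[dir][1], z + N6[dir][2])) continue; // not a border pt in dir
        int nn = n26(x, y, z);
        if (nn <= 1) continue;                       // endpoint: keep
        bool nb[27]; fill_nb(x, y, z, nb);
        if (is_simple(nb)) cand.push_back(i);
      }
      // sequential re-checked deletion in fixed scan order (deterministic)
      for (R_xlen_t i : cand) {
        int z = (int)(i / ((R_xlen_t)nx * ny));
        R_xlen_t rem = i - (R_xlen_t)z * nx * ny;
        int y = (int)(rem / nx), x = (int)(rem % nx);
        int nn = n26(x, y, z);
        if (nn <= 1) continue;
        bool nb[27]; fill_nb(x, y, z, nb);
        if (!is_simple(nb)) continue;
        m[i] = 0; changed = true;
      }
    }
  }
  LogicalVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = m[i] != 0;
  out.attr("dim") = mask.attr("dim");
  return out;
}

// ---------------------------------------------------------------------------
// Rasterize capsules (tube segments with linearly varying radius) into a
// volume: voxel centre v is inside segment (p0,r0)-(p1,r1) if
// |v - (p0 + t*(p1-p0))| <= r(t) for the closest t in [0,1].
// Writes max(current, 1) on hit.
// [[Rcpp::export]]
NumericVector cpp_paint_capsules(IntegerVector dims, NumericVector spacing,
                                 NumericMatrix p0, NumericMatrix p1,
                                 NumericVector r0, NumericVector r1) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t N = (R_xlen_t)nx * ny * nz;
  NumericVector out(N, 0.0);
  out.attr("dim") = dims;
  int nseg = p0.nrow();
  for (int s = 0; s < nseg; ++s) {
    double ax = p0(s, 0), ay = p0(s, 1), az = p0(s, 2);
    double bx = p1(s, 0), by = p1(s, 1), bz = p1(s, 2);
    double ra = r0[s], rb = r1[s];
    double rmax = std::max(ra, rb);
    double lox = std::min(ax, bx) - rmax, hix = std::max(ax, bx) + rmax;
    double loy = std::min(ay, by) - rmax, hiy = std::max(ay, by) + rmax;
    double loz = std::min(az, bz) - rmax, hiz = std::max(az, bz) + rmax;
    int x0 = std::max(0, (int)std::floor(lox / spacing[0] - 0.5));
    int x1i = std::min(nx - 1, (int)std::ceil(hix / spacing[0] - 0.5));
    int y0 = std::max(0, (int)std::floor(loy / spacing[1] - 0.5));
    int y1i = std::min(ny - 1, (int)std::ceil(hiy / spacing[1] - 0.5));
    int z0 = std::max(0, (int)std::floor(loz / spacing[2] - 0.5));
    int z1i = std::min(nz - 1, (int)std::ceil(hiz / spacing[2] - 0.5));
    double dx = bx - ax, dy = by - ay, dz = bz - az;
    double L2 = dx * dx + dy * dy + dz * dz;
    for (int z = z0; z <= z1i; ++z) {
      double vz = (z + 0.5) * spacing[2];
      for (int y = y0; y <= y1i; ++y) {
        double vy = (y + 0.5) * spacing[1];
        for (int x = x0; x <= x1i; ++x) {
          double vx = (x + 0.5) * spacing[0];
          double t = 0.0;
          if (L2 > 0) {
            t = ((vx - ax) * dx + (vy - ay) * dy + (vz - az) * dz) / L2;
            if (t < 0) t = 0; if (t > 1) t = 1;
          }
          double cx = ax + t * dx, cy = ay + t * dy, cz = az + t * dz;
          double r = ra + t * (rb - ra);
          double qx = vx - cx, qy = vy - cy, qz = vz - cz;
          if (qx * qx + qy * qy + qz * qz <= r * r) {
            R_xlen_t i = vidx(x, y, z, nx, ny);
            if (out[i] < 1.0) out[i] = 1.0;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_paint_spheres(IntegerVector dims, NumericVector spacing,
                                NumericMatrix centers, NumericVector radii) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t N = (R_xlen_t)nx * ny * nz;
  NumericVector out(N, 0.0);
  out.attr("dim") = dims;
  for (int s = 0; s < centers.nrow(); ++s) {
    double cx = centers(s, 0), cy = centers(s, 1), cz = centers(s, 2), r = radii[s];
    int x0 = std::max(0, (int)std::floor((cx - r) / spacing[0] - 0.5));
    int x1i = std::min(nx - 1, (int)std::ceil((cx + r) / spacing[0] - 0.5));
    int y0 = std::max(0, (int)std::floor((cy - r) / spacing[1] - 0.5));
    int y1i = std::min(ny - 1, (int)std::ceil((cy + r) / spacing[1] - 0.5));
    int z0 = std::max(0, (int)std::floor((cz - r) / spacing[2] - 0.5));
    int z1i = std::min(nz - 1, (int)std::ceil((cz + r) / spacing[2] - 0.5));
    for (int z = z0; z <= z1i; ++z) {
      double vz = (z + 0.5) * spacing[2] - cz;
      for (int y = y0; y <= y1i; ++y) {
        double vy = (y + 0.5) * spacing[1] - cy;
        for (int x = x0; x <= x1i; ++x) {
          double vx = (x + 0.5) * spacing[0] - cx;
          if (vx * vx + vy * vy + vz * vz <= r * r) {
            R_xlen_t i = vidx(x, y, z, nx, ny);
            if (out[i] < 1.0) out[i] = 1.0;
          }
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear interpolation at physical points (µm); outside-volume samples
// return NA.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector arr, NumericVector spacing, NumericMatrix pts) {
  int nx, ny, nz; get_dims(arr, nx, ny, nz);
  int np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double fx = pts(p, 0) / spacing[0] - 0.5;
    double fy = pts(p, 1) / spacing[1] - 0.5;
    double fz = pts(p, 2) / spacing[2] - 0.5;
    if (fx < 0 || fy < 0 || fz < 0 || fx > nx - 1 || fy > ny - 1 || fz > nz - 1) {
      out[p] = NA_REAL; continue;
    }
    int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1), z1 = std::min(z0 + 1, nz - 1);
    double tx = fx - x0, ty = fy - y0, tz = fz - z0;
    double c000 = arr[vidx(x0, y0, z0, nx, ny)], c100 = arr[vidx(x1, y0, z0, nx, ny)];
    double c010 = arr[vidx(x0, y1, z0, nx, ny)], c110 = arr[vidx(x1, y1, z0, nx, ny)];
    double c001 = arr[vidx(x0, y0, z1, nx, ny)], c101 = arr[vidx(x1, y0, z1, nx, ny)];
    double c011 = arr[vidx(x0, y1, z1, nx, ny)], c111 = arr[vidx(x1, y1, z1, nx, ny)];
    double c00 = c000 + tx * (c100 - c000), c10 = c010 + tx * (c110 - c010);
    double c01 = c001 + tx * (c101 - c001), c11 = c011 + tx * (c111 - c011);
    double c0 = c00 + ty * (c10 - c00), c1 = c01 + ty * (c11 - c01);
    out[p] = c0 + tz * (c1 - c0);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Three-pass box blur per axis: O(N) approximation of a wide Gaussian,
// used for background estimation where kernel precision is immaterial.
// [[Rcpp::export]]
NumericVector cpp_box_blur3d(NumericVector arr, NumericVector sigma_vox) {
  int nx, ny, nz; get_dims(arr, nx, ny, nz);
  std::vector<double> cur(arr.begin(), arr.end()), nxt(cur.size());
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    // box half-width so that 3 passes approximate sigma: w = sigma*sqrt(12/3)/2
    int r = std::max(1, (int)std::round(s * std::sqrt(12.0 / 3.0) / 2.0));
    int len = n[ax];
    R_xlen_t st = stride[ax];
    int a1 = (ax == 0) ? 1 : 0;
    int a2 = (ax == 2) ? 1 : 2;
    std::vector<double> line(len), out(len);
    for (int pass = 0; pass < 3; ++pass) {
      for (int j2 = 0; j2 < n[a2]; ++j2) {
        for (int j1 = 0; j1 < n[a1]; ++j1) {
          R_xlen_t base = stride[a1] * j1 + stride[a2] * j2;
          for (int i = 0; i < len; ++i) line[i] = cur[base + st * i];
          double acc = 0; int cnt = 0;
          for (int i = 0; i < std::min(r, len); ++i) { acc += line[i]; ++cnt; }
          for (int i = 0; i < len; ++i) {
            int add = i + r;
            if (add < len) { acc += line[add]; ++cnt; }
            int rem = i - r - 1;
            if (rem >= 0) { acc -= line[rem]; --cnt; }
            out[i] = acc / cnt;
          }
          for (int i = 0; i < len; ++i) cur[base + st * i] = out[i];
        }
      }
    }
  }
  NumericVector res(cur.begin(), cur.end());
  res.attr("dim") = arr.attr("dim");
  return res;
}
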
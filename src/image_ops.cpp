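// 3D image primitives: median filter, binary morphology, separable smoothing,
// exact Euclidean distance transform, curve-skeleton thinning and fiber
// rasterization. Arrays are column-major with dims (nx, ny, nz), axes (x,y,z).
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int reflect(int i, int n) {
  // reflect-101-style without repeating the border twice collapses for n==1;
  // use simple mirror (edge repeated) which is safe for any n >= 1
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - 1 - i;
  if (i < 0) i = 0;
  if (i >= n) i = n - 1;
  return i;
}

// [[Rcpp::export]]
NumericVector cpp_median_filter3d(NumericVector vol, IntegerVector dim, int kernel) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int h = kernel / 2;
  const int wsize = kernel * kernel * kernel;
  NumericVector out(vol.size());
  std::vector<double> buf(wsize);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int m = 0;
        for (int dk = -h; dk <= h; ++dk) {
          int kk = reflect(k + dk, nz);
          for (int dj = -h; dj <= h; ++dj) {
            int jj = reflect(j + dj, ny);
            for (int di = -h; di <= h; ++di) {
              int ii = reflect(i + di, nx);
              buf[m++] = vol[ii + nx * (jj + (R_xlen_t)ny * kk)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + wsize / 2, buf.begin() + wsize);
        out[i + nx * (j + (R_xlen_t)ny * k)] = buf[wsize / 2];
      }
    }
  }
  return out;
}

// Binary dilation/erosion with an explicit offset list (one row per offset,
// columns dx,dy,dz). Outside the grid counts as background for dilation and
// as foreground for erosion, so structures clipped at the domain faces are
// not eaten away from the boundary side.
// [[Rcpp::export]]
LogicalVector cpp_binary_morph(LogicalVector mask, IntegerVector dim,
                               IntegerMatrix offsets, bool dilate) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int noff = offsets.nrow();
  LogicalVector out(mask.size());
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        bool hit = dilate ? false : true;
        for (int o = 0; o < noff; ++o) {
          int ii = i + offsets(o, 0), jj = j + offsets(o, 1), kk = k + offsets(o, 2);
          bool v;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) {
            v = dilate ? false : true;
          } else {
            v = mask[ii + nx * (jj + (R_xlen_t)ny * kk)];
          }
          if (dilate) { if (v) { hit = true; break; } }
          else        { if (!v) { hit = false; break; } }
        }
        out[i + nx * (j + (R_xlen_t)ny * k)] = hit;
      }
    }
  }
  return out;
}

static void sep_filter(std::vector<double>& a, int nx, int ny, int nz,
                       const std::vector<double>& w) {
  const int h = (int)w.size() / 2;
  std::vector<double> line;
  // x axis
  line.resize(nx);
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) {
    R_xlen_t base = nx * (j + (R_xlen_t)ny * k);
    for (int i = 0; i < nx; ++i) {
      double s = 0;
      for (int d = -h; d <= h; ++d) s += w[d + h] * a[reflect(i + d, nx) + base];
      line[i] = s;
    }
    for (int i = 0; i < nx; ++i) a[i + base] = line[i];
  }
  // y axis
  line.resize(ny);
  for (int k = 0; k < nz; ++k) for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      double s = 0;
      for (int d = -h; d <= h; ++d)
        s += w[d + h] * a[i + nx * (reflect(j + d, ny) + (R_xlen_t)ny * k)];
      line[j] = s;
    }
    for (int j = 0; j < ny; ++j) a[i + nx * (j + (R_xlen_t)ny * k)] = line[j];
  }
  // z axis
  line.resize(nz);
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    for (int k = 0; k < nz; ++k) {
      double s = 0;
      for (int d = -h; d <= h; ++d)
        s += w[d + h] * a[i + nx * (j + (R_xlen_t)ny * reflect(k + d, nz))];
      line[k] = s;
    }
    for (int k = 0; k < nz; ++k) a[i + nx * (j + (R_xlen_t)ny * k)] = line[k];
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3d(NumericVector vol, IntegerVector dim, double sigma) {
  std::vector<double> a(vol.begin(), vol.end());
  int h = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> w(2 * h + 1);
  double s = 0;
  for (int d = -h; d <= h; ++d) { w[d + h] = std::exp(-0.5 * d * d / (sigma * sigma)); s += w[d + h]; }
  for (double& x : w) x /= s;
  sep_filter(a, dim[0], dim[1], dim[2], w);
  return NumericVector(a.begin(), a.end());
}

// [[Rcpp::export]]
NumericVector cpp_box_mean3(NumericVector vol, IntegerVector dim) {
  std::vector<double> a(vol.begin(), vol.end());
  std::vector<double> w(3, 1.0 / 3.0);
  sep_filter(a, dim[0], dim[1], dim[2], w);
  return NumericVector(a.begin(), a.end());
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with grid
// spacing w; f holds squared distances, positions are w*index.
static void dt1d(std::vector<double>& f, int n, double w,
                 std::vector<int>& v, std::vector<double>& z, std::vector<double>& d) {
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double xq = w * q, xv = w * v[k];
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = w * q;
    while (z[k + 1] < xq) ++k;
    double dx = xq - w * v[k];
    d[q] = dx * dx + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact Euclidean distance (physical units) from each foreground voxel to the
// nearest background voxel center; 0 on background.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = 1e30;
  std::vector<double> d2((R_xlen_t)nx * ny * nz);
  for (R_xlen_t t = 0; t < (R_xlen_t)nx * ny * nz; ++t) d2[t] = mask[t] ? INF : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1), dbuf(nmax), line(nmax);
  // x
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) {
    R_xlen_t base = nx * (j + (R_xlen_t)ny * k);
    for (int i = 0; i < nx; ++i) line[i] = d2[i + base];
    dt1d(line, nx, spacing[0], v, z, dbuf);
    for (int i = 0; i < nx; ++i) d2[i + base] = line[i];
  }
  // y
  for (int k = 0; k < nz; ++k) for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) line[j] = d2[i + nx * (j + (R_xlen_t)ny * k)];
    dt1d(line, ny, spacing[1], v, z, dbuf);
    for (int j = 0; j < ny; ++j) d2[i + nx * (j + (R_xlen_t)ny * k)] = line[j];
  }
  // z
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    for (int k = 0; k < nz; ++k) line[k] = d2[i + nx * (j + (R_xlen_t)ny * k)];
    dt1d(line, nz, spacing[2], v, z, dbuf);
    for (int k = 0; k < nz; ++k) d2[i + nx * (j + (R_xlen_t)ny * k)] = line[k];
  }
  NumericVector out(mask.size());
  for (R_xlen_t t = 0; t < (R_xlen_t)out.size(); ++t) out[t] = std::sqrt(d2[t]);
  return out;
}

// ---- topological thinning -------------------------------------------------

// local 3x3x3 neighborhood flags, index = (dx+1) + 3*(dy+1) + 9*(dz+1)
static inline int lidx(int dx, int dy, int dz) { return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1); }

// Simple-point test for 26-connected foreground / 6-connected background
// (Malandain & Bertrand conditions):
//   A: the foreground voxels of N26 form exactly one 26-connected component.
//   B: the background voxels of N18 that are 6-adjacent to the center form
//      exactly one 6-connected component within N18.
static bool is_simple(const bool nb[27]) {
  // --- condition A ---
  bool fg[27];
  int nfg = 0;
  for (int t = 0; t < 27; ++t) { fg[t] = (t != 13) && nb[t]; if (fg[t]) ++nfg; }
  if (nfg == 0) return false;
  // BFS over 26-connectivity in the 3x3x3 box (center excluded)
  int stack[27], ns = 0;
  bool seen[27] = {false};
  for (int t = 0; t < 27; ++t) if (fg[t]) { stack[ns++] = t; seen[t] = true; break; }
  int head = 0, cnt = 0;
  while (head < ns) {
    int cur = stack[head++]; ++cnt;
    int cx = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cz = cur / 9 - 1;
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
      if (!dx && !dy && !dz) continue;
      int xx = cx + dx, yy = cy + dy, zz = cz + dz;
      if (xx < -1 || xx > 1 || yy < -1 || yy > 1 || zz < -1 || zz > 1) continue;
      int t = lidx(xx, yy, zz);
      if (fg[t] && !seen[t]) { seen[t] = true; stack[ns++] = t; }
    }
  }
  if (cnt != nfg) return false;
  // --- condition B ---
  // background within N18 (positions with |dx|+|dy|+|dz| <= 2, excluding center)
  bool bg18[27] = {false};
  for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
    int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
    if (man == 0 || man > 2) continue;
    int t = lidx(dx, dy, dz);
    if (!nb[t]) bg18[t] = true;
  }
  // seeds: 6-neighbors of center that are background
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  int seed = -1, nseed = 0;
  bool isseed[27] = {false};
  for (int s = 0; s < 6; ++s) {
    int t = lidx(d6[s][0], d6[s][1], d6[s][2]);
    if (bg18[t]) { isseed[t] = true; ++nseed; if (seed < 0) seed = t; }
  }
  if (nseed == 0) return false;
  // BFS over 6-connectivity within N18
  bool seenb[27] = {false};
  int st2[27], ns2 = 0, head2 = 0;
  st2[ns2++] = seed; seenb[seed] = true;
  while (head2 < ns2) {
    int cur = st2[head2++];
    int cx = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cz = cur / 9 - 1;
    for (int s = 0; s < 6; ++s) {
      int xx = cx + d6[s][0], yy = cy + d6[s][1], zz = cz + d6[s][2];
      if (xx < -1 || xx > 1 || yy < -1 || yy > 1 || zz < -1 || zz > 1) continue;
      int t = lidx(xx, yy, zz);
      if (bg18[t] && !seenb[t]) { seenb[t] = true; st2[ns2++] = t; }
    }
  }
  for (int t = 0; t < 27; ++t) if (isseed[t] && !seenb[t]) return false;
  return true;
}

// Iterative 6-subiteration thinning to a curve skeleton; curve endpoints
// (exactly one 26-neighbor) are preserved. Outside the grid is background.
// [[Rcpp::export]]
LogicalVector cpp_skeletonize3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<char> m(mask.size());
  std::vector<R_xlen_t> fgidx;
  for (R_xlen_t t = 0; t < (R_xlen_t)mask.size(); ++t) {
    m[t] = mask[t] ? 1 : 0;
    if (m[t]) fgidx.push_back(t);
  }
  auto getnb = [&](int i, int j, int k, bool nb[27], int& n26) {
    n26 = 0;
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
      int t = lidx(dx, dy, dz);
      int ii = i + dx, jj = j + dy, kk = k + dz;
      bool v = false;
      if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
        v = m[ii + nx * (jj + (R_xlen_t)ny * kk)] != 0;
      nb[t] = v;
      if (v && t != 13) ++n26;
    }
    nb[13] = true;
  };
  const int dirs[6][3] = {{0,1,0},{0,-1,0},{0,0,1},{0,0,-1},{1,0,0},{-1,0,0}};
  bool changed = true;
  std::vector<R_xlen_t> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (R_xlen_t t : fgidx) {
        if (!m[t]) continue;
        int i = (int)(t % nx), j = (int)((t / nx) % ny), k = (int)(t / ((R_xlen_t)nx * ny));
        // border in direction d?
        int ii = i + dirs[d][0], jj = j + dirs[d][1], kk = k + dirs[d][2];
        bool nbv = false;
        if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
          nbv = m[ii + nx * (jj + (R_xlen_t)ny * kk)] != 0;
        if (nbv) continue;
        bool nb[27]; int n26;
        getnb(i, j, k, nb, n26);
        if (n26 == 1) continue;       // curve endpoint: keep
        if (n26 == 0) continue;       // isolated voxel: keep
        if (!is_simple(nb)) continue;
        cand.push_back(t);
      }
      // sequential re-check so topology is preserved exactly
      for (R_xlen_t t : cand) {
        int i = (int)(t % nx), j = (int)((t / nx) % ny), k = (int)(t / ((R_xlen_t)nx * ny));
        bool nb[27]; int n26;
        getnb(i, j, k, nb, n26);
        if (n26 <= 1) continue;
        if (!is_simple(nb)) continue;
        m[t] = 0;
        changed = true;
      }
    }
    // compact foreground index list
    std::vector<R_xlen_t> keep;
    keep.reserve(fgidx.size());
    for (R_xlen_t t : fgidx) if (m[t]) keep.push_back(t);
    fgidx.swap(keep);
  }
  LogicalVector out(mask.size());
  for (R_xlen_t t = 0; t < (R_xlen_t)out.size(); ++t) out[t] = m[t] != 0;
  return out;
}

// Rasterize capsule segments: voxel is foreground when its center lies within
// the segment radius of the segment (spherical caps included). Coordinates in
// physical units; voxel centers at origin + (index + 0.5) * spacing.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_segments(NumericMatrix p1, NumericMatrix p2,
                                     NumericVector radius, IntegerVector dim,
                                     NumericVector spacing, NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const int nseg = p1.nrow();
  for (int s = 0; s < nseg; ++s) {
    double ax = p1(s,0), ay = p1(s,1), az = p1(s,2);
    double bx = p2(s,0), by = p2(s,1), bz = p2(s,2);
    double r = radius[s];
    double lox = std::min(ax,bx)-r, hix = std::max(ax,bx)+r;
    double loy = std::min(ay,by)-r, hiy = std::max(ay,by)+r;
    double loz = std::min(az,bz)-r, hiz = std::max(az,bz)+r;
    int i0 = std::max(0, (int)std::floor((lox - origin[0]) / spacing[0] - 0.5));
    int i1 = std::min(nx - 1, (int)std::ceil((hix - origin[0]) / spacing[0] - 0.5));
    int j0 = std::max(0, (int)std::floor((loy - origin[1]) / spacing[1] - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil((hiy - origin[1]) / spacing[1] - 0.5));
    int k0 = std::max(0, (int)std::floor((loz - origin[2]) / spacing[2] - 0.5));
    int k1 = std::min(nz - 1, (int)std::ceil((hiz - origin[2]) / spacing[2] - 0.5));
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double L2 = ux*ux + uy*uy + uz*uz;
    double r2 = r * r;
    for (int k = k0; k <= k1; ++k) {
      double cz = origin[2] + (k + 0.5) * spacing[2];
      for (int j = j0; j <= j1; ++j) {
        double cy = origin[1] + (j + 0.5) * spacing[1];
        for (int i = i0; i <= i1; ++i) {
          double cx = origin[0] + (i + 0.5) * spacing[0];
          double wx = cx - ax, wy = cy - ay, wz = cz - az;
          double t = L2 > 0 ? std::max(0.0, std::min(1.0, (wx*ux + wy*uy + wz*uz) / L2)) : 0.0;
          double dx = wx - t * ux, dy = wy - t * uy, dz = wz - t * uz;
          if (dx*dx + dy*dy + dz*dz <= r2)
            out[i + nx * (j + (R_xlen_t)ny * k)] = true;
        }
      }
    }
  }
  return out;
}

// count of exposed voxel faces (foreground faces adjacent to background or
// the grid boundary) -- surface-area oracle for smoothing tests
// [[Rcpp::export]]
double cpp_exposed_faces(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  double cnt = 0;
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    if (!mask[i + nx * (j + (R_xlen_t)ny * k)]) continue;
    for (int s = 0; s < 6; ++s) {
      int ii = i + d6[s][0], jj = j + d6[s][1], kk = k + d6[s][2];
      bool v = false;
      if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
        v = mask[ii + nx * (jj + (R_xlen_t)ny * kk)];
      if (!v) cnt += 1;
    }
  }
  return cnt;
}
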
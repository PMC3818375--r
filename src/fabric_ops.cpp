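#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Voxel arrays are passed flattened in R's column-major order with the first
// index (x) fastest: idx = x + nx*(y + ny*z). Coordinates are 0-based voxel
// centers throughout.

static inline double frac(double x) { return x - std::floor(x); }

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + (long)ny * z);
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distance from each foreground voxel to the nearest background voxel center.
// Background voxels get 0. Foreground with no background anywhere -> R_PosInf.
// ---------------------------------------------------------------------------

// caller guarantees at least one finite entry; infinite parabolas are
// skipped (they never contribute to the lower envelope)
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int q0 = 0;
  while (f[q0] == INFINITY) q0++;
  int k = 0;
  v[0] = q0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  auto intersect = [&](int q, int p) {
    return ((f[q] + q * (double)q) - (f[p] + p * (double)p)) /
           (2.0 * q - 2.0 * p);
  };
  for (int q = q0 + 1; q < n; q++) {
    if (f[q] == INFINITY) continue;
    double s = intersect(q, v[k]);
    while (k > 0 && s <= z[k]) { k--; s = intersect(q, v[k]); }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector phase, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  NumericVector out(n);
  for (long i = 0; i < n; i++) out[i] = phase[i] ? INFINITY : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);

  // pass along x
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      bool any_fin = false;
      for (int x = 0; x < nx; x++) { f[x] = out[idx3(x,y,z,nx,ny)]; if (f[x] != INFINITY) any_fin = true; }
      if (!any_fin) continue;
      dt1d(f, d, nx);
      for (int x = 0; x < nx; x++) out[idx3(x,y,z,nx,ny)] = d[x];
    }
  // pass along y
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      bool any_fin = false;
      for (int y = 0; y < ny; y++) { f[y] = out[idx3(x,y,z,nx,ny)]; if (f[y] != INFINITY) any_fin = true; }
      if (!any_fin) continue;
      dt1d(f, d, ny);
      for (int y = 0; y < ny; y++) out[idx3(x,y,z,nx,ny)] = d[y];
    }
  // pass along z
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      bool any_fin = false;
      for (int z = 0; z < nz; z++) { f[z] = out[idx3(x,y,z,nx,ny)]; if (f[z] != INFINITY) any_fin = true; }
      if (!any_fin) continue;
      dt1d(f, d, nz);
      for (int z = 0; z < nz; z++) out[idx3(x,y,z,nx,ny)] = d[z];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Local thickness by sphere fitting: every distance-ridge voxel (26-neighbour
// local maximum of the EDT) paints max(th, 2*d - 1) over its inscribed ball of
// radius d - 0.5. Voxels left unpainted fall back to their own 2*d - 1.
// dist: Euclidean distance (not squared) to background; 0 outside the phase.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_local_thickness(NumericVector dist, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  NumericVector th(n);

  // collect ridge voxels
  std::vector<long> ridge;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        long i = idx3(x,y,z,nx,ny);
        double dv = dist[i];
        if (dv <= 0) continue;
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; dz++)
          for (int dy = -1; dy <= 1 && ismax; dy++)
            for (int dx = -1; dx <= 1; dx++) {
              if (!dx && !dy && !dz) continue;
              int X = x+dx, Y = y+dy, Z = z+dz;
              if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
              if (dist[idx3(X,Y,Z,nx,ny)] > dv) { ismax = false; break; }
            }
        if (ismax) ridge.push_back(i);
      }

  std::sort(ridge.begin(), ridge.end(), [&](long a, long b){ return dist[a] > dist[b]; });

  for (long ri : ridge) {
    double dv = dist[ri];
    double t = 2.0 * dv - 1.0;
    // paint over |q - p| <= d: slightly generous coverage so rasterization
    // bumps on curved boundaries inherit the enclosing sphere's thickness
    double r = dv;
    int x0 = (int)(ri % nx);
    int y0 = (int)((ri / nx) % ny);
    int z0 = (int)(ri / ((long)nx * ny));
    int rr = (int)std::floor(r);
    double r2 = r * r;
    for (int dz = -rr; dz <= rr; dz++) {
      int Z = z0 + dz; if (Z < 0 || Z >= nz) continue;
      for (int dy = -rr; dy <= rr; dy++) {
        int Y = y0 + dy; if (Y < 0 || Y >= ny) continue;
        double dd = (double)dz*dz + (double)dy*dy;
        if (dd > r2) continue;
        int dxm = (int)std::floor(std::sqrt(r2 - dd));
        int Xa = std::max(0, x0 - dxm), Xb = std::min(nx - 1, x0 + dxm);
        long base = idx3(0, Y, Z, nx, ny);
        for (int X = Xa; X <= Xb; X++) {
          long i = base + X;
          if (th[i] < t) th[i] = t;
        }
      }
    }
  }
  // fallback: own inscribed ball
  for (long i = 0; i < n; i++)
    if (dist[i] > 0 && th[i] <= 0) th[i] = 2.0 * dist[i] - 1.0;
  return th;
}

// ---------------------------------------------------------------------------
// Euler characteristic of the cubical complex spanned by foreground voxels
// (each voxel a closed unit cube; shared vertices/edges/faces counted once).
// This is the 26-connectivity foreground convention.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_euler3d(LogicalVector vol, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  auto at = [&](int x, int y, int z) -> bool {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return false;
    return vol[idx3(x,y,z,nx,ny)];
  };
  long V = 0, E = 0, F = 0, C = 0;
  for (int z = 0; z <= nz; z++)
    for (int y = 0; y <= ny; y++)
      for (int x = 0; x <= nx; x++) {
        // vertex (x,y,z): incident cubes (x-1..x, y-1..y, z-1..z)
        bool v = false;
        for (int dz = -1; dz <= 0 && !v; dz++)
          for (int dy = -1; dy <= 0 && !v; dy++)
            for (int dx = -1; dx <= 0; dx++)
              if (at(x+dx, y+dy, z+dz)) { v = true; break; }
        if (v) V++;
        // x-edge from (x,y,z): cubes (x, y-1..y, z-1..z); needs x < nx
        if (x < nx) {
          bool e = at(x,y-1,z-1) || at(x,y,z-1) || at(x,y-1,z) || at(x,y,z);
          if (e) E++;
        }
        if (y < ny) {
          bool e = at(x-1,y,z-1) || at(x,y,z-1) || at(x-1,y,z) || at(x,y,z);
          if (e) E++;
        }
        if (z < nz) {
          bool e = at(x-1,y-1,z) || at(x,y-1,z) || at(x-1,y,z) || at(x,y,z);
          if (e) E++;
        }
        // faces: z-normal at (x,y,z) spans x,y; cubes (x,y,z-1..z)
        if (x < nx && y < ny) { if (at(x,y,z-1) || at(x,y,z)) F++; }
        if (x < nx && z < nz) { if (at(x,y-1,z) || at(x,y,z)) F++; }
        if (y < ny && z < nz) { if (at(x-1,y,z) || at(x,y,z)) F++; }
        if (x < nx && y < ny && z < nz) { if (at(x,y,z)) C++; }
      }
  return (double)V - (double)E + (double)F - (double)C;
}

// ---------------------------------------------------------------------------
// Connected components count (26- or 6-connectivity) by flood fill.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
int cpp_count_components(LogicalVector vol, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<long> stack;
  int ncomp = 0;
  for (long s = 0; s < n; s++) {
    if (!vol[s] || seen[s]) continue;
    ncomp++;
    seen[s] = 1;
    stack.push_back(s);
    while (!stack.empty()) {
      long i = stack.back(); stack.pop_back();
      int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / ((long)nx*ny));
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (!dx && !dy && !dz) continue;
            if (connectivity == 6 && (std::abs(dx)+std::abs(dy)+std::abs(dz)) != 1) continue;
            int X = x+dx, Y = y+dy, Z = z+dz;
            if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
            long j = idx3(X,Y,Z,nx,ny);
            if (vol[j] && !seen[j]) { seen[j] = 1; stack.push_back(j); }
          }
    }
  }
  return ncomp;
}

// ---------------------------------------------------------------------------
// MIL line tracing. Test lines are marched at a sub-voxel step; the bone
// phase is tracked from the (bi/tri)linearly interpolated binary field with
// hysteresis (flip to bone at >= 0.75, to background at <= 0.25), which
// suppresses the staircase chatter of rasterized oblique interfaces while
// keeping genuine crossings. Consecutive in-mask samples contribute `step`
// to the line length and one crossing whenever the phase flips.
// ---------------------------------------------------------------------------

static inline double sample3(const LogicalVector &v, int nx, int ny, int nz,
                             double sx, double sy, double sz) {
  int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
  double fx = sx - x0, fy = sy - y0, fz = sz - z0;
  double acc = 0;
  for (int dz = 0; dz <= 1; dz++) {
    int Z = z0 + dz; double wz = dz ? fz : 1 - fz;
    for (int dy = 0; dy <= 1; dy++) {
      int Y = y0 + dy; double wy = dy ? fy : 1 - fy;
      for (int dx = 0; dx <= 1; dx++) {
        int X = x0 + dx; double wx = dx ? fx : 1 - fx;
        double val = (X >= 0 && Y >= 0 && Z >= 0 && X < nx && Y < ny && Z < nz)
                       ? (v[idx3(X,Y,Z,nx,ny)] ? 1.0 : 0.0) : 0.0;
        acc += wx * wy * wz * val;
      }
    }
  }
  return acc;
}

static inline double sample2(const LogicalVector &v, int nx, int nz,
                             double sx, double sz) {
  int x0 = (int)std::floor(sx), z0 = (int)std::floor(sz);
  double fx = sx - x0, fz = sz - z0;
  double acc = 0;
  for (int dz = 0; dz <= 1; dz++) {
    int Z = z0 + dz; double wz = dz ? fz : 1 - fz;
    for (int dx = 0; dx <= 1; dx++) {
      int X = x0 + dx; double wx = dx ? fx : 1 - fx;
      double val = (X >= 0 && Z >= 0 && X < nx && Z < nz)
                     ? (v[X + (long)nx * Z] ? 1.0 : 0.0) : 0.0;
      acc += wx * wz * val;
    }
  }
  return acc;
}

// [[Rcpp::export]]
NumericMatrix cpp_mil_3d(LogicalVector bone, LogicalVector mask, IntegerVector dims,
                         NumericMatrix dirs, double line_spacing, double step,
                         NumericMatrix offsets) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ndir = dirs.nrow();
  NumericMatrix out(ndir, 2); // total length, crossings
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  double R = 0.5 * std::sqrt((double)nx*nx + (double)ny*ny + (double)nz*nz);

  for (int k = 0; k < ndir; k++) {
    double dx = dirs(k,0), dy = dirs(k,1), dz = dirs(k,2);
    // orthonormal basis perpendicular to the direction
    double ax = 0, ay = 0, az = 1;
    if (std::fabs(dz) > 0.9) { ax = 1; az = 0; }
    double ux = dy*az - dz*ay, uy = dz*ax - dx*az, uz = dx*ay - dy*ax;
    double un = std::sqrt(ux*ux + uy*uy + uz*uz);
    ux /= un; uy /= un; uz /= un;
    double vx = dy*uz - dz*uy, vy = dz*ux - dx*uz, vz = dx*uy - dy*ux;

    double oa = offsets(k,0), ob = offsets(k,1);
    double tot_len = 0; double tot_cross = 0;
    const double GOLD = 0.6180339887498949;

    int Ka = (int)std::floor(2 * R / line_spacing);
    int Kb = Ka;
    for (int ia = 0; ia <= Ka; ia++) {
      // per-line fractional offsets decorrelate the grid phase from the voxel
      // lattice (a single shared phase biases crossing counts by several %)
      double fa = frac(oa + ia * GOLD);
      double a = -R + (ia + fa) * line_spacing;
      if (a > R) continue;
      for (int ib = 0; ib <= Kb; ib++) {
        double fb = frac(ob + ib * GOLD);
        double b = -R + (ib + fb) * line_spacing;
        if (b > R) continue;
        double px = cx + a*ux + b*vx, py = cy + a*uy + b*vy, pz = cz + a*uz + b*vz;
        // clip line px + t*d to the volume box [-0.5, n-0.5]
        double tmin = -INFINITY, tmax = INFINITY;
        double P[3] = {px, py, pz}, D[3] = {dx, dy, dz};
        int N[3] = {nx, ny, nz};
        bool miss = false;
        for (int ax2 = 0; ax2 < 3; ax2++) {
          if (std::fabs(D[ax2]) < 1e-12) {
            if (P[ax2] < -0.5 || P[ax2] > N[ax2] - 0.5) { miss = true; break; }
          } else {
            double t0 = (-0.5 - P[ax2]) / D[ax2];
            double t1 = (N[ax2] - 0.5 - P[ax2]) / D[ax2];
            if (t0 > t1) std::swap(t0, t1);
            tmin = std::max(tmin, t0);
            tmax = std::min(tmax, t1);
          }
        }
        if (miss || tmax <= tmin) continue;
        bool prev_in = false;
        int state = -1; // unknown until first decisive sample
        for (double t = tmin; t <= tmax; t += step) {
          double sx = px + t*dx, sy = py + t*dy, sz = pz + t*dz;
          int X = (int)std::lround(sx);
          int Y = (int)std::lround(sy);
          int Z = (int)std::lround(sz);
          bool in = (X >= 0 && Y >= 0 && Z >= 0 && X < nx && Y < ny && Z < nz);
          if (in) in = mask[idx3(X,Y,Z,nx,ny)];
          if (!in) { prev_in = false; state = -1; continue; }
          double val = sample3(bone, nx, ny, nz, sx, sy, sz);
          int ns = state;
          if (val >= 0.75) ns = 1;
          else if (val <= 0.25) ns = 0;
          else if (state == -1) ns = val >= 0.5 ? 1 : 0;
          if (prev_in) {
            tot_len += step;
            if (ns != state) tot_cross += 1;
          }
          state = ns; prev_in = true;
        }
      }
    }
    out(k,0) = tot_len;
    out(k,1) = tot_cross;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_mil_2d(LogicalVector img, LogicalVector mask, IntegerVector dims,
                         NumericVector thetas_rad, double line_spacing, double step,
                         NumericVector offsets) {
  int nx = dims[0], nz = dims[1];
  int nth = thetas_rad.size();
  NumericMatrix out(nth, 2);
  double cx = (nx - 1) / 2.0, cz = (nz - 1) / 2.0;
  double R = 0.5 * std::sqrt((double)nx*nx + (double)nz*nz);

  for (int k = 0; k < nth; k++) {
    double dx = std::cos(thetas_rad[k]), dz = std::sin(thetas_rad[k]);
    double ux = -dz, uz = dx; // perpendicular
    double oa = offsets[k];
    double tot_len = 0, tot_cross = 0;
    const double GOLD = 0.6180339887498949;
    int Ka = (int)std::floor(2 * R / line_spacing);
    for (int ia = 0; ia <= Ka; ia++) {
      double fa = frac(oa + ia * GOLD);
      double a = -R + (ia + fa) * line_spacing;
      if (a > R) continue;
      double px = cx + a*ux, pz = cz + a*uz;
      double tmin = -INFINITY, tmax = INFINITY;
      double P[2] = {px, pz}, D[2] = {dx, dz};
      int N[2] = {nx, nz};
      bool miss = false;
      for (int ax = 0; ax < 2; ax++) {
        if (std::fabs(D[ax]) < 1e-12) {
          if (P[ax] < -0.5 || P[ax] > N[ax] - 0.5) { miss = true; break; }
        } else {
          double t0 = (-0.5 - P[ax]) / D[ax];
          double t1 = (N[ax] - 0.5 - P[ax]) / D[ax];
          if (t0 > t1) std::swap(t0, t1);
          tmin = std::max(tmin, t0);
          tmax = std::min(tmax, t1);
        }
      }
      if (miss || tmax <= tmin) continue;
      bool prev_in = false;
      int state = -1;
      for (double t = tmin; t <= tmax; t += step) {
        double sx = px + t*dx, sz = pz + t*dz;
        int X = (int)std::lround(sx);
        int Z = (int)std::lround(sz);
        bool in = (X >= 0 && Z >= 0 && X < nx && Z < nz);
        if (in) in = mask[X + (long)nx * Z];
        if (!in) { prev_in = false; state = -1; continue; }
        double val = sample2(img, nx, nz, sx, sz);
        int ns = state;
        if (val >= 0.75) ns = 1;
        else if (val <= 0.25) ns = 0;
        else if (state == -1) ns = val >= 0.5 ? 1 : 0;
        if (prev_in) {
          tot_len += step;
          if (ns != state) tot_cross += 1;
        }
        state = ns; prev_in = true;
      }
    }
    out(k,0) = tot_len;
    out(k,1) = tot_cross;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear affine resampling: out(p) = vol(Rinv %*% (p - c_out) + c_in).
// Samples outside the input grid evaluate to `fill`.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_affine_resample(NumericVector vol, IntegerVector dims_in,
                                  IntegerVector dims_out, NumericMatrix rinv,
                                  NumericVector c_in, NumericVector c_out,
                                  double fill) {
  int nx = dims_in[0], ny = dims_in[1], nz = dims_in[2];
  int mx = dims_out[0], my = dims_out[1], mz = dims_out[2];
  NumericVector out((long)mx * my * mz);
  double r11 = rinv(0,0), r12 = rinv(0,1), r13 = rinv(0,2);
  double r21 = rinv(1,0), r22 = rinv(1,1), r23 = rinv(1,2);
  double r31 = rinv(2,0), r32 = rinv(2,1), r33 = rinv(2,2);
  long o = 0;
  for (int z = 0; z < mz; z++)
    for (int y = 0; y < my; y++)
      for (int x = 0; x < mx; x++, o++) {
        double qx = x - c_out[0], qy = y - c_out[1], qz = z - c_out[2];
        double sx = r11*qx + r12*qy + r13*qz + c_in[0];
        double sy = r21*qx + r22*qy + r23*qz + c_in[1];
        double sz = r31*qx + r32*qy + r33*qz + c_in[2];
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
        if (x0 < -1 || y0 < -1 || z0 < -1 || x0 >= nx || y0 >= ny || z0 >= nz) {
          out[o] = fill; continue;
        }
        double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        double acc = 0;
        for (int dz = 0; dz <= 1; dz++) {
          int Z = z0 + dz; double wz = dz ? fz : 1 - fz;
          for (int dy = 0; dy <= 1; dy++) {
            int Y = y0 + dy; double wy = dy ? fy : 1 - fy;
            for (int dx = 0; dx <= 1; dx++) {
              int X = x0 + dx; double wx = dx ? fx : 1 - fx;
              double v = (X >= 0 && Y >= 0 && Z >= 0 && X < nx && Y < ny && Z < nz)
                           ? vol[idx3(X,Y,Z,nx,ny)] : fill;
              acc += wx * wy * wz * v;
            }
          }
        }
        out[o] = acc;
      }
  return out;
}

// ---------------------------------------------------------------------------
// |median(A) - median(B)| for every allocation column (1-based indices into
// pool); used by the exhaustive/Monte-Carlo permutation engine.
// ---------------------------------------------------------------------------

static double median_of(std::vector<double> &v) {
  size_t n = v.size();
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double hi = v[n / 2];
  if (n % 2) return hi;
  double lo = *std::max_element(v.begin(), v.begin() + n / 2);
  return (lo + hi) / 2.0;
}

// [[Rcpp::export]]
NumericVector cpp_perm_median_stats(NumericVector pool, IntegerMatrix alloc) {
  int n = pool.size(), nA = alloc.nrow(), m = alloc.ncol();
  NumericVector out(m);
  std::vector<char> inA(n);
  std::vector<double> a(nA), b(n - nA);
  for (int j = 0; j < m; j++) {
    std::fill(inA.begin(), inA.end(), 0);
    for (int i = 0; i < nA; i++) inA[alloc(i, j) - 1] = 1;
    int ia = 0, ib = 0;
    for (int i = 0; i < n; i++) (inA[i] ? a[ia++] : b[ib++]) = pool[i];
    out[j] = std::fabs(median_of(a) - median_of(b));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Direct-form II transposed IIR filter, y[n] = (b*x - a[2:]*y)/a[1].
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_iir(NumericVector b, NumericVector a, NumericVector x,
                      double x_init) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nw = std::max(na, nb);
  // steady-state (DC) initial conditions scaled by x_init, so constant
  // signals pass through without transients (assumes a[0] == 1-normalized
  // coefficients with unit DC gain)
  std::vector<double> w(nw, 0.0);
  for (int j = nw - 1; j >= 1; j--) {
    double bj = j < nb ? b[j] : 0.0;
    double aj = j < na ? a[j] : 0.0;
    w[j-1] = (bj - aj) * x_init + (j < nw - 1 ? w[j] : 0.0);
  }
  NumericVector y(n);
  double a0 = a[0];
  for (int i = 0; i < n; i++) {
    double yi = (b[0] * x[i] + w[0]) / a0;
    for (int j = 1; j < nw; j++) {
      double bj = j < nb ? b[j] : 0.0;
      double aj = j < na ? a[j] : 0.0;
      w[j-1] = bj * x[i] - aj * yi + (j < nw - 1 ? w[j] : 0.0);
    }
    y[i] = yi;
  }
  return y;
}
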
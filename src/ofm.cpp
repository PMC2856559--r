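// Compiled kernels for the hierarchical optical-flow tracker: separable
// convolution with reflect padding, trilinear sampling, the global
// (translation + rotation) Gauss-Newton normal equations, and the per-voxel
// windowed Gauss-Newton local flow loop. All positions are 0-based voxel
// indices, x fastest-varying.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n - 2;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - i;
  return i;
}

// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector vol, NumericVector kernel, int axis) {
  IntegerVector d = vol.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int klen = kernel.size(), kh = klen / 2;
  NumericVector out(vol.size());
  out.attr("dim") = d;
  const double *v = vol.begin();
  double *o = out.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        for (int k = 0; k < klen; ++k) {
          const int off = k - kh;
          int xx = x, yy = y, zz = z;
          if (axis == 0) xx = reflect_idx(x + off, nx);
          else if (axis == 1) yy = reflect_idx(y + off, ny);
          else zz = reflect_idx(z + off, nz);
          acc += kernel[k] * v[xx + (size_t)nx * (yy + (size_t)ny * zz)];
        }
        o[x + (size_t)nx * (y + (size_t)ny * z)] = acc;
      }
  return out;
}

static inline double trilinear(const double *v, int nx, int ny, int nz,
                               double x, double y, double z, bool &ok) {
  if (!(x >= 0.0 && y >= 0.0 && z >= 0.0 &&
        x <= nx - 1.0 && y <= ny - 1.0 && z <= nz - 1.0)) {
    ok = false;
    return 0.0;
  }
  ok = true;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (nx == 1) x0 = 0;
  if (ny == 1) y0 = 0;
  if (nz == 1) z0 = 0;
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  const int x1 = (nx == 1) ? x0 : x0 + 1;
  const int y1 = (ny == 1) ? y0 : y0 + 1;
  const int z1 = (nz == 1) ? z0 : z0 + 1;
#define V(i, j, k) v[(i) + (size_t)nx * ((j) + (size_t)ny * (k))]
  const double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  const double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  const double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  const double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
#undef V
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Sample a volume at arbitrary (0-based) positions; outside-grid samples get
// `background` and are flagged FALSE in the "inside" attribute.
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, NumericMatrix pts,
                                   double background) {
  IntegerVector d = vol.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int n = pts.nrow();
  NumericVector out(n);
  LogicalVector inside(n);
  const double *v = vol.begin();
  for (int i = 0; i < n; ++i) {
    bool ok;
    const double val = trilinear(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2), ok);
    out[i] = ok ? val : background;
    inside[i] = ok;
  }
  out.attr("inside") = inside;
  return out;
}

// Accumulate the Gauss-Newton normal equations for the global 6-parameter
// (translation + small-angle rotation) model. Positions are expressed in
// finest-level voxel units via per-axis scale factors `fscale`, so the same
// parameter vector is valid across pyramid levels. Jacobians use the average
// of the two images' spatial gradients (symmetric form).
// [[Rcpp::export]]
List cpp_global_accum(NumericVector La, NumericVector Lb,
                      NumericVector GxA, NumericVector GyA, NumericVector GzA,
                      NumericVector GxB, NumericVector GyB, NumericVector GzB,
                      NumericVector tpar, NumericVector Rmat,
                      NumericVector center, NumericVector fscale,
                      bool mode2d) {
  IntegerVector d = La.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const double *la = La.begin(), *lb = Lb.begin();
  const double *gxa = GxA.begin(), *gya = GyA.begin(), *gza = GzA.begin();
  const double *gxb = GxB.begin(), *gyb = GyB.begin(), *gzb = GzB.begin();
  const double fx = fscale[0], fy = fscale[1], fz = fscale[2];
  NumericMatrix A(6, 6);
  NumericVector g(6);
  double ssd = 0.0;
  long nused = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        // position in fine units, relative to center
        const double px = x * fx - center[0];
        const double py = y * fy - center[1];
        const double pz = z * fz - center[2];
        // u = t + (R - I) p  (fine voxel units)
        const double ux = tpar[0] + (Rmat[0] - 1.0) * px + Rmat[3] * py + Rmat[6] * pz;
        const double uy = tpar[1] + Rmat[1] * px + (Rmat[4] - 1.0) * py + Rmat[7] * pz;
        const double uz = tpar[2] + Rmat[2] * px + Rmat[5] * py + (Rmat[8] - 1.0) * pz;
        // sample position in level units
        const double sx = x - ux / fx, sy = y - uy / fy, sz = z - uz / fz;
        bool ok;
        const double a = trilinear(la, nx, ny, nz, sx, sy, sz, ok);
        if (!ok) continue;
        const size_t idx = x + (size_t)nx * (y + (size_t)ny * z);
        const double e = lb[idx] - a;
        bool okg;
        // gradients w.r.t. fine-unit displacement: level gradient / fscale
        double jx = 0.5 * (trilinear(gxa, nx, ny, nz, sx, sy, sz, okg) + gxb[idx]) / fx;
        double jy = 0.5 * (trilinear(gya, nx, ny, nz, sx, sy, sz, okg) + gyb[idx]) / fy;
        double jz = mode2d ? 0.0
          : 0.5 * (trilinear(gza, nx, ny, nz, sx, sy, sz, okg) + gzb[idx]) / fz;
        // rows of J: translation = (jx, jy, jz); rotation_k = grad . (e_k x p)
        double j[6];
        j[0] = jx; j[1] = jy; j[2] = jz;
        j[3] = jy * (-pz) + jz * py;   // e_x x p = (0, -pz, py)
        j[4] = jx * pz + jz * (-px);   // e_y x p = (pz, 0, -px)
        j[5] = jx * (-py) + jy * px;   // e_z x p = (-py, px, 0)
        if (mode2d) { j[2] = j[3] = j[4] = 0.0; }
        for (int r = 0; r < 6; ++r) {
          g[r] += j[r] * e;
          for (int c = r; c < 6; ++c) A(r, c) += j[r] * j[c];
        }
        ssd += e * e;
        ++nused;
      }
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < r; ++c) A(r, c) = A(c, r);
  return List::create(_["A"] = A, _["g"] = g, _["ssd"] = ssd, _["n"] = (double)nused);
}

// SSD only, for step acceptance tests in the global stage.
// [[Rcpp::export]]
List cpp_global_ssd(NumericVector La, NumericVector Lb,
                    NumericVector tpar, NumericVector Rmat,
                    NumericVector center, NumericVector fscale) {
  IntegerVector d = La.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const double *la = La.begin(), *lb = Lb.begin();
  const double fx = fscale[0], fy = fscale[1], fz = fscale[2];
  double ssd = 0.0;
  long nused = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const double px = x * fx - center[0];
        const double py = y * fy - center[1];
        const double pz = z * fz - center[2];
        const double ux = tpar[0] + (Rmat[0] - 1.0) * px + Rmat[3] * py + Rmat[6] * pz;
        const double uy = tpar[1] + Rmat[1] * px + (Rmat[4] - 1.0) * py + Rmat[7] * pz;
        const double uz = tpar[2] + Rmat[2] * px + Rmat[5] * py + (Rmat[8] - 1.0) * pz;
        bool ok;
        const double a = trilinear(la, nx, ny, nz, x - ux / fx, y - uy / fy, z - uz / fz, ok);
        if (!ok) continue;
        const double e = lb[x + (size_t)nx * (y + (size_t)ny * z)] - a;
        ssd += e * e;
        ++nused;
      }
  return List::create(_["ssd"] = ssd, _["n"] = (double)nused);
}

// eigenvalues of a symmetric 3x3 (descending); analytic trigonometric form
static void eig3_sym(const double A[3][3], double ev[3]) {
  const double p1 = A[0][1] * A[0][1] + A[0][2] * A[0][2] + A[1][2] * A[1][2];
  if (p1 == 0.0) {
    ev[0] = A[0][0]; ev[1] = A[1][1]; ev[2] = A[2][2];
  } else {
    const double q = (A[0][0] + A[1][1] + A[2][2]) / 3.0;
    const double p2 = (A[0][0] - q) * (A[0][0] - q) + (A[1][1] - q) * (A[1][1] - q) +
                      (A[2][2] - q) * (A[2][2] - q) + 2.0 * p1;
    const double p = std::sqrt(p2 / 6.0);
    double B[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        B[i][j] = (A[i][j] - (i == j ? q : 0.0)) / p;
    const double detB = B[0][0] * (B[1][1] * B[2][2] - B[1][2] * B[2][1]) -
                        B[0][1] * (B[1][0] * B[2][2] - B[1][2] * B[2][0]) +
                        B[0][2] * (B[1][0] * B[2][1] - B[1][1] * B[2][0]);
    double r = detB / 2.0;
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    const double phi = std::acos(r) / 3.0;
    ev[0] = q + 2.0 * p * std::cos(phi);
    ev[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    ev[1] = 3.0 * q - ev[0] - ev[2];
  }
  // sort descending
  for (int i = 0; i < 2; ++i)
    for (int j = i + 1; j < 3; ++j)
      if (ev[j] > ev[i]) std::swap(ev[i], ev[j]);
}

static bool solve3(const double A[3][3], const double b[3], double x[3]) {
  const double det =
      A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
      A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
      A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  if (det == 0.0 || !std::isfinite(det)) return false;
  const double inv = 1.0 / det;
  x[0] = inv * (b[0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
                A[0][1] * (b[1] * A[2][2] - A[1][2] * b[2]) +
                A[0][2] * (b[1] * A[2][1] - A[1][1] * b[2]));
  x[1] = inv * (A[0][0] * (b[1] * A[2][2] - A[1][2] * b[2]) -
                b[0] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
                A[0][2] * (A[1][0] * b[2] - b[1] * A[2][0]));
  x[2] = inv * (A[0][0] * (A[1][1] * b[2] - b[1] * A[2][1]) -
                A[0][1] * (A[1][0] * b[2] - b[1] * A[2][0]) +
                b[0] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]));
  return std::isfinite(x[0]) && std::isfinite(x[1]) && std::isfinite(x[2]);
}

struct WinCtx {
  const double *la, *lb;
  int nx, ny, nz;
  int wx, wy, wz; // half-extents
  int minpts;
};

// mean squared difference over the inspection window for candidate motion u
static double window_ssd(const WinCtx &c, int x, int y, int z,
                         double ux, double uy, double uz) {
  double ssd = 0.0;
  int n = 0;
  for (int dz = -c.wz; dz <= c.wz; ++dz) {
    const int zz = z + dz;
    if (zz < 0 || zz >= c.nz) continue;
    for (int dy = -c.wy; dy <= c.wy; ++dy) {
      const int yy = y + dy;
      if (yy < 0 || yy >= c.ny) continue;
      for (int dx = -c.wx; dx <= c.wx; ++dx) {
        const int xx = x + dx;
        if (xx < 0 || xx >= c.nx) continue;
        bool ok;
        const double a = trilinear(c.la, c.nx, c.ny, c.nz,
                                   xx - ux, yy - uy, zz - uz, ok);
        if (!ok) continue;
        const double e = c.lb[xx + (size_t)c.nx * (yy + (size_t)c.ny * zz)] - a;
        ssd += e * e;
        ++n;
      }
    }
  }
  if (n < c.minpts) return R_PosInf;
  return ssd / n;
}

// Per-voxel windowed Gauss-Newton flow. `uinit` is an n x 3 matrix of initial
// motions (from the global stage). Returns the refined flow and a validity
// mask; voxels whose normal matrix is ill-conditioned keep their initial
// motion and are flagged invalid.
// [[Rcpp::export]]
List cpp_local_flow(NumericVector La, NumericVector Lb,
                    NumericVector GxA, NumericVector GyA, NumericVector GzA,
                    NumericVector GxB, NumericVector GyB, NumericVector GzB,
                    NumericMatrix uinit, int whalf, int wzhalf, int iters,
                    bool mode2d, double load_eps, double cond_max,
                    int max_halvings) {
  IntegerVector d = La.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  WinCtx c;
  c.la = La.begin(); c.lb = Lb.begin();
  c.nx = nx; c.ny = ny; c.nz = nz;
  c.wx = whalf; c.wy = whalf; c.wz = mode2d ? 0 : wzhalf;
  if (nz == 1) c.wz = 0;
  c.minpts = mode2d ? 3 : 4;
  const double *gxa = GxA.begin(), *gya = GyA.begin(), *gza = GzA.begin();
  const double *gxb = GxB.begin(), *gyb = GyB.begin(), *gzb = GzB.begin();
  const size_t n = (size_t)nx * ny * nz;
  NumericMatrix uout((int)n, 3);
  LogicalVector valid((int)n);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const size_t idx = x + (size_t)nx * (y + (size_t)ny * z);
        double u[3] = { uinit((int)idx, 0), uinit((int)idx, 1),
                        mode2d ? 0.0 : uinit((int)idx, 2) };
        bool ok_voxel = true;
        double best = window_ssd(c, x, y, z, u[0], u[1], u[2]);
        if (!std::isfinite(best)) {
          valid[idx] = false;
          uout((int)idx, 0) = u[0]; uout((int)idx, 1) = u[1]; uout((int)idx, 2) = u[2];
          continue;
        }
        for (int it = 0; it < iters; ++it) {
          double A[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
          double g[3] = {0, 0, 0};
          int npts = 0;
          for (int dz = -c.wz; dz <= c.wz; ++dz) {
            const int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            for (int dy = -c.wy; dy <= c.wy; ++dy) {
              const int yy = y + dy;
              if (yy < 0 || yy >= ny) continue;
              for (int dx = -c.wx; dx <= c.wx; ++dx) {
                const int xx = x + dx;
                if (xx < 0 || xx >= nx) continue;
                const double sx = xx - u[0], sy = yy - u[1], sz = zz - u[2];
                bool ok;
                const double a = trilinear(c.la, nx, ny, nz, sx, sy, sz, ok);
                if (!ok) continue;
                const size_t widx = xx + (size_t)nx * (yy + (size_t)ny * zz);
                const double e = c.lb[widx] - a;
                bool okg;
                double j[3];
                j[0] = 0.5 * (trilinear(gxa, nx, ny, nz, sx, sy, sz, okg) + gxb[widx]);
                j[1] = 0.5 * (trilinear(gya, nx, ny, nz, sx, sy, sz, okg) + gyb[widx]);
                j[2] = mode2d ? 0.0
                  : 0.5 * (trilinear(gza, nx, ny, nz, sx, sy, sz, okg) + gzb[widx]);
                for (int r = 0; r < 3; ++r) {
                  g[r] += j[r] * e;
                  for (int cc = r; cc < 3; ++cc) A[r][cc] += j[r] * j[cc];
                }
                ++npts;
              }
            }
          }
          if (npts < c.minpts) { ok_voxel = false; break; }
          A[1][0] = A[0][1]; A[2][0] = A[0][2]; A[2][1] = A[1][2];
          if (mode2d) A[2][2] = 1.0; // inert z row; u_z stays 0
          const double tr = A[0][0] + A[1][1] + A[2][2];
          if (!(tr > 0.0)) { ok_voxel = false; break; }
          // conditioning check on the unloaded system
          double ev[3];
          eig3_sym(A, ev);
          const double evmin = mode2d ? std::min(ev[1], ev[2]) : ev[2];
          const double evmax = ev[0];
          if (!(evmin > 0.0) || evmax / evmin > cond_max) { ok_voxel = false; break; }
          const double eps = load_eps * tr;
          A[0][0] += eps; A[1][1] += eps; A[2][2] += eps;
          double du[3];
          if (!solve3(A, g, du)) { ok_voxel = false; break; }
          du[0] = -du[0]; du[1] = -du[1]; du[2] = mode2d ? 0.0 : -du[2];
          // descent-safeguarded update: halve up to max_halvings times
          bool accepted = false;
          double scale = 1.0;
          for (int h = 0; h <= max_halvings; ++h) {
            const double cand[3] = { u[0] + scale * du[0], u[1] + scale * du[1],
                                     u[2] + scale * du[2] };
            const double s = window_ssd(c, x, y, z, cand[0], cand[1], cand[2]);
            if (s < best) {
              u[0] = cand[0]; u[1] = cand[1]; u[2] = cand[2];
              best = s;
              accepted = true;
              break;
            }
            scale *= 0.5;
          }
          if (!accepted) break; // SSD converged
        }
        uout((int)idx, 0) = u[0];
        uout((int)idx, 1) = u[1];
        uout((int)idx, 2) = u[2];
        valid[idx] = ok_voxel;
      }
  return List::create(_["u"] = uout, _["valid"] = valid);
}
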
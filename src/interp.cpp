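#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Catmull-Rom weight evaluation for a fractional offset t in [0,1)
static inline void catmull_rom(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2.0 * t2 - t);
  w[1] = 0.5 * (3.0 * t3 - 5.0 * t2 + 2.0);
  w[2] = 0.5 * (-3.0 * t3 + 4.0 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Sample a 3D array (column-major, dims nx,ny,nz) at 0-based fractional
// voxel coordinates. cubic = Catmull-Rom, otherwise trilinear. Queries
// outside [0, n-1] on any axis return `fill` and inside = FALSE.
// [[Rcpp::export]]
List cpp_interp3(NumericVector vol, NumericVector qx, NumericVector qy,
                 NumericVector qz, double fill, bool cubic) {
  IntegerVector d = vol.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t n = qx.size();
  NumericVector out(n);
  LogicalVector inside(n);
  const double *v = REAL(vol);
  const double *px = REAL(qx), *py = REAL(qy), *pz = REAL(qz);

  const double btol = 1e-6;  // boundary slack against float round-off
  for (R_xlen_t q = 0; q < n; ++q) {
    double x = px[q], y = py[q], z = pz[q];
    if (!(x >= -btol && x <= nx - 1.0 + btol && y >= -btol &&
          y <= ny - 1.0 + btol && z >= -btol && z <= nz - 1.0 + btol)) {
      out[q] = fill;
      inside[q] = false;
      continue;
    }
    if (x < 0.0) x = 0.0; else if (x > nx - 1.0) x = nx - 1.0;
    if (y < 0.0) y = 0.0; else if (y > ny - 1.0) y = ny - 1.0;
    if (z < 0.0) z = 0.0; else if (z > nz - 1.0) z = nz - 1.0;
    inside[q] = true;
    int ix = 0, iy = 0, iz = 0;
    double tx = 0.0, ty = 0.0, tz = 0.0;
    if (nx > 1) { ix = (int)std::floor(x); if (ix == nx - 1) ix--; tx = x - ix; }
    if (ny > 1) { iy = (int)std::floor(y); if (iy == ny - 1) iy--; ty = y - iy; }
    if (nz > 1) { iz = (int)std::floor(z); if (iz == nz - 1) iz--; tz = z - iz; }

    if (!cubic) {
      double acc = 0.0;
      for (int kz = 0; kz <= (nz > 1); ++kz) {
        double wz = kz ? tz : 1.0 - tz;
        for (int ky = 0; ky <= (ny > 1); ++ky) {
          double wy = ky ? ty : 1.0 - ty;
          for (int kx = 0; kx <= (nx > 1); ++kx) {
            double wx = kx ? tx : 1.0 - tx;
            acc += wx * wy * wz *
              v[(ix + kx) + (R_xlen_t)nx * ((iy + ky) + (R_xlen_t)ny * (iz + kz))];
          }
        }
      }
      out[q] = acc;
    } else {
      double wx[4], wy[4], wz[4];
      catmull_rom(tx, wx);
      catmull_rom(ty, wy);
      catmull_rom(tz, wz);
      double acc = 0.0;
      for (int kz = 0; kz < 4; ++kz) {
        int zz = clampi(iz - 1 + kz, 0, nz - 1);
        for (int ky = 0; ky < 4; ++ky) {
          int yy = clampi(iy - 1 + ky, 0, ny - 1);
          double wyz = wy[ky] * wz[kz];
          R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
          for (int kx = 0; kx < 4; ++kx) {
            int xx = clampi(ix - 1 + kx, 0, nx - 1);
            acc += wx[kx] * wyz * v[xx + base];
          }
        }
      }
      out[q] = acc;
    }
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}

// Trilinear upsampling of a field defined on a regular coarse node grid
// (origin o*, spacing s* in voxel units, node counts = dims of `nodes`)
// onto the full voxel grid nx*ny*nz. Coordinates outside the node grid are
// extrapolated linearly from the edge cell (smooth fields keep their trend
// beyond the outermost subset centers).
// [[Rcpp::export]]
NumericVector cpp_upsample_field(NumericVector nodes, double ox, double oy,
                                 double oz, double sx, double sy, double sz,
                                 int nx, int ny, int nz) {
  IntegerVector d = nodes.attr("dim");
  const int mx = d[0], my = d[1], mz = d[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double *v = REAL(nodes);
  double *o = REAL(out);

  for (int k = 0; k < nz; ++k) {
    double gz = (k - oz) / sz;
    int iz = clampi((int)std::floor(gz), 0, mz - 2);
    if (mz == 1) iz = 0;
    double tz = mz > 1 ? gz - iz : 0.0;
    for (int j = 0; j < ny; ++j) {
      double gy = (j - oy) / sy;
      int iy = clampi((int)std::floor(gy), 0, my - 2);
      if (my == 1) iy = 0;
      double ty = my > 1 ? gy - iy : 0.0;
      for (int i = 0; i < nx; ++i) {
        double gx = (i - ox) / sx;
        int ix = clampi((int)std::floor(gx), 0, mx - 2);
        if (mx == 1) ix = 0;
        double tx = mx > 1 ? gx - ix : 0.0;

        double acc = 0.0;
        for (int kz = 0; kz <= (mz > 1); ++kz) {
          double wz = kz ? tz : 1.0 - tz;
          for (int ky = 0; ky <= (my > 1); ++ky) {
            double wy = ky ? ty : 1.0 - ty;
            for (int kx = 0; kx <= (mx > 1); ++kx) {
              double wx = kx ? tx : 1.0 - tx;
              acc += wx * wy * wz *
                v[(ix + kx) + (R_xlen_t)mx * ((iy + ky) + (R_xlen_t)my * (iz + kz))];
            }
          }
        }
        o[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = acc;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Warp a volume by a voxel-resolution displacement field (voxel units):
// out(i,j,k) = vol(i + ux, j + uy, k + uz), Catmull-Rom sampled. Voxels
// whose source coordinate falls outside the grid are filled and flagged
// in the returned `outside` mask (content that left the field of view).
// [[Rcpp::export]]
List cpp_warp_by_field(NumericVector vol, NumericVector ux,
                       NumericVector uy, NumericVector uz,
                       double fill) {
  IntegerVector d = vol.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  LogicalVector outside((R_xlen_t)nx * ny * nz);
  const double *v = REAL(vol);
  const double *dx = REAL(ux), *dy = REAL(uy), *dz = REAL(uz);
  double *o = REAL(out);

  const double btol = 1e-6;  // boundary slack against float round-off
  R_xlen_t q = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++q) {
        double x = i + dx[q], y = j + dy[q], z = k + dz[q];
        if (!(x >= -btol && x <= nx - 1.0 + btol && y >= -btol &&
              y <= ny - 1.0 + btol && z >= -btol && z <= nz - 1.0 + btol)) {
          o[q] = fill;
          outside[q] = true;
          continue;
        }
        if (x < 0.0) x = 0.0; else if (x > nx - 1.0) x = nx - 1.0;
        if (y < 0.0) y = 0.0; else if (y > ny - 1.0) y = ny - 1.0;
        if (z < 0.0) z = 0.0; else if (z > nz - 1.0) z = nz - 1.0;
        int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
        if (ix == nx - 1) ix--;
        if (iy == ny - 1) iy--;
        if (iz == nz - 1) iz--;
        double wx[4], wy[4], wz[4];
        catmull_rom(x - ix, wx);
        catmull_rom(y - iy, wy);
        catmull_rom(z - iz, wz);
        double acc = 0.0;
        for (int kz = 0; kz < 4; ++kz) {
          int zz = clampi(iz - 1 + kz, 0, nz - 1);
          for (int ky = 0; ky < 4; ++ky) {
            int yy = clampi(iy - 1 + ky, 0, ny - 1);
            double wyz = wy[ky] * wz[kz];
            R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            for (int kx = 0; kx < 4; ++kx)
              acc += wx[kx] * wyz * v[clampi(ix - 1 + kx, 0, nx - 1) + base];
          }
        }
        o[q] = acc;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  outside.attr("dim") = IntegerVector::create(nx, ny, nz);
  return List::create(_["values"] = out, _["outside"] = outside);
}
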
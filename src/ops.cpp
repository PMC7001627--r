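// Low-level array kernels for volume reconstruction.
//
// All volumes are numeric vectors with dim = c(nx, ny, nz), x fastest
// (R column-major). Voxel indices are 0-based in C++; physical positions
// use voxel-center convention: x_um = origin + (i + 0.5) * voxel.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
}

// Centered 1-D correlation along one axis, zero boundary.
// ker has odd length; axis: 0=x, 1=y, 2=z. For symmetric kernels this is
// identical to convolution; callers mirror the kernel otherwise.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector vol, IntegerVector dim,
                            NumericVector ker, int axis) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int K = ker.size(), r = (K - 1) / 2;
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* in = vol.begin();
  double* o = out.begin();
  const double* k = ker.begin();
  if (axis == 0) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const double* line = in + idx3(0, y, z, nx, ny);
        double* lo = o + idx3(0, y, z, nx, ny);
        for (int x = 0; x < nx; ++x) {
          double acc = 0.0;
          int j0 = std::max(0, r - x), j1 = std::min(K, nx - x + r);
          for (int j = j0; j < j1; ++j) acc += k[j] * line[x + j - r];
          lo[x] = acc;
        }
      }
  } else if (axis == 1) {
    for (int z = 0; z < nz; ++z)
      for (int j = 0; j < K; ++j) {
        double w = k[j];
        int dyo = j - r;
        int y0 = std::max(0, -dyo), y1 = std::min(ny, ny - dyo);
        for (int y = y0; y < y1; ++y) {
          const double* line = in + idx3(0, y + dyo, z, nx, ny);
          double* lo = o + idx3(0, y, z, nx, ny);
          for (int x = 0; x < nx; ++x) lo[x] += w * line[x];
        }
      }
  } else {
    for (int j = 0; j < K; ++j) {
      double w = k[j];
      int dzo = j - r;
      int z0 = std::max(0, -dzo), z1 = std::min(nz, nz - dzo);
      for (int z = z0; z < z1; ++z)
        for (int y = 0; y < ny; ++y) {
          const double* line = in + idx3(0, y, z + dzo, nx, ny);
          double* lo = o + idx3(0, y, z, nx, ny);
          for (int x = 0; x < nx; ++x) lo[x] += w * line[x];
        }
    }
  }
  return out;
}

static inline double trilin(const double* in, int nx, int ny, int nz,
                            double sx, double sy, double sz) {
  // sample at 0-based voxel coordinates (sx, sy, sz); zero outside.
  if (sx <= -1.0 || sy <= -1.0 || sz <= -1.0 ||
      sx >= (double)nx || sy >= (double)ny || sz >= (double)nz)
    return 0.0;
  int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
  double fx = sx - x0, fy = sy - y0, fz = sz - z0;
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz) {
    int z = z0 + dz;
    if (z < 0 || z >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dy = 0; dy < 2; ++dy) {
      int y = y0 + dy;
      if (y < 0 || y >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      double w = wz * wy;
      for (int dx = 0; dx < 2; ++dx) {
        int x = x0 + dx;
        if (x < 0 || x >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        acc += w * wx * in[idx3(x, y, z, nx, ny)];
      }
    }
  }
  return acc;
}

// Trilinear subvoxel shift: out(p) = in(p - shift); zero boundary.
// Decomposed into (up to) 8 weighted integer translations, so each pass is
// a contiguous strided add; zero-weight corners are skipped. The adjoint
// of this operator is the same operator with -shift.
// [[Rcpp::export]]
NumericVector cpp_shift3(NumericVector vol, IntegerVector dim,
                         NumericVector shift) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* in = vol.begin();
  double* o = out.begin();
  int ix = (int)std::floor(shift[0]), iy = (int)std::floor(shift[1]),
      iz = (int)std::floor(shift[2]);
  double fx = shift[0] - ix, fy = shift[1] - iy, fz = shift[2] - iz;
  for (int cz = 0; cz < 2; ++cz) {
    double wz = cz ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int cy = 0; cy < 2; ++cy) {
      double wy = cy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int cx = 0; cx < 2; ++cx) {
        double wx = cx ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        double w = wz * wy * wx;
        // out(p) += w * in(p - (i + c)) over the overlap box
        int tx = ix + cx, ty = iy + cy, tz = iz + cz;
        int x0 = std::max(0, tx), x1 = std::min(nx, nx + tx);
        int y0 = std::max(0, ty), y1 = std::min(ny, ny + ty);
        int z0 = std::max(0, tz), z1 = std::min(nz, nz + tz);
        for (int z = z0; z < z1; ++z)
          for (int y = y0; y < y1; ++y) {
            double* op = o + idx3(x0, y, z, nx, ny);
            const double* ip = in + idx3(x0 - tx, y - ty, z - tz, nx, ny);
            for (int x = x0; x < x1; ++x) *op++ += w * *ip++;
          }
      }
    }
  }
  return out;
}

// Affine pull-back resampling in 0-based voxel coordinates:
// out(p) = in(A p + t). Returns the resampled data and a validity mask
// (1 where the source point lies inside the source box).
// [[Rcpp::export]]
List cpp_affine3(NumericVector vol, IntegerVector dim,
                 NumericVector A, NumericVector t, IntegerVector odim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  IntegerVector mask((R_xlen_t)ox * oy * oz);
  const double* in = vol.begin();
  double* o = out.begin();
  int* m = mask.begin();
  // A row-major 3x3
  double a11 = A[0], a12 = A[1], a13 = A[2];
  double a21 = A[3], a22 = A[4], a23 = A[5];
  double a31 = A[6], a32 = A[7], a33 = A[8];
  double t1 = t[0], t2 = t[1], t3 = t[2];
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x) {
        double sx = a11 * x + a12 * y + a13 * z + t1;
        double sy = a21 * x + a22 * y + a23 * z + t2;
        double sz = a31 * x + a32 * y + a33 * z + t3;
        R_xlen_t p = idx3(x, y, z, ox, oy);
        o[p] = trilin(in, nx, ny, nz, sx, sy, sz);
        m[p] = (sx >= 0 && sx <= nx - 1 && sy >= 0 && sy <= ny - 1 &&
                sz >= 0 && sz <= nz - 1) ? 1 : 0;
      }
  return List::create(_["data"] = out, _["inside"] = mask);
}

// Block-average downsampling by integer factors.
// [[Rcpp::export]]
NumericVector cpp_block_down(NumericVector vol, IntegerVector dim,
                             IntegerVector f) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int fx = f[0], fy = f[1], fz = f[2];
  int ox = nx / fx, oy = ny / fy, oz = nz / fz;
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* in = vol.begin();
  double* o = out.begin();
  double inv = 1.0 / ((double)fx * fy * fz);
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x) {
        double acc = 0.0;
        for (int c = 0; c < fz; ++c)
          for (int b = 0; b < fy; ++b)
            for (int a = 0; a < fx; ++a)
              acc += in[idx3(x * fx + a, y * fy + b, z * fz + c, nx, ny)];
        o[idx3(x, y, z, ox, oy)] = acc * inv;
      }
  return out;
}

// Replicating upsampling (adjoint of block averaging, up to the 1/B factor
// which the caller applies).
// [[Rcpp::export]]
NumericVector cpp_block_up(NumericVector vol, IntegerVector dim,
                           IntegerVector f) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int fx = f[0], fy = f[1], fz = f[2];
  int ox = nx * fx, oy = ny * fy, oz = nz * fz;
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* in = vol.begin();
  double* o = out.begin();
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x)
        o[idx3(x, y, z, ox, oy)] =
          in[idx3(x / fx, y / fy, z / fz, nx, ny)];
  return out;
}

static inline double ncdf(double x) { return 0.5 * std::erfc(-x * M_SQRT1_2); }

// Deposit anisotropic Gaussian blobs (flux integrated over voxel cells, so
// interior flux is exact). centers: n x 3 (um), sigmas: n x 3 (um), flux: n.
// [[Rcpp::export]]
NumericVector cpp_render_points_vol(IntegerVector dim, NumericVector voxel,
                                    NumericVector origin, NumericMatrix centers,
                                    NumericMatrix sigmas, NumericVector flux,
                                    double radius_sigmas) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* o = out.begin();
  int n = centers.nrow();
  std::vector<double> wx(nx), wy(ny), wz(nz);
  for (int p = 0; p < n; ++p) {
    double cx = centers(p, 0), cy = centers(p, 1), cz = centers(p, 2);
    double sx = sigmas(p, 0), sy = sigmas(p, 1), sz = sigmas(p, 2);
    double F = flux[p];
    int dims[3] = {nx, ny, nz};
    double ctr[3] = {cx, cy, cz};
    double sig[3] = {sx, sy, sz};
    int lo[3], hi[3];
    std::vector<double>* ws[3] = {&wx, &wy, &wz};
    bool skip = false;
    for (int a = 0; a < 3; ++a) {
      double v = voxel[a], og = origin[a];
      double s = std::max(sig[a], 1e-9);
      double half = radius_sigmas * s + v;
      lo[a] = std::max(0, (int)std::floor((ctr[a] - half - og) / v));
      hi[a] = std::min(dims[a] - 1, (int)std::ceil((ctr[a] + half - og) / v));
      if (lo[a] > hi[a]) { skip = true; break; }
      for (int i = lo[a]; i <= hi[a]; ++i) {
        double e0 = og + i * v, e1 = e0 + v;
        (*ws[a])[i] = ncdf((e1 - ctr[a]) / s) - ncdf((e0 - ctr[a]) / s);
      }
    }
    if (skip) continue;
    for (int z = lo[2]; z <= hi[2]; ++z)
      for (int y = lo[1]; y <= hi[1]; ++y) {
        double wyz = F * wy[y] * wz[z];
        if (wyz == 0.0) continue;
        double* line = o + idx3(0, y, z, nx, ny);
        for (int x = lo[0]; x <= hi[0]; ++x) line[x] += wyz * wx[x];
      }
  }
  return out;
}

// Render a tilted-scan frame sequence of point sources. Frame i images the
// fixed detection plane z = z_plane while the sample is displaced by i*d,
// so a source at c appears laterally at c_xy + i*d_xy with axial weight
// N(c_z + i*d_z - z_plane; sig_ax) * d_z (flux per stack ~ flux).
// Lateral profiles are pixel-integrated Gaussians. Frames: nx x ny x nt.
// [[Rcpp::export]]
NumericVector cpp_render_frames(IntegerVector fdim, double pixel_um,
                                NumericVector origin_xy, NumericMatrix centers,
                                NumericVector sig_lat, NumericVector sig_ax,
                                NumericVector flux, NumericVector d_um,
                                double z_plane, double radius_sigmas) {
  int nx = fdim[0], ny = fdim[1], nt = fdim[2];
  NumericVector out((R_xlen_t)nx * ny * nt);
  double* o = out.begin();
  int n = centers.nrow();
  double dx = d_um[0], dy = d_um[1], dz = d_um[2];
  std::vector<double> wx(nx), wy(ny);
  for (int p = 0; p < n; ++p) {
    double cx = centers(p, 0), cy = centers(p, 1), cz = centers(p, 2);
    double sl = std::max(sig_lat[p], 1e-9), sa = std::max(sig_ax[p], 1e-9);
    double F = flux[p];
    // frame range where the source crosses the sheet
    double icross = (z_plane - cz) / dz;
    double ihalf = radius_sigmas * sa / dz + 1.0;
    int i0 = std::max(0, (int)std::floor(icross - ihalf));
    int i1 = std::min(nt - 1, (int)std::ceil(icross + ihalf));
    for (int i = i0; i <= i1; ++i) {
      double az = cz + i * dz - z_plane;
      double wax = std::exp(-0.5 * az * az / (sa * sa)) /
                   (sa * std::sqrt(2.0 * M_PI)) * dz;
      if (wax < 1e-300) continue;
      double mx = cx + i * dx, my = cy + i * dy;
      double half = radius_sigmas * sl + pixel_um;
      int x0 = std::max(0, (int)std::floor((mx - half - origin_xy[0]) / pixel_um));
      int x1 = std::min(nx - 1, (int)std::ceil((mx + half - origin_xy[0]) / pixel_um));
      int y0 = std::max(0, (int)std::floor((my - half - origin_xy[1]) / pixel_um));
      int y1 = std::min(ny - 1, (int)std::ceil((my + half - origin_xy[1]) / pixel_um));
      if (x0 > x1 || y0 > y1) continue;
      for (int x = x0; x <= x1; ++x) {
        double e0 = origin_xy[0] + x * pixel_um;
        wx[x] = ncdf((e0 + pixel_um - mx) / sl) - ncdf((e0 - mx) / sl);
      }
      for (int y = y0; y <= y1; ++y) {
        double e0 = origin_xy[1] + y * pixel_um;
        wy[y] = ncdf((e0 + pixel_um - my) / sl) - ncdf((e0 - my) / sl);
      }
      for (int y = y0; y <= y1; ++y) {
        double wyy = F * wax * wy[y];
        double* line = o + idx3(0, y, i, nx, ny);
        for (int x = x0; x <= x1; ++x) line[x] += wyy * wx[x];
      }
    }
  }
  return out;
}

// Strict 26-neighbourhood local maxima above a threshold (interior voxels).
// Returns a 3 x m matrix of 1-based (x, y, z) indices.
// [[Rcpp::export]]
IntegerMatrix cpp_local_maxima(NumericVector vol, IntegerVector dim,
                               double threshold) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* in = vol.begin();
  std::vector<int> hits;
  for (int z = 1; z < nz - 1; ++z)
    for (int y = 1; y < ny - 1; ++y)
      for (int x = 1; x < nx - 1; ++x) {
        double v = in[idx3(x, y, z, nx, ny)];
        if (v <= threshold) continue;
        bool ismax = true;
        for (int c = -1; c <= 1 && ismax; ++c)
          for (int b = -1; b <= 1 && ismax; ++b)
            for (int a = -1; a <= 1; ++a) {
              if (!a && !b && !c) continue;
              if (in[idx3(x + a, y + b, z + c, nx, ny)] >= v) {
                ismax = false;
                break;
              }
            }
        if (ismax) {
          hits.push_back(x + 1);
          hits.push_back(y + 1);
          hits.push_back(z + 1);
        }
      }
  int m = hits.size() / 3;
  IntegerMatrix out(3, m);
  for (int j = 0; j < m; ++j) {
    out(0, j) = hits[3 * j];
    out(1, j) = hits[3 * j + 1];
    out(2, j) = hits[3 * j + 2];
  }
  return out;
}
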
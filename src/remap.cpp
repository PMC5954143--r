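#include <Rcpp.h>
using namespace Rcpp;

// Cubic convolution kernel (Keys, a = -0.5), the usual "bicubic" weights.
static inline void cubic_weights(double t, double w[4]) {
  const double a = -0.5;
  double t2 = t * t, t3 = t2 * t;
  w[0] = a * (t3 - 2.0 * t2 + t);
  w[1] = (a + 2.0) * t3 - (a + 3.0) * t2 + 1.0;
  w[2] = -(a + 2.0) * t3 + (2.0 * a + 3.0) * t2 - a * t;
  w[3] = -a * (t3 - t2);
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Resample img at continuous 0-based coordinates (map_y, map_x).
// Coordinates outside [0, n-1] yield the fill value (default 0).
// [[Rcpp::export]]
NumericMatrix remap_bicubic_cpp(NumericMatrix img, NumericMatrix map_y,
                                NumericMatrix map_x, double fill = 0.0) {
  int ny = img.nrow(), nx = img.ncol();
  int oy = map_y.nrow(), ox = map_y.ncol();
  NumericMatrix out(oy, ox);
  for (int j = 0; j < ox; ++j) {
    for (int i = 0; i < oy; ++i) {
      double sy = map_y(i, j), sx = map_x(i, j);
      if (!(sy >= 0.0 && sy <= ny - 1.0 && sx >= 0.0 && sx <= nx - 1.0)) {
        out(i, j) = fill;
        continue;
      }
      int iy = (int)std::floor(sy), ix = (int)std::floor(sx);
      double fy = sy - iy, fx = sx - ix;
      double wy[4], wx[4];
      cubic_weights(fy, wy);
      cubic_weights(fx, wx);
      double acc = 0.0;
      for (int m = 0; m < 4; ++m) {
        int yy = clampi(iy - 1 + m, 0, ny - 1);
        double row = 0.0;
        for (int n = 0; n < 4; ++n) {
          int xx = clampi(ix - 1 + n, 0, nx - 1);
          row += wx[n] * img(yy, xx);
        }
        acc += wy[m] * row;
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Resample a (nz, ny, nx) volume along z: out[z, y, x] = vol[src_z[z], y, x]
// with cubic interpolation along z; src_z in 0-based plane coordinates.
// [[Rcpp::export]]
NumericVector resample_z_cubic_cpp(NumericVector vol, IntegerVector dim,
                                   NumericVector src_z, double fill = 0.0) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(vol.size());
  int plane = nz; // stride between consecutive y at fixed (z): arrays are
                  // column-major with z fastest, i.e. index = z + nz*(y + ny*x)
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)plane * (y + (R_xlen_t)ny * x);
      for (int z = 0; z < nz; ++z) {
        double sz = src_z[z];
        if (!(sz >= 0.0 && sz <= nz - 1.0)) {
          out[base + z] = fill;
          continue;
        }
        int iz = (int)std::floor(sz);
        double fz = sz - iz;
        double wz[4];
        cubic_weights(fz, wz);
        double acc = 0.0;
        for (int m = 0; m < 4; ++m) {
          int zz = clampi(iz - 1 + m, 0, nz - 1);
          acc += wz[m] * vol[base + zz];
        }
        out[base + z] = acc;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
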
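#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear / nearest-neighbour sampling of a 3-D column-major volume at
// continuous 0-based voxel coordinates. Points outside [0, dim-1] on any
// axis yield `pad` (may be NA_REAL so callers can drop out-of-field samples).

static inline double sample_one(const double *v, int nx, int ny, int nz,
                                double x, double y, double z,
                                int interp, double pad) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0)
    return pad;
  if (interp == 0) { // nearest neighbour
    int ix = (int)std::lround(x), iy = (int)std::lround(y), iz = (int)std::lround(z);
    if (ix >= nx) ix = nx - 1;
    if (iy >= ny) iy = ny - 1;
    if (iz >= nz) iz = nz - 1;
    return v[ix + (size_t)nx * (iy + (size_t)ny * iz)];
  }
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2;
  if (y0 > ny - 2) y0 = ny - 2;
  if (z0 > nz - 2) z0 = nz - 2;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  size_t sxy = (size_t)nx * ny;
  const double *p = v + x0 + (size_t)nx * y0 + sxy * z0;
  double c00 = p[0] * (1 - fx) + p[1] * fx;
  double c10 = p[nx] * (1 - fx) + p[nx + 1] * fx;
  double c01 = p[sxy] * (1 - fx) + p[sxy + 1] * fx;
  double c11 = p[sxy + nx] * (1 - fx) + p[sxy + nx + 1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector sample_volume_cpp(NumericVector data, IntegerVector dims,
                                NumericMatrix pts, int interp, double pad) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double *v = REAL(data);
  for (int i = 0; i < n; ++i)
    out[i] = sample_one(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2),
                        interp, pad);
  return out;
}

// Resample a full volume: M is the 4x4 map from output voxel indices
// (0-based) to continuous input voxel indices.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector data, IntegerVector dims_in,
                                  NumericMatrix M, IntegerVector dims_out,
                                  int interp, double pad) {
  int nx = dims_in[0], ny = dims_in[1], nz = dims_in[2];
  int ox = dims_out[0], oy = dims_out[1], oz = dims_out[2];
  NumericVector out((size_t)ox * oy * oz);
  const double *v = REAL(data);
  double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2), m03 = M(0, 3);
  double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2), m13 = M(1, 3);
  double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2), m23 = M(2, 3);
  size_t idx = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j) {
      double bx = m01 * j + m02 * k + m03;
      double by = m11 * j + m12 * k + m13;
      double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < ox; ++i, ++idx)
        out[idx] = sample_one(v, nx, ny, nz, m00 * i + bx, m10 * i + by,
                              m20 * i + bz, interp, pad);
    }
  return out;
}

// NMI between a fixed image (pre-binned intensities at ROI voxels) and a
// moving volume sampled at the mapped ROI positions. The joint histogram is
// accumulated only over points falling inside the moving field of view, so
// marginal entropies refer to the overlap region. Returns c(nmi, n_in).
// [[Rcpp::export]]
NumericVector nmi_points_cpp(NumericVector data, IntegerVector dims,
                             NumericMatrix pts, IntegerVector fix_bin,
                             int bins, double mov_min, double mov_max) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = pts.nrow();
  const double *v = REAL(data);
  std::vector<double> joint((size_t)bins * bins, 0.0);
  double rng = mov_max - mov_min;
  if (rng <= 0) return NumericVector::create(NA_REAL, 0.0);
  double scale = bins / rng;
  long n_in = 0;
  for (int i = 0; i < n; ++i) {
    double val = sample_one(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2),
                            1, NA_REAL);
    if (!ISNAN(val)) {
      int bm = (int)((val - mov_min) * scale);
      if (bm < 0) bm = 0;
      if (bm >= bins) bm = bins - 1;
      int bf = fix_bin[i] - 1; // 1-based from R
      joint[(size_t)bf + (size_t)bins * bm] += 1.0;
      ++n_in;
    }
  }
  if (n_in == 0) return NumericVector::create(NA_REAL, 0.0);
  std::vector<double> pa(bins, 0.0), pb(bins, 0.0);
  double hab = 0.0, inv_n = 1.0 / n_in;
  for (int b = 0; b < bins; ++b)
    for (int a = 0; a < bins; ++a) {
      double c = joint[(size_t)a + (size_t)bins * b];
      if (c > 0) {
        double p = c * inv_n;
        hab -= p * std::log(p);
        pa[a] += p;
        pb[b] += p;
      }
    }
  double ha = 0.0, hb = 0.0;
  for (int a = 0; a < bins; ++a)
    if (pa[a] > 0) ha -= pa[a] * std::log(pa[a]);
  for (int b = 0; b < bins; ++b)
    if (pb[b] > 0) hb -= pb[b] * std::log(pb[b]);
  if (hab <= 0) return NumericVector::create(NA_REAL, (double)n_in);
  return NumericVector::create((ha + hb) / hab, (double)n_in);
}
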
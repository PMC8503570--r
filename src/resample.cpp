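#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Affine resampling of a 3D volume with B-spline interpolation (orders 0, 1,
// 3, 5).  Orders >= 2 require transforming the samples into B-spline
// coefficients first; this uses the standard recursive (IIR) prefilter with
// mirror boundary conditions (Unser-style).  All work is done in 0-based
// voxel-index coordinates; the R wrapper builds the index->index map from the
// world-space affine.

static const double POLE3[1] = { -0.26794919243112270647 };           // sqrt(3) - 2
static const double POLE5[2] = { -0.43057534709997114, -0.04309628820326465 };

static double initial_causal(const double *c, int n, int stride, double z,
                             double tol) {
  int horizon = (int)std::ceil(std::log(tol) / std::log(std::fabs(z)));
  if (horizon < n) {
    double zk = z, sum = c[0];
    for (int k = 1; k < horizon; k++) {
      sum += zk * c[k * stride];
      zk *= z;
    }
    return sum;
  }
  // full mirror-periodic initialization
  double zk = z, iz = 1.0 / z;
  double z2n = std::pow(z, (double)(n - 1));
  double sum = c[0] + z2n * c[(n - 1) * stride];
  z2n *= z2n * iz;
  for (int k = 1; k <= n - 2; k++) {
    sum += (zk + z2n) * c[k * stride];
    zk *= z;
    z2n *= iz;
  }
  return sum / (1.0 - std::pow(z, (double)(2 * n - 2)));
}

static double initial_anticausal(const double *c, int n, int stride, double z) {
  return (z / (z * z - 1.0)) * (z * c[(n - 2) * stride] + c[(n - 1) * stride]);
}

static void filter_line(double *c, int n, int stride, const double *poles,
                        int npoles) {
  const double tol = 1e-12;
  if (n == 1) return;
  double lambda = 1.0;
  for (int i = 0; i < npoles; i++)
    lambda *= (1.0 - poles[i]) * (1.0 - 1.0 / poles[i]);
  for (int k = 0; k < n; k++) c[k * stride] *= lambda;
  for (int i = 0; i < npoles; i++) {
    double z = poles[i];
    c[0] = initial_causal(c, n, stride, z, tol);
    for (int k = 1; k < n; k++)
      c[k * stride] += z * c[(k - 1) * stride];
    c[(n - 1) * stride] = initial_anticausal(c, n, stride, z);
    for (int k = n - 2; k >= 0; k--)
      c[k * stride] = z * (c[(k + 1) * stride] - c[k * stride]);
  }
}

static void prefilter(double *c, int nx, int ny, int nz, int order) {
  if (order < 2) return;
  const double *poles = (order == 3) ? POLE3 : POLE5;
  int npoles = (order == 3) ? 1 : 2;
  // along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      filter_line(c + (size_t)nx * (j + (size_t)ny * k), nx, 1, poles, npoles);
  // along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++)
      filter_line(c + i + (size_t)nx * ny * k, ny, nx, poles, npoles);
  // along z
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++)
      filter_line(c + i + (size_t)nx * j, nz, nx * ny, poles, npoles);
}

// centered B-spline basis of odd order n (3 or 5), truncated-power form
static inline double bspline_basis(int n, double t) {
  double half = 0.5 * (n + 1);
  if (t <= -half || t >= half) return 0.0;
  double sum = 0.0, sign = 1.0, binom = 1.0; // C(n+1, k)
  for (int k = 0; k <= n + 1; k++) {
    double u = t + half - k;
    if (u > 0.0) {
      double p = u;
      for (int m = 1; m < n; m++) p *= u;
      sum += sign * binom * p;
    }
    sign = -sign;
    binom = binom * (n + 1 - k) / (k + 1);
  }
  double fact = 1.0;
  for (int m = 2; m <= n; m++) fact *= m;
  return sum / fact;
}

static inline int mirror_index(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n - 2;
  i = std::abs(i) % period;
  return (i >= n) ? period - i : i;
}

// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector vol, IntegerVector dims,
                                  NumericMatrix map, int order,
                                  double background) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nvox = (size_t)nx * ny * nz;
  if ((size_t)vol.size() != nvox) stop("volume length does not match dims");
  if (!(order == 0 || order == 1 || order == 3 || order == 5))
    stop("interpolation order must be 0, 1, 3 or 5");
  if (map.nrow() != 3 || map.ncol() != 4) stop("map must be 3 x 4");

  std::vector<double> coef(vol.begin(), vol.end());
  prefilter(coef.data(), nx, ny, nz, order);

  NumericVector out(no_init((R_xlen_t)nvox));
  const double m00 = map(0,0), m01 = map(0,1), m02 = map(0,2), m03 = map(0,3);
  const double m10 = map(1,0), m11 = map(1,1), m12 = map(1,2), m13 = map(1,3);
  const double m20 = map(2,0), m21 = map(2,1), m22 = map(2,2), m23 = map(2,3);
  const int ns = order + 1; // support size per axis
  double wx[6], wy[6], wz[6];
  int ix[6], iy[6], iz[6];

  size_t idx = 0;
  for (int k = 0; k < nz; k++) {
    for (int j = 0; j < ny; j++) {
      for (int i = 0; i < nx; i++, idx++) {
        double u = m00 * i + m01 * j + m02 * k + m03;
        double v = m10 * i + m11 * j + m12 * k + m13;
        double w = m20 * i + m21 * j + m22 * k + m23;
        // outside the source field of view (allowing the half-voxel rim)
        if (u < -0.5 || u > nx - 0.5 || v < -0.5 || v > ny - 0.5 ||
            w < -0.5 || w > nz - 0.5) {
          out[idx] = background;
          continue;
        }
        if (order == 0) {
          int iu = mirror_index((int)std::lround(u), nx);
          int iv = mirror_index((int)std::lround(v), ny);
          int iw = mirror_index((int)std::lround(w), nz);
          out[idx] = coef[iu + (size_t)nx * (iv + (size_t)ny * iw)];
          continue;
        }
        if (order == 1) {
          int u0 = (int)std::floor(u), v0 = (int)std::floor(v),
              w0 = (int)std::floor(w);
          double fu = u - u0, fv = v - v0, fw = w - w0;
          ix[0] = mirror_index(u0, nx); ix[1] = mirror_index(u0 + 1, nx);
          iy[0] = mirror_index(v0, ny); iy[1] = mirror_index(v0 + 1, ny);
          iz[0] = mirror_index(w0, nz); iz[1] = mirror_index(w0 + 1, nz);
          wx[0] = 1 - fu; wx[1] = fu;
          wy[0] = 1 - fv; wy[1] = fv;
          wz[0] = 1 - fw; wz[1] = fw;
        } else {
          int u0 = (int)std::floor(u) - order / 2;
          int v0 = (int)std::floor(v) - order / 2;
          int w0 = (int)std::floor(w) - order / 2;
          for (int s = 0; s < ns; s++) {
            ix[s] = mirror_index(u0 + s, nx);
            iy[s] = mirror_index(v0 + s, ny);
            iz[s] = mirror_index(w0 + s, nz);
            wx[s] = bspline_basis(order, u - (u0 + s));
            wy[s] = bspline_basis(order, v - (v0 + s));
            wz[s] = bspline_basis(order, w - (w0 + s));
          }
        }
        int nsl = (order == 1) ? 2 : ns;
        double acc = 0.0;
        for (int c = 0; c < nsl; c++) {
          double accy = 0.0;
          size_t zoff = (size_t)nx * ny * iz[c];
          for (int b = 0; b < nsl; b++) {
            double accx = 0.0;
            size_t yoff = zoff + (size_t)nx * iy[b];
            for (int a = 0; a < nsl; a++)
              accx += wx[a] * coef[yoff + ix[a]];
            accy += wy[b] * accx;
          }
          acc += wz[c] * accy;
        }
        out[idx] = acc;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
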
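#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Activations are stored as C x N matrices whose columns enumerate voxels of a
// (D,H,W) grid in R's column-major order: n = d + D*h + D*H*w (0-based).
// Patch rows are ordered c*k^3 + kd + k*kh + k^2*kw; convolution weights use
// the same inner ordering, so conv forward is a single GEMM: Y = W %*% cols.

static inline int out_extent(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col3(const NumericMatrix& x, const IntegerVector& sdim,
                      int k, int s, int p) {
  const int C = x.nrow();
  const int D = sdim[0], H = sdim[1], W = sdim[2];
  if (x.ncol() != D * H * W) stop("im2col3: spatial dims do not match matrix");
  const int Do = out_extent(D, k, s, p);
  const int Ho = out_extent(H, k, s, p);
  const int Wo = out_extent(W, k, s, p);
  if (Do < 1 || Ho < 1 || Wo < 1) stop("im2col3: kernel larger than padded input");
  const int k3 = k * k * k;
  NumericMatrix cols(C * k3, Do * Ho * Wo);
  const double* xp = x.begin();
  double* cp = cols.begin();
  const int crow = C * k3;
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      for (int od = 0; od < Do; ++od) {
        const int j = od + Do * (oh + Ho * ow);
        double* colj = cp + (size_t)j * crow;
        for (int kw = 0; kw < k; ++kw) {
          const int iw = ow * s - p + kw;
          for (int kh = 0; kh < k; ++kh) {
            const int ih = oh * s - p + kh;
            for (int kd = 0; kd < k; ++kd) {
              const int id = od * s - p + kd;
              const int r = kd + k * (kh + k * kw);
              if (id < 0 || id >= D || ih < 0 || ih >= H || iw < 0 || iw >= W) {
                for (int c = 0; c < C; ++c) colj[c * k3 + r] = 0.0;
              } else {
                const int n = id + D * (ih + H * iw);
                const double* xn = xp + (size_t)n * C;
                for (int c = 0; c < C; ++c) colj[c * k3 + r] = xn[c];
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add adjoint of im2col3: rebuilds a C x (D*H*W) activation gradient.
// [[Rcpp::export]]
NumericMatrix col2im3(const NumericMatrix& cols, int C, const IntegerVector& sdim,
                      int k, int s, int p) {
  const int D = sdim[0], H = sdim[1], W = sdim[2];
  const int Do = out_extent(D, k, s, p);
  const int Ho = out_extent(H, k, s, p);
  const int Wo = out_extent(W, k, s, p);
  const int k3 = k * k * k;
  if (cols.nrow() != C * k3 || cols.ncol() != Do * Ho * Wo)
    stop("col2im3: column matrix shape mismatch");
  NumericMatrix x(C, D * H * W);
  const double* cp = cols.begin();
  double* xp = x.begin();
  const int crow = C * k3;
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      for (int od = 0; od < Do; ++od) {
        const int j = od + Do * (oh + Ho * ow);
        const double* colj = cp + (size_t)j * crow;
        for (int kw = 0; kw < k; ++kw) {
          const int iw = ow * s - p + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int ih = oh * s - p + kh;
            if (ih < 0 || ih >= H) continue;
            for (int kd = 0; kd < k; ++kd) {
              const int id = od * s - p + kd;
              if (id < 0 || id >= D) continue;
              const int r = kd + k * (kh + k * kw);
              const int n = id + D * (ih + H * iw);
              double* xn = xp + (size_t)n * C;
              for (int c = 0; c < C; ++c) xn[c] += colj[c * k3 + r];
            }
          }
        }
      }
    }
  }
  return x;
}

// Directed nearest-surface distances for the 95% Hausdorff metric.
// a, b: n x 3 matrices of 0-based voxel indices; spacing: mm per axis.
// Returns d_a[i] = min_j ||a_i - b_j||_mm and d_b symmetrically.
// [[Rcpp::export]]
List surface_min_dists(const NumericMatrix& a, const NumericMatrix& b,
                       const NumericVector& spacing) {
  const int na = a.nrow(), nb = b.nrow();
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  NumericVector da(na, R_PosInf), db(nb, R_PosInf);
  for (int i = 0; i < na; ++i) {
    const double ax = a(i, 0) * sx, ay = a(i, 1) * sy, az = a(i, 2) * sz;
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - b(j, 0) * sx;
      const double dy = ay - b(j, 1) * sy;
      const double dz = az - b(j, 2) * sz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
      if (d2 < db[j]) db[j] = d2;
    }
    da[i] = best;
  }
  for (int i = 0; i < na; ++i) da[i] = std::sqrt(da[i]);
  for (int j = 0; j < nb; ++j) db[j] = std::sqrt(db[j]);
  return List::create(_["da"] = da, _["db"] = db);
}
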
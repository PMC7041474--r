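#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Discrete differential operators on regular voxel grids (unit spacing).
// Scalar fields: (nx, ny, nz) column-major. Vector fields: (nx, ny, nz, 3),
// components ordered (x, y, z). Symmetric tensor fields: (nx, ny, nz, 6),
// components ordered (xx, yy, zz, xy, xz, yz); off-diagonals are stored once
// and double-counted in inner products / Frobenius norms.
//
// Gradient and symmetrized derivative use forward differences with a zero
// difference at the trailing plane of each axis; the divergences are their
// exact negative adjoints (backward differences, matching closure).

static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// [[Rcpp::export(name = ".cpp_grad")]]
NumericVector cpp_grad(NumericVector p, int nx, int ny, int nz) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(3 * n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = idx3(i, j, k, nx, ny);
        double pc = p[id];
        out[id]         = (i < nx - 1) ? p[id + 1] - pc : 0.0;
        out[n + id]     = (j < ny - 1) ? p[id + nx] - pc : 0.0;
        out[2 * n + id] = (k < nz - 1) ? p[id + (R_xlen_t)nx * ny] - pc : 0.0;
      }
  return out;
}

// [[Rcpp::export(name = ".cpp_div_vec")]]
NumericVector cpp_div_vec(NumericVector v, int nx, int ny, int nz) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = idx3(i, j, k, nx, ny);
        double acc = 0.0;
        if (i < nx - 1) acc += v[id];
        if (i > 0)      acc -= v[id - 1];
        if (j < ny - 1) acc += v[n + id];
        if (j > 0)      acc -= v[n + id - nx];
        if (k < nz - 1) acc += v[2 * n + id];
        if (k > 0)      acc -= v[2 * n + id - (R_xlen_t)nx * ny];
        out[id] = acc;
      }
  return out;
}

// forward difference of component field w (offset into array) along axis
static inline double fdiff(const NumericVector &a, R_xlen_t off, R_xlen_t id,
                           int i, int lim, R_xlen_t stride) {
  return (i < lim - 1) ? a[off + id + stride] - a[off + id] : 0.0;
}

// [[Rcpp::export(name = ".cpp_symgrad")]]
NumericVector cpp_symgrad(NumericVector v, int nx, int ny, int nz) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  NumericVector out(6 * n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = idx3(i, j, k, nx, ny);
        double dxvx = fdiff(v, 0, id, i, nx, sx);
        double dyvy = fdiff(v, n, id, j, ny, sy);
        double dzvz = fdiff(v, 2 * n, id, k, nz, sz);
        double dxvy = fdiff(v, n, id, i, nx, sx);
        double dyvx = fdiff(v, 0, id, j, ny, sy);
        double dxvz = fdiff(v, 2 * n, id, i, nx, sx);
        double dzvx = fdiff(v, 0, id, k, nz, sz);
        double dyvz = fdiff(v, 2 * n, id, j, ny, sy);
        double dzvy = fdiff(v, n, id, k, nz, sz);
        out[id]         = dxvx;
        out[n + id]     = dyvy;
        out[2 * n + id] = dzvz;
        out[3 * n + id] = 0.5 * (dxvy + dyvx);
        out[4 * n + id] = 0.5 * (dxvz + dzvx);
        out[5 * n + id] = 0.5 * (dyvz + dzvy);
      }
  return out;
}

// backward difference (adjoint closure) of component field along axis
static inline double bdiff(const NumericVector &a, R_xlen_t off, R_xlen_t id,
                           int i, int lim, R_xlen_t stride) {
  double acc = 0.0;
  if (i < lim - 1) acc += a[off + id];
  if (i > 0)       acc -= a[off + id - stride];
  return acc;
}

// [[Rcpp::export(name = ".cpp_div_tens")]]
NumericVector cpp_div_tens(NumericVector w, int nx, int ny, int nz) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  NumericVector out(3 * n);
  // component order in w: xx, yy, zz, xy, xz, yz
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = idx3(i, j, k, nx, ny);
        out[id] = bdiff(w, 0, id, i, nx, sx) +          // dx wxx
                  bdiff(w, 3 * n, id, j, ny, sy) +      // dy wxy
                  bdiff(w, 4 * n, id, k, nz, sz);       // dz wxz
        out[n + id] = bdiff(w, 3 * n, id, i, nx, sx) +  // dx wxy
                      bdiff(w, n, id, j, ny, sy) +      // dy wyy
                      bdiff(w, 5 * n, id, k, nz, sz);   // dz wyz
        out[2 * n + id] = bdiff(w, 4 * n, id, i, nx, sx) +  // dx wxz
                          bdiff(w, 5 * n, id, j, ny, sy) +  // dy wyz
                          bdiff(w, 2 * n, id, k, nz, sz);   // dz wzz
      }
  return out;
}

// [[Rcpp::export(name = ".cpp_proj_vec")]]
NumericVector cpp_proj_vec(NumericVector v, double alpha, R_xlen_t n) {
  NumericVector out(3 * n);
  for (R_xlen_t id = 0; id < n; ++id) {
    double a = v[id], b = v[n + id], c = v[2 * n + id];
    double nrm = std::sqrt(a * a + b * b + c * c);
    double s = (nrm > alpha) ? alpha / nrm : 1.0;
    out[id] = a * s; out[n + id] = b * s; out[2 * n + id] = c * s;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_proj_tens")]]
NumericVector cpp_proj_tens(NumericVector w, double alpha, R_xlen_t n) {
  NumericVector out(6 * n);
  for (R_xlen_t id = 0; id < n; ++id) {
    double d0 = w[id], d1 = w[n + id], d2 = w[2 * n + id];
    double o0 = w[3 * n + id], o1 = w[4 * n + id], o2 = w[5 * n + id];
    double nrm = std::sqrt(d0 * d0 + d1 * d1 + d2 * d2 +
                           2.0 * (o0 * o0 + o1 * o1 + o2 * o2));
    double s = (nrm > alpha) ? alpha / nrm : 1.0;
    out[id] = d0 * s; out[n + id] = d1 * s; out[2 * n + id] = d2 * s;
    out[3 * n + id] = o0 * s; out[4 * n + id] = o1 * s; out[5 * n + id] = o2 * s;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_l1_vec")]]
double cpp_l1_vec(NumericVector v, R_xlen_t n) {
  double acc = 0.0;
  for (R_xlen_t id = 0; id < n; ++id) {
    double a = v[id], b = v[n + id], c = v[2 * n + id];
    acc += std::sqrt(a * a + b * b + c * c);
  }
  return acc;
}

// [[Rcpp::export(name = ".cpp_l1_tens")]]
double cpp_l1_tens(NumericVector w, R_xlen_t n) {
  double acc = 0.0;
  for (R_xlen_t id = 0; id < n; ++id) {
    double d0 = w[id], d1 = w[n + id], d2 = w[2 * n + id];
    double o0 = w[3 * n + id], o1 = w[4 * n + id], o2 = w[5 * n + id];
    acc += std::sqrt(d0 * d0 + d1 * d1 + d2 * d2 +
                     2.0 * (o0 * o0 + o1 * o1 + o2 * o2));
  }
  return acc;
}
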
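#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Column-major 3D indexing, 0-based voxel coordinates throughout.
static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

static inline double trilinear(const double* v, int nx, int ny, int nz,
                               double x, double y, double z, double bg) {
  if (x < -1.0 || y < -1.0 || z < -1.0 || x > nx || y > ny || z > nz)
    return bg;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double out = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zz = z0 + dz;
    double wz = dz ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dy = 0; dy <= 1; ++dy) {
      int yy = y0 + dy;
      double wy = dy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int dx = 0; dx <= 1; ++dx) {
        int xx = x0 + dx;
        double wx = dx ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        double val = bg;
        if (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz)
          val = v[idx3(xx, yy, zz, nx, ny)];
        out += wx * wy * wz * val;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dim,
                                   NumericVector xs, NumericVector ys,
                                   NumericVector zs, double bg) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = xs.size();
  NumericVector out(n);
  const double* v = REAL(vol);
  for (R_xlen_t t = 0; t < n; ++t)
    out[t] = trilinear(v, nx, ny, nz, xs[t], ys[t], zs[t], bg);
  return out;
}

// Warp vol by displacement field: out(x) = vol(x + u(x)).
// [[Rcpp::export]]
NumericVector cpp_warp_field(NumericVector vol, IntegerVector dim,
                             NumericVector ux, NumericVector uy,
                             NumericVector uz, double bg) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  const double* v = REAL(vol);
  const double* px = REAL(ux);
  const double* py = REAL(uy);
  const double* pz = REAL(uz);
  double* o = REAL(out);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t t = idx3(i, j, k, nx, ny);
        o[t] = trilinear(v, nx, ny, nz, i + px[t], j + py[t], k + pz[t], bg);
      }
  return out;
}

// Nearest-neighbour variant for label volumes.
// [[Rcpp::export]]
NumericVector cpp_warp_field_nn(NumericVector vol, IntegerVector dim,
                                NumericVector ux, NumericVector uy,
                                NumericVector uz, double bg) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  const double* v = REAL(vol);
  const double* px = REAL(ux);
  const double* py = REAL(uy);
  const double* pz = REAL(uz);
  double* o = REAL(out);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t t = idx3(i, j, k, nx, ny);
        int xi = (int)std::lround(i + px[t]);
        int yi = (int)std::lround(j + py[t]);
        int zi = (int)std::lround(k + pz[t]);
        if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz)
          o[t] = bg;
        else
          o[t] = v[idx3(xi, yi, zi, nx, ny)];
      }
  return out;
}

// Separable Gaussian smoothing, kernel truncated at 3 sigma and
// renormalized at the faces (no implicit zero padding).
static void smooth_axis(std::vector<double>& buf, std::vector<double>& tmp,
                        int nx, int ny, int nz, int axis, double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) return;
  std::vector<double> w(2 * r + 1);
  double wsum = 0.0;
  for (int d = -r; d <= r; ++d) {
    w[d + r] = std::exp(-0.5 * (double)d * d / (sigma * sigma));
    wsum += w[d + r];
  }
  for (int d = -r; d <= r; ++d) w[d + r] /= wsum;   // interior needs no division
  int nax = axis == 0 ? nx : (axis == 1 ? ny : nz);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? (R_xlen_t)nx
                                               : (R_xlen_t)nx * ny);
  int nb = axis == 0 ? ny : nx;
  int nc = axis == 2 ? ny : nz;
  R_xlen_t strideB = axis == 0 ? (R_xlen_t)nx : 1;
  R_xlen_t strideC = axis == 2 ? (R_xlen_t)nx : (R_xlen_t)nx * ny;
  std::vector<double> line(nax);
  for (int c = 0; c < nc; ++c)
    for (int b = 0; b < nb; ++b) {
      R_xlen_t base = b * strideB + c * strideC;
      for (int p = 0; p < nax; ++p) line[p] = buf[base + p * stride];
      int hiEdge = std::max(r, nax - r);
      for (int p = 0; p < nax; ++p) {
        double acc = 0.0;
        if (p >= r && p < nax - r) {
          for (int d = -r; d <= r; ++d) acc += w[d + r] * line[p + d];
        } else {
          double ws = 0.0;
          int lo = std::max(-r, -p), hi = std::min(r, nax - 1 - p);
          for (int d = lo; d <= hi; ++d) {
            acc += w[d + r] * line[p + d];
            ws += w[d + r];
          }
          acc /= ws;
        }
        tmp[base + p * stride] = acc;
      }
      (void)hiEdge;
    }
  std::swap(buf, tmp);
}

// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector vol, IntegerVector dim, double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = vol.size();
  std::vector<double> buf(REAL(vol), REAL(vol) + n), tmp(n);
  if (sigma > 0.0)
    for (int ax = 0; ax < 3; ++ax)
      smooth_axis(buf, tmp, nx, ny, nz, ax, sigma);
  NumericVector out(n);
  std::copy(buf.begin(), buf.end(), REAL(out));
  return out;
}

// Central-difference gradient, one-sided at faces. Returns 3 volumes.
// [[Rcpp::export]]
List cpp_gradient(NumericVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = vol.size();
  NumericVector gx(n), gy(n), gz(n);
  const double* v = REAL(vol);
  double* px = REAL(gx); double* py = REAL(gy); double* pz = REAL(gz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t t = idx3(i, j, k, nx, ny);
        int ip = std::min(i + 1, nx - 1), im = std::max(i - 1, 0);
        int jp = std::min(j + 1, ny - 1), jm = std::max(j - 1, 0);
        int kp = std::min(k + 1, nz - 1), km = std::max(k - 1, 0);
        px[t] = (v[idx3(ip, j, k, nx, ny)] - v[idx3(im, j, k, nx, ny)]) / (ip - im);
        py[t] = (v[idx3(i, jp, k, nx, ny)] - v[idx3(i, jm, k, nx, ny)]) / (jp - jm);
        pz[t] = (v[idx3(i, j, kp, nx, ny)] - v[idx3(i, j, km, nx, ny)]) / (kp - km);
      }
  return List::create(_["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
}

// det(I + grad u) with central differences (one-sided at faces).
// [[Rcpp::export]]
NumericVector cpp_jacobian_det(NumericVector ux, NumericVector uy,
                               NumericVector uz, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = ux.size();
  NumericVector out(n);
  const double* u[3] = { REAL(ux), REAL(uy), REAL(uz) };
  double* o = REAL(out);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int ip = std::min(i + 1, nx - 1), im = std::max(i - 1, 0);
        int jp = std::min(j + 1, ny - 1), jm = std::max(j - 1, 0);
        int kp = std::min(k + 1, nz - 1), km = std::max(k - 1, 0);
        double J[3][3];
        for (int c = 0; c < 3; ++c) {
          J[c][0] = (u[c][idx3(ip, j, k, nx, ny)] - u[c][idx3(im, j, k, nx, ny)]) / (ip - im);
          J[c][1] = (u[c][idx3(i, jp, k, nx, ny)] - u[c][idx3(i, jm, k, nx, ny)]) / (jp - jm);
          J[c][2] = (u[c][idx3(i, j, kp, nx, ny)] - u[c][idx3(i, j, km, nx, ny)]) / (kp - km);
          J[c][c] += 1.0;
        }
        o[idx3(i, j, k, nx, ny)] =
            J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1])
          - J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0])
          + J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      }
  return out;
}

// One demons update: given fixed image, moving image warped by the current
// field, compute the capped Thirion update (intensity difference times
// warped-image gradient over |grad|^2 + diff^2).
// [[Rcpp::export]]
List cpp_demons_update(NumericVector fixed, NumericVector warped,
                       IntegerVector dim, double stepCap) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = fixed.size();
  NumericVector dx(n), dy(n), dz(n);
  List g = cpp_gradient(warped, dim);
  NumericVector gx = g["gx"], gy = g["gy"], gz = g["gz"];
  const double* f = REAL(fixed);
  const double* w = REAL(warped);
  const double* pgx = REAL(gx); const double* pgy = REAL(gy); const double* pgz = REAL(gz);
  double* px = REAL(dx); double* py = REAL(dy); double* pz = REAL(dz);
  double ssd = 0.0;
  for (R_xlen_t t = 0; t < n; ++t) {
    double diff = f[t] - w[t];
    ssd += diff * diff;
    double g2 = pgx[t] * pgx[t] + pgy[t] * pgy[t] + pgz[t] * pgz[t];
    double denom = g2 + diff * diff;
    if (denom < 1e-12) continue;
    double s = diff / denom;
    double vx = s * pgx[t], vy = s * pgy[t], vz = s * pgz[t];
    double nrm = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (nrm > stepCap) {
      double sc = stepCap / nrm;
      vx *= sc; vy *= sc; vz *= sc;
    }
    px[t] = vx; py[t] = vy; pz[t] = vz;
  }
  return List::create(_["dx"] = dx, _["dy"] = dy, _["dz"] = dz, _["ssd"] = ssd);
}

// Zero the outermost voxel shell of a field component, in place on a copy.
// [[Rcpp::export]]
NumericVector cpp_zero_shell(NumericVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(vol);
  double* o = REAL(out);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 || k == nz - 1)
          o[idx3(i, j, k, nx, ny)] = 0.0;
  return out;
}
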
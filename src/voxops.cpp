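#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Index helper: volumes are column-major arrays dim = (nx, ny, nz).
static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// ---- 1D squared distance transform (Felzenszwalb & Huttenlocher) ----------
// f: sampled function; w: sample spacing. Result overwritten into d.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, double w) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  // lower envelope over the finite parabolas only (Inf entries contribute
  // nothing and would poison the intersection arithmetic)
  std::vector<int> fin;
  fin.reserve(n);
  for (int q = 0; q < n; ++q) if (f[q] < INF) fin.push_back(q);
  if (fin.empty()) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  std::vector<int> v(fin.size());
  std::vector<double> z(fin.size() + 1);
  int kk = 0;
  v[0] = fin[0];
  z[0] = -INF;
  z[1] = INF;
  const double w2 = w * w;
  for (size_t t = 1; t < fin.size(); ++t) {
    const int q = fin[t];
    double s;
    while (true) {
      s = ((f[q] + w2 * (double)q * q) - (f[v[kk]] + w2 * (double)v[kk] * v[kk])) /
          (2.0 * w2 * (q - v[kk]));
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = INF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    const double dq = w * (q - v[kk]);
    d[q] = dq * dq + f[v[kk]];
  }
}

// Euclidean distance (mm) from every voxel to the nearest true voxel.
// Voxels where mask is true get 0. If the mask is empty, returns Inf.
// [[Rcpp::export]]
NumericVector cpp_edt3(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double INF = std::numeric_limits<double>::infinity();
  for (R_xlen_t t = 0; t < n; ++t) out[t] = mask[t] ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = out[idx3(i, j, k, nx, ny)];
      dt1d(f, d, spacing[0]);
      for (int i = 0; i < nx; ++i) out[idx3(i, j, k, nx, ny)] = d[i];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = out[idx3(i, j, k, nx, ny)];
      dt1d(f, d, spacing[1]);
      for (int j = 0; j < ny; ++j) out[idx3(i, j, k, nx, ny)] = d[j];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = out[idx3(i, j, k, nx, ny)];
      dt1d(f, d, spacing[2]);
      for (int k = 0; k < nz; ++k) out[idx3(i, j, k, nx, ny)] = d[k];
    }
  for (R_xlen_t t = 0; t < n; ++t) out[t] = std::sqrt(out[t]);
  return out;
}

// ---- separable Gaussian smoothing ----------------------------------------
// sigma_vox: per-axis sigma in voxel units; kernel truncated at 3 sigma and
// renormalized at the borders (replicate-free normalization).
static void smooth_axis(std::vector<double>& vol, int nx, int ny, int nz,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  for (int t = -r; t <= r; ++t) kern[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
  const int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  std::vector<double> line(len), res(len);
  const int n1 = axis == 0 ? ny : nx;
  const int n2 = axis == 2 ? ny : nz;
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      for (int t = 0; t < len; ++t) {
        R_xlen_t id = axis == 0 ? idx3(t, a, b, nx, ny)
                    : axis == 1 ? idx3(a, t, b, nx, ny)
                                : idx3(a, b, t, nx, ny);
        line[t] = vol[id];
      }
      for (int t = 0; t < len; ++t) {
        double acc = 0.0, wsum = 0.0;
        const int lo = std::max(0, t - r), hi = std::min(len - 1, t + r);
        for (int s = lo; s <= hi; ++s) {
          const double w = kern[s - t + r];
          acc += w * line[s];
          wsum += w;
        }
        res[t] = acc / wsum;
      }
      for (int t = 0; t < len; ++t) {
        R_xlen_t id = axis == 0 ? idx3(t, a, b, nx, ny)
                    : axis == 1 ? idx3(a, t, b, nx, ny)
                                : idx3(a, b, t, nx, ny);
        vol[id] = res[t];
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector vol, IntegerVector dim, NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> buf(vol.begin(), vol.end());
  smooth_axis(buf, nx, ny, nz, 0, sigma_vox[0]);
  smooth_axis(buf, nx, ny, nz, 1, sigma_vox[1]);
  smooth_axis(buf, nx, ny, nz, 2, sigma_vox[2]);
  return NumericVector(buf.begin(), buf.end());
}

// ---- interpolation --------------------------------------------------------
// Sample volume at continuous voxel coordinates (0-based). mode: 0 linear,
// 1 nearest. oob: 0 -> fill value, 1 -> clamp to border.
static double sample_at(const double* vol, int nx, int ny, int nz,
                        double x, double y, double z,
                        int mode, int oob, double fill, bool* outside) {
  if (oob == 1) {
    x = std::min(std::max(x, 0.0), (double)(nx - 1));
    y = std::min(std::max(y, 0.0), (double)(ny - 1));
    z = std::min(std::max(z, 0.0), (double)(nz - 1));
  } else if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    if (outside) *outside = true;
    return fill;
  }
  if (mode == 1) {
    const int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
    return vol[idx3(std::min(std::max(i, 0), nx - 1),
                    std::min(std::max(j, 0), ny - 1),
                    std::min(std::max(k, 0), nz - 1), nx, ny)];
  }
  const int i0 = std::min((int)std::floor(x), nx - 2 >= 0 ? nx - 2 : 0);
  const int j0 = std::min((int)std::floor(y), ny - 2 >= 0 ? ny - 2 : 0);
  const int k0 = std::min((int)std::floor(z), nz - 2 >= 0 ? nz - 2 : 0);
  const int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
            k1 = std::min(k0 + 1, nz - 1);
  const double fx = x - i0, fy = y - j0, fz = z - k0;
  const double c000 = vol[idx3(i0, j0, k0, nx, ny)], c100 = vol[idx3(i1, j0, k0, nx, ny)];
  const double c010 = vol[idx3(i0, j1, k0, nx, ny)], c110 = vol[idx3(i1, j1, k0, nx, ny)];
  const double c001 = vol[idx3(i0, j0, k1, nx, ny)], c101 = vol[idx3(i1, j0, k1, nx, ny)];
  const double c011 = vol[idx3(i0, j1, k1, nx, ny)], c111 = vol[idx3(i1, j1, k1, nx, ny)];
  const double c00 = c000 * (1 - fx) + c100 * fx;
  const double c10 = c010 * (1 - fx) + c110 * fx;
  const double c01 = c001 * (1 - fx) + c101 * fx;
  const double c11 = c011 * (1 - fx) + c111 * fx;
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Sample a volume at arbitrary continuous voxel coordinates (matrix n x 3,
// 0-based). Returns sampled values; attribute "n_outside" counts fill hits.
// [[Rcpp::export]]
NumericVector cpp_sample(NumericVector vol, IntegerVector dim, NumericMatrix pts,
                         int mode, int oob, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  R_xlen_t n_out = 0;
  const double* v = REAL(vol);
  for (R_xlen_t t = 0; t < n; ++t) {
    bool outside = false;
    out[t] = sample_at(v, nx, ny, nz, pts(t, 0), pts(t, 1), pts(t, 2),
                       mode, oob, fill, &outside);
    if (outside) ++n_out;
  }
  out.attr("n_outside") = (double)n_out;
  return out;
}

// Pull-back warp on a shared grid: out(x) = vol(x + disp(x)/spacing), where
// disp holds three displacement components in mm stacked as a 4D array.
// [[Rcpp::export]]
NumericVector cpp_pullback(NumericVector vol, IntegerVector dim, NumericVector spacing,
                           NumericVector disp, int mode, int oob, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double* v = REAL(vol);
  const double* dx = REAL(disp);
  const double* dy = dx + n;
  const double* dz = dy + n;
  R_xlen_t n_out = 0, t = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++t) {
        bool outside = false;
        out[t] = sample_at(v, nx, ny, nz,
                           i + dx[t] / spacing[0],
                           j + dy[t] / spacing[1],
                           k + dz[t] / spacing[2],
                           mode, oob, fill, &outside);
        if (outside) ++n_out;
      }
  out.attr("n_outside") = (double)n_out;
  return out;
}

// ---- demons iteration loop ------------------------------------------------
// Full demons refinement on signed distance maps: v is updated in place
// (pull-back convention, total field = u_base + v), with a per-iteration
// step cap (mm) and separable Gaussian regularization of v.
// [[Rcpp::export]]
NumericVector cpp_demons(NumericVector f, NumericVector m, NumericVector u_base,
                         NumericVector v0, IntegerVector dim,
                         NumericVector spacing, int iters,
                         double sigma_elastic, double max_step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double *fp = REAL(f), *mp = REAL(m), *ub = REAL(u_base);
  std::vector<double> v(v0.begin(), v0.end());

  // fixed-image gradient (central differences, mm units) and its norm^2
  std::vector<double> gx(n), gy(n), gz(n), g2(n);
  {
    R_xlen_t t = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++t) {
          const int i0 = i > 0 ? i - 1 : 0, i1 = i < nx - 1 ? i + 1 : nx - 1;
          const int j0 = j > 0 ? j - 1 : 0, j1 = j < ny - 1 ? j + 1 : ny - 1;
          const int k0 = k > 0 ? k - 1 : 0, k1 = k < nz - 1 ? k + 1 : nz - 1;
          gx[t] = (fp[idx3(i1, j, k, nx, ny)] - fp[idx3(i0, j, k, nx, ny)]) /
                  (2.0 * spacing[0]);
          gy[t] = (fp[idx3(i, j1, k, nx, ny)] - fp[idx3(i, j0, k, nx, ny)]) /
                  (2.0 * spacing[1]);
          gz[t] = (fp[idx3(i, j, k1, nx, ny)] - fp[idx3(i, j, k0, nx, ny)]) /
                  (2.0 * spacing[2]);
          g2[t] = gx[t] * gx[t] + gy[t] * gy[t] + gz[t] * gz[t];
        }
  }
  std::vector<double> comp((size_t)n);
  for (int it = 0; it < iters; ++it) {
    R_xlen_t t = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++t) {
          const double px = i + (ub[t] + v[t]) / spacing[0];
          const double py = j + (ub[n + t] + v[n + t]) / spacing[1];
          const double pz = k + (ub[2 * n + t] + v[2 * n + t]) / spacing[2];
          const double mw = sample_at(mp, nx, ny, nz, px, py, pz, 0, 1, 0.0,
                                      nullptr);
          const double diff = mw - fp[t];
          double denom = g2[t] + diff * diff;
          if (denom < 1e-9) denom = 1e-9;
          const double s = -diff / denom;   // descend SSD of distance maps
          double dx = s * gx[t], dy = s * gy[t], dz = s * gz[t];
          const double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (nrm > max_step) {
            const double sc = max_step / nrm;
            dx *= sc; dy *= sc; dz *= sc;
          }
          v[t] += dx; v[n + t] += dy; v[2 * n + t] += dz;
        }
    for (int cmp = 0; cmp < 3; ++cmp) {
      std::copy(v.begin() + (R_xlen_t)cmp * n, v.begin() + (R_xlen_t)(cmp + 1) * n,
                comp.begin());
      smooth_axis(comp, nx, ny, nz, 0, sigma_elastic / spacing[0]);
      smooth_axis(comp, nx, ny, nz, 1, sigma_elastic / spacing[1]);
      smooth_axis(comp, nx, ny, nz, 2, sigma_elastic / spacing[2]);
      std::copy(comp.begin(), comp.end(), v.begin() + (R_xlen_t)cmp * n);
    }
  }
  return NumericVector(v.begin(), v.end());
}
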
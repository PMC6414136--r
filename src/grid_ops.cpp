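#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double EDT_INF = 1e20;

static inline double sq(double x) { return x * x; }

// 1D squared Euclidean distance transform (lower-envelope-of-parabolas
// algorithm), samples at physical positions q*s for voxel pitch s.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double s, std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e300;
  z[1] = 1e300;
  for (int q = 1; q < n; q++) {
    double fq = f[q];
    double sP;
    while (true) {
      int p = v[k];
      sP = ((fq + sq(q * s)) - (f[p] + sq(p * s))) / (2.0 * s * (q - p));
      if (sP <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = sP;
    z[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q * s) k++;
    d[q] = sq((q - v[k]) * s) + f[v[k]];
  }
}

// Exact Euclidean distance (mm) from every voxel center to the nearest TRUE
// voxel center, honouring anisotropic spacing. TRUE voxels map to 0; if the
// mask is empty every voxel maps to Inf.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<double> D(n);
  for (size_t i = 0; i < n; i++) D[i] = mask[i] ? 0.0 : EDT_INF;

  int mmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(mmax), d(mmax), z(mmax + 1);
  std::vector<int> v(mmax);

  // x pass
  for (int k = 0; k < nz; k++) {
    for (int j = 0; j < ny; j++) {
      size_t base = (size_t)k * nx * ny + (size_t)j * nx;
      for (int i = 0; i < nx; i++) f[i] = D[base + i];
      dt1d(f, d, nx, spacing[0], v, z);
      for (int i = 0; i < nx; i++) D[base + i] = d[i];
    }
  }
  // y pass
  for (int k = 0; k < nz; k++) {
    for (int i = 0; i < nx; i++) {
      size_t base = (size_t)k * nx * ny + i;
      for (int j = 0; j < ny; j++) f[j] = D[base + (size_t)j * nx];
      dt1d(f, d, ny, spacing[1], v, z);
      for (int j = 0; j < ny; j++) D[base + (size_t)j * nx] = d[j];
    }
  }
  // z pass
  const size_t sz = (size_t)nx * ny;
  for (int j = 0; j < ny; j++) {
    for (int i = 0; i < nx; i++) {
      size_t base = (size_t)j * nx + i;
      for (int k = 0; k < nz; k++) f[k] = D[base + (size_t)k * sz];
      dt1d(f, d, nz, spacing[2], v, z);
      for (int k = 0; k < nz; k++) D[base + (size_t)k * sz] = d[k];
    }
  }

  NumericVector out(n);
  for (size_t i = 0; i < n; i++) {
    out[i] = (D[i] >= 1e19) ? R_PosInf : std::sqrt(D[i]);
  }
  return out;
}

// 6-connected component labelling; labels 1..K in decreasing order is NOT
// guaranteed -- caller tabulates sizes. Background voxels get 0.
// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<size_t> stack;
  int next = 0;
  const size_t sy = (size_t)nx, sz = (size_t)nx * ny;
  for (size_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / sz);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int q = 0; q < 6; q++) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        size_t nb = (size_t)kk * sz + (size_t)jj * sy + ii;
        if (mask[nb] && lab[nb] == 0) {
          lab[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Resample a grid-aligned scalar field onto a new lattice sharing voxel
// (0,0,0)'s center. Output voxel m sits at physical offset m*newspacing along
// each grid axis; source coordinates are clamped to the input extent.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dim,
                           NumericVector spacing, IntegerVector newdim,
                           NumericVector newspacing, bool nearest) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = newdim[0], my = newdim[1], mz = newdim[2];
  const size_t sy = (size_t)nx, szr = (size_t)nx * ny;
  NumericVector out((size_t)mx * my * mz);
  size_t o = 0;
  for (int k = 0; k < mz; k++) {
    double gz = k * newspacing[2] / spacing[2];
    if (gz < 0) gz = 0;
    if (gz > nz - 1) gz = nz - 1;
    for (int j = 0; j < my; j++) {
      double gy = j * newspacing[1] / spacing[1];
      if (gy < 0) gy = 0;
      if (gy > ny - 1) gy = ny - 1;
      for (int i = 0; i < mx; i++, o++) {
        double gx = i * newspacing[0] / spacing[0];
        if (gx < 0) gx = 0;
        if (gx > nx - 1) gx = nx - 1;
        if (nearest) {
          int ii = (int)std::lround(gx), jj = (int)std::lround(gy),
              kk = (int)std::lround(gz);
          out[o] = vol[(size_t)kk * szr + (size_t)jj * sy + ii];
        } else {
          int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
              k0 = (int)std::floor(gz);
          if (i0 > nx - 2) i0 = nx - 2;
          if (j0 > ny - 2) j0 = ny - 2;
          if (k0 > nz - 2) k0 = nz - 2;
          if (i0 < 0) i0 = 0;
          if (j0 < 0) j0 = 0;
          if (k0 < 0) k0 = 0;
          double tx = gx - i0, ty = gy - j0, tz = gz - k0;
          size_t b = (size_t)k0 * szr + (size_t)j0 * sy + i0;
          double c00 = vol[b] * (1 - tx) + vol[b + 1] * tx;
          double c10 = vol[b + sy] * (1 - tx) + vol[b + sy + 1] * tx;
          double c01 = vol[b + szr] * (1 - tx) + vol[b + szr + 1] * tx;
          double c11 = vol[b + szr + sy] * (1 - tx) + vol[b + szr + sy + 1] * tx;
          double c0 = c00 * (1 - ty) + c10 * ty;
          double c1 = c01 * (1 - ty) + c11 * ty;
          out[o] = c0 * (1 - tz) + c1 * tz;
        }
      }
    }
  }
  return out;
}

// Separable Gaussian filter in voxel units, clamp (replicate) boundary.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  if (sigma <= 0) return clone(vol);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> w(2 * r + 1);
  double tot = 0;
  for (int t = -r; t <= r; t++) {
    w[t + r] = std::exp(-0.5 * sq(t / sigma));
    tot += w[t + r];
  }
  for (double& x : w) x /= tot;

  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const size_t strides[3] = {1, (size_t)nx, (size_t)nx * ny};
  const int dims[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ax++) {
    size_t st = strides[ax];
    int m = dims[ax];
    size_t nlines = n / m;
    // iterate lines along axis ax
    for (size_t line = 0; line < nlines; line++) {
      // compute base index of this line
      size_t rem = line, base = 0;
      for (int q = 0; q < 3; q++) {
        if (q == ax) continue;
        size_t d = (size_t)dims[q];
        base += (rem % d) * strides[q];
        rem /= d;
      }
      for (int p = 0; p < m; p++) {
        double acc = 0;
        for (int t = -r; t <= r; t++) {
          int pp = p + t;
          if (pp < 0) pp = 0;
          if (pp > m - 1) pp = m - 1;
          acc += w[t + r] * a[base + (size_t)pp * st];
        }
        b[base + (size_t)p * st] = acc;
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}
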
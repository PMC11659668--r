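#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 13 unique 3D direction offsets at Chebyshev distance 1 (symmetric pairs excluded)
static const int OFF13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static const double BIG = 1e15;

// 1D squared distance transform (lower envelope of parabolas) with sample step s
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double s) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double qq = q * s;
    double sv;
    for (;;) {
      double vk = v[k] * s;
      sv = ((f[q] + qq * qq) - (f[v[k]] + vk * vk)) / (2.0 * qq - 2.0 * vk);
      if (sv <= z[k] && k > 0) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = sv;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double qq = q * s;
    while (z[k + 1] < qq) k++;
    double vk = v[k] * s;
    d[q] = (qq - vk) * (qq - vk) + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest TRUE voxel.
// Separable exact transform; spacing gives the physical step per axis.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dm, NumericVector spacing) {
  int nx = dm[0], ny = dm[1], nz = dm[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  for (size_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      size_t base = (size_t)j * nx + (size_t)k * nx * ny;
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      size_t base = (size_t)i + (size_t)k * nx * ny;
      for (int j = 0; j < ny; j++) f[j] = out[base + (size_t)j * nx];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; j++) out[base + (size_t)j * nx] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      size_t base = (size_t)i + (size_t)j * nx;
      for (int k = 0; k < nz; k++) f[k] = out[base + (size_t)k * nx * ny];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; k++) out[base + (size_t)k * nx * ny] = d[k];
    }
  out.attr("dim") = dm;
  return out;
}

// Surface area (mm^2) of a binary mask: gradient-magnitude integral of the
// Gaussian-smoothed indicator (sigma in voxels), computed on a zero-padded
// copy with central differences.
// [[Rcpp::export]]
double cpp_surface_area(LogicalVector mask, IntegerVector dm,
                        NumericVector spacing, double sigma) {
  const int R = 3;
  int nx = dm[0] + 2 * (R + 1), ny = dm[1] + 2 * (R + 1), nz = dm[2] + 2 * (R + 1);
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> a(n, 0.0), b(n, 0.0);
  for (int k = 0; k < dm[2]; k++)
    for (int j = 0; j < dm[1]; j++)
      for (int i = 0; i < dm[0]; i++)
        a[(size_t)(i + R + 1) + (size_t)(j + R + 1) * nx + (size_t)(k + R + 1) * nx * ny] =
          mask[(size_t)i + (size_t)j * dm[0] + (size_t)k * dm[0] * dm[1]] ? 1.0 : 0.0;
  double kern[2 * R + 1], ksum = 0.0;
  for (int o = -R; o <= R; o++) { kern[o + R] = std::exp(-0.5 * o * o / (sigma * sigma)); ksum += kern[o + R]; }
  for (int o = 0; o <= 2 * R; o++) kern[o] /= ksum;
  size_t strides[3] = {1, (size_t)nx, (size_t)nx * ny};
  int dims[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; axis++) {
    size_t s = strides[axis];
    int nd = dims[axis];
    std::fill(b.begin(), b.end(), 0.0);
    for (size_t idx = 0; idx < n; idx++) {
      double v = a[idx];
      if (v == 0.0) continue;
      int pos = (int)((idx / s) % nd);
      for (int o = -R; o <= R; o++) {
        int p2 = pos + o;
        if (p2 < 0 || p2 >= nd) continue;
        b[idx + (size_t)o * (long long)s] += v * kern[o + R];
      }
    }
    std::swap(a, b);
  }
  double total = 0.0;
  for (int k = 1; k < nz - 1; k++)
    for (int j = 1; j < ny - 1; j++)
      for (int i = 1; i < nx - 1; i++) {
        size_t idx = (size_t)i + (size_t)j * nx + (size_t)k * nx * ny;
        double gx = (a[idx + 1] - a[idx - 1]) / (2.0 * spacing[0]);
        double gy = (a[idx + nx] - a[idx - nx]) / (2.0 * spacing[1]);
        double gz = (a[idx + (size_t)nx * ny] - a[idx - (size_t)nx * ny]) / (2.0 * spacing[2]);
        total += std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  return total * spacing[0] * spacing[1] * spacing[2];
}

// Symmetric grey-level co-occurrence counts for 13 directions at distance 1.
// g holds discretized levels 1..nbins, 0 = outside the region.
// Returns an nbins x nbins x 13 array of counts.
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector g, IntegerVector dm, int nbins) {
  int nx = dm[0], ny = dm[1], nz = dm[2];
  NumericVector out((size_t)nbins * nbins * 13);
  double* o = REAL(out);
  for (int d = 0; d < 13; d++) {
    int dx = OFF13[d][0], dy = OFF13[d][1], dz = OFF13[d][2];
    double* od = o + (size_t)d * nbins * nbins;
    for (int k = 0; k < nz; k++) {
      int k2 = k + dz;
      if (k2 < 0 || k2 >= nz) continue;
      for (int j = 0; j < ny; j++) {
        int j2 = j + dy;
        if (j2 < 0 || j2 >= ny) continue;
        for (int i = 0; i < nx; i++) {
          int i2 = i + dx;
          if (i2 < 0 || i2 >= nx) continue;
          int a = g[(size_t)i + (size_t)j * nx + (size_t)k * nx * ny];
          if (a == 0) continue;
          int b = g[(size_t)i2 + (size_t)j2 * nx + (size_t)k2 * nx * ny];
          if (b == 0) continue;
          od[(a - 1) + (size_t)(b - 1) * nbins] += 1.0;
          od[(b - 1) + (size_t)(a - 1) * nbins] += 1.0;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nbins, nbins, 13);
  return out;
}

// Grey-level run-length counts summed over the 13 direction families.
// Rows = grey level, columns = run length.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector g, IntegerVector dm, int nbins) {
  int nx = dm[0], ny = dm[1], nz = dm[2];
  int maxlen = nx + ny + nz;
  NumericMatrix out(nbins, maxlen);
  for (int d = 0; d < 13; d++) {
    int dx = OFF13[d][0], dy = OFF13[d][1], dz = OFF13[d][2];
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          int lev = g[(size_t)i + (size_t)j * nx + (size_t)k * nx * ny];
          if (lev == 0) continue;
          // run starts here iff the previous voxel along -d is absent/different
          int ip = i - dx, jp = j - dy, kp = k - dz;
          if (ip >= 0 && ip < nx && jp >= 0 && jp < ny && kp >= 0 && kp < nz) {
            if (g[(size_t)ip + (size_t)jp * nx + (size_t)kp * nx * ny] == lev) continue;
          }
          int len = 1;
          int ic = i + dx, jc = j + dy, kc = k + dz;
          while (ic >= 0 && ic < nx && jc >= 0 && jc < ny && kc >= 0 && kc < nz &&
                 g[(size_t)ic + (size_t)jc * nx + (size_t)kc * nx * ny] == lev) {
            len++;
            ic += dx; jc += dy; kc += dz;
          }
          if (len > maxlen) len = maxlen;
          out(lev - 1, len - 1) += 1.0;
        }
  }
  return out;
}

// Grey-level size-zone decomposition: connected components (26-connectivity)
// of equal-level voxels. Returns a matrix with columns (level, size).
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector g, IntegerVector dm) {
  int nx = dm[0], ny = dm[1], nz = dm[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> levels, sizes;
  std::vector<size_t> stack;
  for (size_t s0 = 0; s0 < n; s0++) {
    if (seen[s0] || g[s0] == 0) continue;
    int lev = g[s0];
    int size = 0;
    stack.clear();
    stack.push_back(s0);
    seen[s0] = 1;
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      size++;
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((size_t)nx * ny));
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int i2 = i + di, j2 = j + dj, k2 = k + dk;
            if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz) continue;
            size_t idx = (size_t)i2 + (size_t)j2 * nx + (size_t)k2 * nx * ny;
            if (!seen[idx] && g[idx] == lev) {
              seen[idx] = 1;
              stack.push_back(idx);
            }
          }
    }
    levels.push_back(lev);
    sizes.push_back(size);
  }
  IntegerMatrix out(levels.size(), 2);
  for (int r = 0; r < (int)levels.size(); r++) {
    out(r, 0) = levels[r];
    out(r, 1) = sizes[r];
  }
  return out;
}

// Neighbourhood grey-tone difference accumulators: for each level i,
// s[i] = sum over in-region voxels of |i - mean(26-neighbourhood levels)|,
// cnt[i] = number of contributing voxels.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector g, IntegerVector dm, int nbins) {
  int nx = dm[0], ny = dm[1], nz = dm[2];
  NumericVector s(nbins), cnt(nbins);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        int lev = g[(size_t)i + (size_t)j * nx + (size_t)k * nx * ny];
        if (lev == 0) continue;
        double acc = 0.0;
        int m = 0;
        for (int dk = -1; dk <= 1; dk++)
          for (int dj = -1; dj <= 1; dj++)
            for (int di = -1; di <= 1; di++) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int i2 = i + di, j2 = j + dj, k2 = k + dk;
              if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz) continue;
              int nb = g[(size_t)i2 + (size_t)j2 * nx + (size_t)k2 * nx * ny];
              if (nb > 0) {
                acc += nb;
                m++;
              }
            }
        if (m > 0) {
          s[lev - 1] += std::fabs((double)lev - acc / m);
          cnt[lev - 1] += 1.0;
        }
      }
  return List::create(_["s"] = s, _["n"] = cnt);
}
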
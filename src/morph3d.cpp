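// 3D binary-morphology primitives for volumetric bone images.
// Arrays are column-major with dims (d1, d2, d3) = (y, x, z); linear index
// i1 + d1*(i2 + d2*i3).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int lin(int i, int j, int k, int d1, int d2) {
  return i + d1 * (j + d2 * k);
}

// Connected-component labeling by iterative BFS.
// connectivity: 6 (face) or 26 (face+edge+vertex).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  std::vector<int> off;
  std::vector<int> di, dj, dk;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        int m = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (connectivity == 6 && m != 1) continue;
        di.push_back(dy); dj.push_back(dx); dk.push_back(dz);
      }
  const int nn = (int)di.size();

  std::vector<int> stack;
  stack.reserve(1024);
  int lab = 0;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int v = lin(i, j, k, d1, d2);
        if (!mask[v] || labels[v] != 0) continue;
        ++lab;
        labels[v] = lab;
        stack.push_back(v);
        while (!stack.empty()) {
          int cur = stack.back();
          stack.pop_back();
          int ck = cur / (d1 * d2);
          int rem = cur - ck * d1 * d2;
          int cj = rem / d1;
          int ci = rem - cj * d1;
          for (int t = 0; t < nn; ++t) {
            int ni = ci + di[t], nj = cj + dj[t], nk = ck + dk[t];
            if (ni < 0 || ni >= d1 || nj < 0 || nj >= d2 || nk < 0 || nk >= d3) continue;
            int w = lin(ni, nj, nk, d1, d2);
            if (mask[w] && labels[w] == 0) {
              labels[w] = lab;
              stack.push_back(w);
            }
          }
        }
      }
  labels.attr("dim") = dim;
  return labels;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) of a sampled
// function f; result overwrites d.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (in voxel units) from every voxel to the nearest
// TRUE voxel of `feature`. Voxels outside the grid carry no feature.
// [[Rcpp::export]]
NumericVector cpp_edt3d_sq(LogicalVector feature, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (feature.size() != n) stop("feature length does not match dim");
  // large finite sentinel: infinity breaks the parabola intersection formula
  const double FAR = 1e20;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = feature[i] ? 0.0 : FAR;

  int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along dim1 (y)
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j) {
      for (int i = 0; i < d1; ++i) f[i] = out[lin(i, j, k, d1, d2)];
      dt1d(f, d, v, z, d1);
      for (int i = 0; i < d1; ++i) out[lin(i, j, k, d1, d2)] = d[i];
    }
  // along dim2 (x)
  for (int k = 0; k < d3; ++k)
    for (int i = 0; i < d1; ++i) {
      for (int j = 0; j < d2; ++j) f[j] = out[lin(i, j, k, d1, d2)];
      dt1d(f, d, v, z, d2);
      for (int j = 0; j < d2; ++j) out[lin(i, j, k, d1, d2)] = d[j];
    }
  // along dim3 (z)
  for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      for (int k = 0; k < d3; ++k) f[k] = out[lin(i, j, k, d1, d2)];
      dt1d(f, d, v, z, d3);
      for (int k = 0; k < d3; ++k) out[lin(i, j, k, d1, d2)] = d[k];
    }
  out.attr("dim") = dim;
  return out;
}

// Per-label 26-neighbourhood contact flags against two reference masks
// (columns: exterior contact, marrow contact).
// [[Rcpp::export]]
LogicalMatrix cpp_contact_flags(IntegerVector labels, LogicalVector exterior,
                                LogicalVector marrow, IntegerVector dim, int nlab) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  LogicalMatrix flags(nlab, 2);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int v = lin(i, j, k, d1, d2);
        int lab = labels[v];
        if (lab <= 0) continue;
        if (flags(lab - 1, 0) && flags(lab - 1, 1)) continue;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy) {
              if (dy == 0 && dx == 0 && dz == 0) continue;
              int ni = i + dy, nj = j + dx, nk = k + dz;
              if (ni < 0 || ni >= d1 || nj < 0 || nj >= d2 || nk < 0 || nk >= d3) continue;
              int w = lin(ni, nj, nk, d1, d2);
              if (exterior[w]) flags(lab - 1, 0) = true;
              if (marrow[w]) flags(lab - 1, 1) = true;
            }
      }
  return flags;
}

static void blur_axis(std::vector<double>& src, std::vector<double>& dst,
                      int d1, int d2, int d3, int axis, const std::vector<double>& kern) {
  int r = (int)kern.size() / 2;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        double acc = 0.0, wsum = 0.0;
        for (int t = -r; t <= r; ++t) {
          int ni = i, nj = j, nk = k;
          if (axis == 0) ni += t; else if (axis == 1) nj += t; else nk += t;
          if (ni < 0 || ni >= d1 || nj < 0 || nj >= d2 || nk < 0 || nk >= d3) continue;
          double w = kern[t + r];
          acc += w * src[lin(ni, nj, nk, d1, d2)];
          wsum += w;
        }
        dst[lin(i, j, k, d1, d2)] = acc / wsum;
      }
}

// Separable Gaussian blur, sigma in voxels, kernel truncated at 3 sigma and
// renormalized at the borders (replicate-free edge handling).
// [[Rcpp::export]]
NumericVector cpp_blur3(NumericVector vol, IntegerVector dim, double sigma) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (vol.size() != n) stop("vol length does not match dim");
  if (sigma <= 0) return clone(vol);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  for (int t = -r; t <= r; ++t) kern[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));

  std::vector<double> a(n), b(n);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = vol[i];
  blur_axis(a, b, d1, d2, d3, 0, kern);
  blur_axis(b, a, d1, d2, d3, 1, kern);
  blur_axis(a, b, d1, d2, d3, 2, kern);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = b[i];
  out.attr("dim") = dim;
  return out;
}
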
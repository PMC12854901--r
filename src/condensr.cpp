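#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Arrays are R arrays dim (ny, nx, nz), column-major: idx = y + ny*(x + nx*z).

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 3D running median with edge replication, exact.
// Bucket counts over the global intensity range are maintained
// incrementally while sliding along y; the median bucket is found by a
// cumulative walk and the exact order statistic is resolved from the raw
// window values inside that bucket.
// [[Rcpp::export]]
NumericVector cpp_median_filter(NumericVector img, int ky, int kx, int kz) {
  IntegerVector dim = img.attr("dim");
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const int hy = ky / 2, hx = kx / 2, hz = kz / 2;
  NumericVector out(img.size());
  out.attr("dim") = dim;
  const int wsize = ky * kx * kz;
  const int target = wsize / 2; // 0-based rank(s) of the median
  const bool even = wsize % 2 == 0;

  double lo = img[0], hi = img[0];
  for (R_xlen_t i = 1; i < img.size(); ++i) {
    if (img[i] < lo) lo = img[i];
    if (img[i] > hi) hi = img[i];
  }
  const int nb = 256;
  const double width = (hi > lo) ? (hi - lo) / nb : 1.0;
  auto bucket_of = [&](double v) {
    int b = (int)((v - lo) / width);
    return b < 0 ? 0 : (b >= nb ? nb - 1 : b);
  };
  // precomputed bucket index per voxel avoids repeated divisions
  std::vector<unsigned char> bimg(img.size());
  for (R_xlen_t i = 0; i < img.size(); ++i) bimg[i] = (unsigned char)bucket_of(img[i]);
  auto idx_at = [&](int y, int x, int z) {
    return (size_t)clampi(y, 0, ny - 1) +
           (size_t)ny * (clampi(x, 0, nx - 1) +
                         (size_t)nx * clampi(z, 0, nz - 1));
  };
  auto value_at = [&](int y, int x, int z) { return img[idx_at(y, x, z)]; };
  auto bucket_at = [&](int y, int x, int z) { return (int)bimg[idx_at(y, x, z)]; };

  std::vector<int> counts(nb);
  std::vector<double> inbucket;
  inbucket.reserve(wsize);
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      std::fill(counts.begin(), counts.end(), 0);
      for (int dz = -hz; dz <= hz; ++dz)
        for (int dx = -hx; dx <= hx; ++dx)
          for (int dy = -hy; dy <= hy; ++dy)
            ++counts[bucket_at(dy, x + dx, z + dz)];
      for (int y = 0; y < ny; ++y) {
        if (y > 0) {
          for (int dz = -hz; dz <= hz; ++dz)
            for (int dx = -hx; dx <= hx; ++dx) {
              --counts[bucket_at(y - 1 - hy, x + dx, z + dz)];
              ++counts[bucket_at(y + hy, x + dx, z + dz)];
            }
        }
        int below = 0, b = 0;
        while (below + counts[b] <= target) below += counts[b++];
        // rank of the median within bucket b
        int rank = target - below;
        inbucket.clear();
        for (int dz = -hz; dz <= hz; ++dz)
          for (int dx = -hx; dx <= hx; ++dx)
            for (int dy = -hy; dy <= hy; ++dy) {
              size_t ii = idx_at(y + dy, x + dx, z + dz);
              if ((int)bimg[ii] == b) inbucket.push_back(img[ii]);
            }
        std::nth_element(inbucket.begin(), inbucket.begin() + rank,
                         inbucket.end());
        double med = inbucket[rank];
        if (even) {
          double lo2;
          if (rank > 0) {
            lo2 = *std::max_element(inbucket.begin(), inbucket.begin() + rank);
          } else {
            // previous order statistic lives in an earlier bucket
            lo2 = -INFINITY;
            for (int dz = -hz; dz <= hz; ++dz)
              for (int dx = -hx; dx <= hx; ++dx)
                for (int dy = -hy; dy <= hy; ++dy) {
                  size_t ii = idx_at(y + dy, x + dx, z + dz);
                  double v = img[ii];
                  if (v < med && v > lo2 && (int)bimg[ii] < b) lo2 = v;
                }
          }
          med = 0.5 * (med + lo2);
        }
        out[y + (size_t)ny * (x + (size_t)nx * z)] = med;
      }
    }
  }
  return out;
}

// Sum-of-Gaussians curve with increment-parameterised means:
// par = (A_1..A_k, mu_1, d_2..d_k, s_1..s_k), mu_i = mu_1 + sum d_j.
static inline void inc_means(const double* par, int k, std::vector<double>& mu) {
  mu[0] = par[k];
  for (int i = 1; i < k; ++i) mu[i] = mu[i - 1] + par[k + i];
}

// [[Rcpp::export]]
NumericVector cpp_gmm_residuals_inc(NumericVector par, NumericVector x,
                                    NumericVector y, int k) {
  const int n = x.size();
  std::vector<double> mu(k);
  inc_means(par.begin(), k, mu);
  NumericVector r(n);
  for (int i = 0; i < n; ++i) {
    double f = 0.0;
    for (int j = 0; j < k; ++j) {
      double d = (x[i] - mu[j]) / par[2 * k + j];
      f += par[j] * std::exp(-0.5 * d * d);
    }
    r[i] = f - y[i];
  }
  return r;
}

// [[Rcpp::export]]
NumericMatrix cpp_gmm_jacobian_inc(NumericVector par, NumericVector x,
                                   NumericVector y, int k) {
  const int n = x.size();
  std::vector<double> mu(k);
  inc_means(par.begin(), k, mu);
  NumericMatrix J(n, 3 * k);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) {
      double s = par[2 * k + j];
      double d = x[i] - mu[j];
      double e = std::exp(-0.5 * d * d / (s * s));
      double a = par[j];
      J(i, j) = e;
      double dmu = a * e * d / (s * s);
      // d mu_j / d delta_l = 1 for l <= j: accumulate into increment columns
      for (int l = 0; l <= j; ++l) J(i, k + l) += dmu;
      J(i, 2 * k + j) = a * e * d * d / (s * s * s);
    }
  }
  return J;
}

static void blur_axis(std::vector<double>& v, std::vector<double>& tmp,
                      const std::vector<double>& kern, int n, int stride,
                      int nline, const std::vector<size_t>& starts) {
  const int h = ((int)kern.size() - 1) / 2;
  for (int l = 0; l < nline; ++l) {
    const size_t s = starts[l];
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = -h; j <= h; ++j)
        acc += kern[j + h] * v[s + (size_t)stride * clampi(i + j, 0, n - 1)];
      tmp[s + (size_t)stride * i] = acc;
    }
  }
  v.swap(tmp);
}

// Separable Gaussian blur, per-axis sigma in voxels; edge replication.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector img, double sy, double sx, double sz) {
  IntegerVector dim = img.attr("dim");
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  std::vector<double> v(img.begin(), img.end()), tmp(v.size());
  auto kernel = [](double s) {
    std::vector<double> k;
    int h = std::max(1, (int)std::ceil(4.0 * s));
    double sum = 0.0;
    for (int i = -h; i <= h; ++i) {
      double w = std::exp(-0.5 * (i / s) * (i / s));
      k.push_back(w);
      sum += w;
    }
    for (double& w : k) w /= sum;
    return k;
  };
  if (sy > 0) {
    std::vector<size_t> starts;
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) starts.push_back((size_t)ny * (x + (size_t)nx * z));
    blur_axis(v, tmp, kernel(sy), ny, 1, (int)starts.size(), starts);
  }
  if (sx > 0) {
    std::vector<size_t> starts;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) starts.push_back((size_t)y + (size_t)ny * nx * z);
    blur_axis(v, tmp, kernel(sx), nx, ny, (int)starts.size(), starts);
  }
  if (sz > 0) {
    std::vector<size_t> starts;
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) starts.push_back((size_t)y + (size_t)ny * x);
    blur_axis(v, tmp, kernel(sz), nz, ny * nx, (int)starts.size(), starts);
  }
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// Connected-component labelling of a logical mask, breadth-first,
// connectivity 6 (faces) or 26 (faces+edges+corners). Labels follow
// column-major scan order of the first voxel of each component.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, int connectivity) {
  IntegerVector dim = mask.attr("dim");
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  IntegerVector labels((size_t)ny * nx * nz);
  labels.attr("dim") = dim;
  std::vector<std::array<int, 3>> nbrs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        int manh = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        nbrs.push_back({dy, dx, dz});
      }
  int next = 0;
  std::queue<size_t> q;
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        size_t i = y + (size_t)ny * (x + (size_t)nx * z);
        if (!mask[i] || labels[i] != 0) continue;
        labels[i] = ++next;
        q.push(i);
        while (!q.empty()) {
          size_t c = q.front();
          q.pop();
          int cy = c % ny, cx = (c / ny) % nx, cz = c / ((size_t)ny * nx);
          for (const auto& d : nbrs) {
            int yy = cy + d[0], xx = cx + d[1], zz = cz + d[2];
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
              continue;
            size_t j = yy + (size_t)ny * (xx + (size_t)nx * zz);
            if (mask[j] && labels[j] == 0) {
              labels[j] = next;
              q.push(j);
            }
          }
        }
      }
  return labels;
}
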
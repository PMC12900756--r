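#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>

using namespace Rcpp;

// Index helpers: arrays are R arrays in column-major order, dim = (nx, ny, nz),
// linear index = x + nx*(y + ny*z), 0-based here.

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---------------------------------------------------------------------------
// 1-D squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// applied separably along each axis with physical spacing.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double step) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
               (2.0 * s2 * q - 2.0 * s2 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
          (2.0 * s2 * q - 2.0 * s2 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (q - v[k]) * step;
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared physical distance from every voxel to the nearest foreground voxel.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = 1e30;
  NumericVector d(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) d[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, out;
  // x pass
  f.resize(nx); out.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = d[lin(x, y, z, nx, ny)];
      dt1d(f, out, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) d[lin(x, y, z, nx, ny)] = out[x];
    }
  // y pass
  f.resize(ny); out.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = d[lin(x, y, z, nx, ny)];
      dt1d(f, out, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) d[lin(x, y, z, nx, ny)] = out[y];
    }
  // z pass
  f.resize(nz); out.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = d[lin(x, y, z, nx, ny)];
      dt1d(f, out, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) d[lin(x, y, z, nx, ny)] = out[z];
    }
  return d;
}

// ---------------------------------------------------------------------------
// Sliding-window first-order statistics (19 channels) over an odd cubic
// window restricted to in-mask neighbors.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List local_stats_cpp(NumericVector img, LogicalVector mask, IntegerVector dim,
                     int window, double bin_width, int min_support,
                     double voxel_volume) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int r = window / 2;
  std::vector<int> vox;
  vox.reserve(16384);
  for (R_xlen_t i = 0; i < mask.size(); ++i) if (mask[i]) vox.push_back((int)i);
  const int n = (int)vox.size();
  NumericMatrix stats(n, 19);
  LogicalVector valid(n);
  IntegerVector idx(n);
  IntegerVector support(n);

  const double* pimg = REAL(img);
  const int* pmask = LOGICAL(mask);
  std::vector<double> vals(window * window * window);
  std::vector<int> hist;
  hist.reserve(4096);

  for (int t = 0; t < n; ++t) {
    const int i = vox[t];
    idx[t] = i + 1;  // 1-based for R
    const int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    int m = 0;
    const int z0 = std::max(z - r, 0), z1 = std::min(z + r, nz - 1);
    const int y0 = std::max(y - r, 0), y1 = std::min(y + r, ny - 1);
    const int x0 = std::max(x - r, 0), x1 = std::min(x + r, nx - 1);
    for (int zz = z0; zz <= z1; ++zz)
      for (int yy = y0; yy <= y1; ++yy) {
        const int base = nx * (yy + ny * zz);
        for (int xx = x0; xx <= x1; ++xx) {
          const int j = base + xx;
          if (pmask[j]) vals[m++] = pimg[j];
        }
      }
    valid[t] = m >= min_support;
    support[t] = m;
    std::sort(vals.begin(), vals.begin() + m);
    double sum = 0, sum2 = 0, sumabs;
    for (int u = 0; u < m; ++u) { sum += vals[u]; sum2 += vals[u] * vals[u]; }
    const double mean = sum / m;
    double m2 = 0, m3 = 0, m4 = 0; sumabs = 0;
    for (int u = 0; u < m; ++u) {
      const double d1 = vals[u] - mean;
      m2 += d1 * d1; m3 += d1 * d1 * d1; m4 += d1 * d1 * d1 * d1;
      sumabs += std::fabs(d1);
    }
    m2 /= m; m3 /= m; m4 /= m;
    auto pct = [&](double q) {
      if (m == 1) return vals[0];
      const double pos = q * (m - 1);
      const int lo = (int)std::floor(pos);
      const int hi = std::min(lo + 1, m - 1);
      const double w = pos - lo;
      return vals[lo] * (1 - w) + vals[hi] * w;
    };
    const double p10 = pct(0.10), p25 = pct(0.25), p50 = pct(0.50),
                 p75 = pct(0.75), p90 = pct(0.90);
    // robust MAD: values within [p10, p90]
    double rsum = 0; int rn = 0;
    for (int u = 0; u < m; ++u)
      if (vals[u] >= p10 && vals[u] <= p90) { rsum += vals[u]; ++rn; }
    double rmad = 0;
    if (rn > 0) {
      const double rmean = rsum / rn;
      for (int u = 0; u < m; ++u)
        if (vals[u] >= p10 && vals[u] <= p90) rmad += std::fabs(vals[u] - rmean);
      rmad /= rn;
    }
    // histogram on fixed-width bins for entropy/uniformity
    double entropy = 0, uniformity = 0;
    {
      const int b0 = (int)std::floor(vals[0] / bin_width);
      const int b1 = (int)std::floor(vals[m - 1] / bin_width);
      hist.assign(b1 - b0 + 1, 0);
      for (int u = 0; u < m; ++u)
        hist[(int)std::floor(vals[u] / bin_width) - b0]++;
      for (size_t u = 0; u < hist.size(); ++u) {
        if (hist[u] > 0) {
          const double p = (double)hist[u] / m;
          entropy -= p * std::log2(p);
          uniformity += p * p;
        }
      }
    }
    const double sd = std::sqrt(m2);
    stats(t, 0)  = sum2;                              // Energy
    stats(t, 1)  = sum2 * voxel_volume;               // TotalEnergy
    stats(t, 2)  = entropy;                           // Entropy
    stats(t, 3)  = vals[0];                           // Minimum
    stats(t, 4)  = p10;                               // 10Percentile
    stats(t, 5)  = p90;                               // 90Percentile
    stats(t, 6)  = vals[m - 1];                       // Maximum
    stats(t, 7)  = mean;                              // Mean
    stats(t, 8)  = p50;                               // Median
    stats(t, 9)  = p75 - p25;                         // InterquartileRange
    stats(t, 10) = vals[m - 1] - vals[0];             // Range
    stats(t, 11) = sumabs / m;                        // MeanAbsoluteDeviation
    stats(t, 12) = rmad;                              // RobustMeanAbsoluteDeviation
    stats(t, 13) = std::sqrt(sum2 / m);               // RootMeanSquared
    stats(t, 14) = sd;                                // StandardDeviation
    stats(t, 15) = (m2 > 0) ? m3 / std::pow(m2, 1.5) : 0.0;  // Skewness
    stats(t, 16) = (m2 > 0) ? m4 / (m2 * m2) : 0.0;   // Kurtosis
    stats(t, 17) = m2;                                // Variance
    stats(t, 18) = uniformity;                        // Uniformity
  }
  return List::create(_["values"] = stats, _["valid"] = valid, _["index"] = idx,
                      _["support"] = support);
}

// ---------------------------------------------------------------------------
// Texture matrices. `levels` is an integer array with 0 outside the region
// and 1..ng inside.
// ---------------------------------------------------------------------------

static const int DIR13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

// Symmetric gray-level co-occurrence counts, one ng x ng slab per direction.
// [[Rcpp::export]]
NumericVector glcm_counts_cpp(IntegerVector levels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(ng * ng * 13);
  for (int d = 0; d < 13; ++d) {
    const int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z) {
      const int zz = z + dz;
      if (zz < 0 || zz >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        const int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        for (int x = 0; x < nx; ++x) {
          const int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          const int a = levels[lin(x, y, z, nx, ny)];
          const int b = levels[lin(xx, yy, zz, nx, ny)];
          if (a > 0 && b > 0) {
            out[(a - 1) + ng * (b - 1) + ng * ng * d] += 1.0;
            out[(b - 1) + ng * (a - 1) + ng * ng * d] += 1.0;
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// Run-length counts, one ng x max_run slab per direction.
// [[Rcpp::export]]
NumericVector glrlm_counts_cpp(IntegerVector levels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int maxrun = std::max(nx, std::max(ny, nz));
  NumericVector out(ng * maxrun * 13);
  for (int d = 0; d < 13; ++d) {
    const int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int g = levels[lin(x, y, z, nx, ny)];
          if (g <= 0) continue;
          // start of a run only if predecessor is not the same level
          const int px = x - dx, py = y - dy, pz = z - dz;
          if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz &&
              levels[lin(px, py, pz, nx, ny)] == g) continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz &&
                 levels[lin(cx, cy, cz, nx, ny)] == g) {
            ++len; cx += dx; cy += dy; cz += dz;
          }
          out[(g - 1) + ng * (len - 1) + ng * maxrun * d] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxrun, 13);
  return out;
}

// Size-zone list: 26-connected components per gray level.
// Returns a 2-column matrix (level, zone size).
// [[Rcpp::export]]
IntegerMatrix glszm_zones_cpp(IntegerVector levels, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<char> seen(levels.size(), 0);
  std::vector<int> zl, zs;
  std::vector<int> stack;
  for (R_xlen_t i = 0; i < levels.size(); ++i) {
    if (levels[i] <= 0 || seen[i]) continue;
    const int g = levels[i];
    int size = 0;
    stack.clear();
    stack.push_back((int)i);
    seen[i] = 1;
    while (!stack.empty()) {
      const int j = stack.back(); stack.pop_back();
      ++size;
      const int x = j % nx, y = (j / nx) % ny, z = j / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            const int k = lin(xx, yy, zz, nx, ny);
            if (!seen[k] && levels[k] == g) { seen[k] = 1; stack.push_back(k); }
          }
    }
    zl.push_back(g); zs.push_back(size);
  }
  IntegerMatrix out((int)zl.size(), 2);
  for (size_t u = 0; u < zl.size(); ++u) { out(u, 0) = zl[u]; out(u, 1) = zs[u]; }
  return out;
}

// NGTDM: per gray level, occurrence count n_i and summed absolute deviation
// s_i of voxel value from the mean of its in-region 26-neighbors.
// [[Rcpp::export]]
NumericMatrix ngtdm_cpp(IntegerVector levels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2);
  for (R_xlen_t i = 0; i < levels.size(); ++i) {
    const int g = levels[i];
    if (g <= 0) continue;
    const int x = i % nx, y = (i / nx) % ny, z = (int)(i / (nx * ny));
    double nbsum = 0; int nbn = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          const int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          const int h = levels[lin(xx, yy, zz, nx, ny)];
          if (h > 0) { nbsum += h; ++nbn; }
        }
    out(g - 1, 0) += 1.0;
    if (nbn > 0) out(g - 1, 1) += std::fabs((double)g - nbsum / nbn);
  }
  return out;
}

// GLDM: dependence counts. A neighbor is dependent if |level difference| <= alpha.
// Matrix ng x (27): column d holds the count of voxels with d dependent
// neighbors (d in 0..26).
// [[Rcpp::export]]
NumericMatrix gldm_counts_cpp(IntegerVector levels, IntegerVector dim, int ng,
                              int alpha) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 27);
  for (R_xlen_t i = 0; i < levels.size(); ++i) {
    const int g = levels[i];
    if (g <= 0) continue;
    const int x = i % nx, y = (i / nx) % ny, z = (int)(i / (nx * ny));
    int dep = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          const int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          const int h = levels[lin(xx, yy, zz, nx, ny)];
          if (h > 0 && std::abs(h - g) <= alpha) ++dep;
        }
    out(g - 1, dep) += 1.0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Geometry helpers
// ---------------------------------------------------------------------------

// Maximum pairwise Euclidean distance between rows of a coordinate matrix.
// [[Rcpp::export]]
double max_pairwise_dist_cpp(NumericMatrix coords) {
  const int n = coords.nrow(), p = coords.ncol();
  double best = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0;
      for (int k = 0; k < p; ++k) {
        const double d = coords(i, k) - coords(j, k);
        s += d * d;
      }
      if (s > best) best = s;
    }
  return std::sqrt(best);
}

// Separable convolution along one axis (0, 1 or 2) with nearest-edge padding.
// Kernel length must be odd.
// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector arr, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kl = kernel.size(), r = kl / 2;
  NumericVector out(arr.size());
  const int n[3] = {nx, ny, nz};
  const int len = n[axis];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double s = 0;
        for (int t = -r; t <= r; ++t) {
          int xx = x, yy = y, zz = z;
          int* c = (axis == 0) ? &xx : (axis == 1) ? &yy : &zz;
          *c += t;
          if (*c < 0) *c = 0;
          if (*c >= len) *c = len - 1;
          s += kernel[t + r] * arr[lin(xx, yy, zz, nx, ny)];
        }
        out[lin(x, y, z, nx, ny)] = s;
      }
  return out;
}

// Trilinear (or nearest-neighbor) resampling onto a new grid defined in the
// same physical space: value at physical point origin_out + i * spacing_out.
// [[Rcpp::export]]
NumericVector resample_cpp(NumericVector arr, IntegerVector dim,
                           NumericVector spacing, NumericVector origin,
                           IntegerVector out_dim, NumericVector out_spacing,
                           NumericVector out_origin, bool nearest) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x) {
        // continuous index in the source grid
        const double fx = (out_origin[0] + x * out_spacing[0] - origin[0]) / spacing[0];
        const double fy = (out_origin[1] + y * out_spacing[1] - origin[1]) / spacing[1];
        const double fz = (out_origin[2] + z * out_spacing[2] - origin[2]) / spacing[2];
        double v;
        if (nearest) {
          int ix = (int)std::lround(fx), iy = (int)std::lround(fy), iz = (int)std::lround(fz);
          ix = std::min(std::max(ix, 0), nx - 1);
          iy = std::min(std::max(iy, 0), ny - 1);
          iz = std::min(std::max(iz, 0), nz - 1);
          v = arr[lin(ix, iy, iz, nx, ny)];
        } else {
          double cx = std::min(std::max(fx, 0.0), (double)(nx - 1));
          double cy = std::min(std::max(fy, 0.0), (double)(ny - 1));
          double cz = std::min(std::max(fz, 0.0), (double)(nz - 1));
          const int x0 = std::min((int)std::floor(cx), nx - 2 >= 0 ? nx - 2 : 0);
          const int y0 = std::min((int)std::floor(cy), ny - 2 >= 0 ? ny - 2 : 0);
          const int z0 = std::min((int)std::floor(cz), nz - 2 >= 0 ? nz - 2 : 0);
          const double wx = cx - x0, wy = cy - y0, wz = cz - z0;
          const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
                    z1 = std::min(z0 + 1, nz - 1);
          v = (1 - wz) * ((1 - wy) * ((1 - wx) * arr[lin(x0, y0, z0, nx, ny)] +
                                      wx * arr[lin(x1, y0, z0, nx, ny)]) +
                          wy * ((1 - wx) * arr[lin(x0, y1, z0, nx, ny)] +
                                wx * arr[lin(x1, y1, z0, nx, ny)])) +
              wz * ((1 - wy) * ((1 - wx) * arr[lin(x0, y0, z1, nx, ny)] +
                                wx * arr[lin(x1, y0, z1, nx, ny)]) +
                    wy * ((1 - wx) * arr[lin(x0, y1, z1, nx, ny)] +
                          wx * arr[lin(x1, y1, z1, nx, ny)]));
        }
        out[lin(x, y, z, ox, oy)] = v;
      }
  return out;
}

// Fill unlabeled in-mask voxels (label 0) by breadth-first propagation from
// labeled voxels over the 6-neighborhood; ties resolved toward the smaller
// label via processing order.
// [[Rcpp::export]]
IntegerVector label_fill_cpp(IntegerVector labels, LogicalVector mask,
                             IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out = clone(labels);
  std::queue<int> q;
  for (R_xlen_t i = 0; i < out.size(); ++i)
    if (mask[i] && out[i] > 0) q.push((int)i);
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    const int j = q.front(); q.pop();
    const int x = j % nx, y = (j / nx) % ny, z = j / (nx * ny);
    for (int d = 0; d < 6; ++d) {
      const int xx = x + off[d][0], yy = y + off[d][1], zz = z + off[d][2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      const int k = lin(xx, yy, zz, nx, ny);
      if (mask[k] && out[k] == 0) { out[k] = out[j]; q.push(k); }
    }
  }
  return out;
}
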
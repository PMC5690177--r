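// Low-level voxel kernels: connected-component labelling, binary morphology
// with arbitrary structuring-element offsets, 3D Sobel gradient magnitude,
// boundary extraction and brute-force nearest-neighbour lookup.
// All grids are passed as flat vectors with a dim attribute (nx, ny, nz),
// column-major as in R arrays: index = x + nx*(y + ny*z).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// 26-connected component labelling by iterative flood fill.
// Returns integer labels (0 = background), numbered in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++next;
    labels[seed] = next;
    stack.push_back((int)seed);
    while (!stack.empty()) {
      const int cur = stack.back();
      stack.pop_back();
      const int z = cur / (nx * ny);
      const int rem = cur - z * nx * ny;
      const int y = rem / nx;
      const int x = rem - y * nx;
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            const int ni = lin(xx, yy, zz, nx, ny);
            if (mask[ni] && labels[ni] == 0) {
              labels[ni] = next;
              stack.push_back(ni);
            }
          }
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// Binary erosion by a structuring element given as K x 3 integer voxel
// offsets. Outside the grid counts as background, so masks erode at the
// grid border (consistent with a bounded field of view).
// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dim,
                        IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int k = offsets.nrow();
  LogicalVector out(n, false);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    const int z = (int)(i / (nx * ny));
    const int rem = (int)(i - (R_xlen_t)z * nx * ny);
    const int y = rem / nx;
    const int x = rem - y * nx;
    bool keep = true;
    for (int j = 0; j < k; ++j) {
      const int xx = x + offsets(j, 0);
      const int yy = y + offsets(j, 1);
      const int zz = z + offsets(j, 2);
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz ||
          !mask[lin(xx, yy, zz, nx, ny)]) {
        keep = false;
        break;
      }
    }
    out[i] = keep;
  }
  out.attr("dim") = dim;
  return out;
}

// Binary dilation by the same offset convention (offsets are applied
// from every foreground voxel; clipped at the grid border).
// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dim,
                         IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int k = offsets.nrow();
  LogicalVector out(n, false);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    const int z = (int)(i / (nx * ny));
    const int rem = (int)(i - (R_xlen_t)z * nx * ny);
    const int y = rem / nx;
    const int x = rem - y * nx;
    for (int j = 0; j < k; ++j) {
      const int xx = x + offsets(j, 0);
      const int yy = y + offsets(j, 1);
      const int zz = z + offsets(j, 2);
      if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
        out[lin(xx, yy, zz, nx, ny)] = true;
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Boundary voxels: foreground voxels with at least one 6-neighbour in the
// background (or outside the grid).
// [[Rcpp::export]]
LogicalVector cpp_boundary(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    const int z = (int)(i / (nx * ny));
    const int rem = (int)(i - (R_xlen_t)z * nx * ny);
    const int y = rem / nx;
    const int x = rem - y * nx;
    for (int j = 0; j < 6; ++j) {
      const int xx = x + dx[j], yy = y + dy[j], zz = z + dz[j];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz ||
          !mask[lin(xx, yy, zz, nx, ny)]) {
        out[i] = true;
        break;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// 3D Sobel gradient magnitude. Each component uses the derivative kernel
// (-1, 0, 1) along its axis and the smoothing kernel (1, 2, 4, 2, 1 as the
// separable product of (1,2,1)x(1,2,1)) across the other two; components
// are scaled by 1/16 so a unit axis-aligned step has unit peak response.
// Borders are clamped (replicated edge values).
// [[Rcpp::export]]
NumericVector cpp_sobel_magnitude(NumericVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double s[3] = {1.0, 2.0, 1.0};
  const double d[3] = {-1.0, 0.0, 1.0};
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        double gx = 0.0, gy = 0.0, gz = 0.0;
        for (int kz = -1; kz <= 1; ++kz) {
          int zz = z + kz;
          zz = zz < 0 ? 0 : (zz >= nz ? nz - 1 : zz);
          for (int ky = -1; ky <= 1; ++ky) {
            int yy = y + ky;
            yy = yy < 0 ? 0 : (yy >= ny ? ny - 1 : yy);
            for (int kx = -1; kx <= 1; ++kx) {
              int xx = x + kx;
              xx = xx < 0 ? 0 : (xx >= nx ? nx - 1 : xx);
              const double v = vol[lin(xx, yy, zz, nx, ny)];
              gx += d[kx + 1] * s[ky + 1] * s[kz + 1] * v;
              gy += s[kx + 1] * d[ky + 1] * s[kz + 1] * v;
              gz += s[kx + 1] * s[ky + 1] * d[kz + 1] * v;
            }
          }
        }
        gx /= 16.0; gy /= 16.0; gz /= 16.0;
        out[lin(x, y, z, nx, ny)] = std::sqrt(gx * gx + gy * gy + gz * gz);
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// For each query point, the row index (1-based) of its Euclidean nearest
// neighbour among the reference points. Brute force; exact.
// [[Rcpp::export]]
IntegerVector cpp_nn_index(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = R_PosInf;
    int arg = 0;
    for (int j = 0; j < nr; ++j) {
      const double dx = qx - ref(j, 0);
      const double dy = qy - ref(j, 1);
      const double dz = qz - ref(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        arg = j;
      }
    }
    out[i] = arg + 1;
  }
  return out;
}

// Grayscale reconstruction by dilation of `marker` under `limit` with
// 6-connectivity, by iterated neighbourhood maxima clamped to the limit.
// Used for the H-convex transform on small volumes of interest.
// [[Rcpp::export]]
NumericVector cpp_reconstruct_dilation(NumericVector marker,
                                       NumericVector limit,
                                       IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector cur = clone(marker);
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          const int i = lin(x, y, z, nx, ny);
          double m = cur[i];
          for (int j = 0; j < 6; ++j) {
            const int xx = x + dx[j], yy = y + dy[j], zz = z + dz[j];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            const double v = cur[lin(xx, yy, zz, nx, ny)];
            if (v > m) m = v;
          }
          if (m > limit[i]) m = limit[i];
          if (m > cur[i]) {
            cur[i] = m;
            changed = true;
          }
        }
      }
    }
  }
  cur.attr("dim") = dim;
  return cur;
}
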
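#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Low-level 3D lattice kernels. Arrays arrive as flat vectors in R's
// column-major order; dims = (nx, ny, nz). All bounds handling treats
// out-of-lattice voxels as background.

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Neighbourhood offsets for 6/18/26-connectivity.
static void neighbour_offsets(int connectivity, std::vector<int> &dx,
                              std::vector<int> &dy, std::vector<int> &dz) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manhattan = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manhattan > 1) continue;
        if (connectivity == 18 && manhattan > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// Label connected components of a binary lattice (0 = background).
// Labels are assigned in raster order of each component's first voxel,
// so labelling is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  const int nb = (int)dx.size();

  IntegerVector labels(n, 0);
  int next = 0;
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    labels[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int cz = cur / (nx * ny);
      int rem = cur - cz * nx * ny;
      int cy = rem / nx;
      int cx = rem - cy * nx;
      for (int k = 0; k < nb; ++k) {
        int x = cx + dx[k], y = cy + dy[k], z = cz + dz[k];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        int j = lin(x, y, z, nx, ny);
        if (mask[j] && labels[j] == 0) {
          labels[j] = next;
          q.push(j);
        }
      }
    }
  }
  labels.attr("n_components") = next;
  return labels;
}

// Dilation by an explicit offset set (rows of `offsets`, voxel units).
// Out-of-lattice voxels are background.
// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dims,
                         IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  LogicalVector out(n, false);
  const int no = offsets.nrow();
  for (int i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int cz = i / (nx * ny);
    int rem = i - cz * nx * ny;
    int cy = rem / nx;
    int cx = rem - cy * nx;
    for (int k = 0; k < no; ++k) {
      int x = cx + offsets(k, 0), y = cy + offsets(k, 1), z = cz + offsets(k, 2);
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
      out[lin(x, y, z, nx, ny)] = true;
    }
  }
  return out;
}

// Erosion: voxel survives iff every structuring-element offset lands on
// foreground (out-of-lattice counts as background).
// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dims,
                        IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  LogicalVector out(n, false);
  const int no = offsets.nrow();
  for (int i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int cz = i / (nx * ny);
    int rem = i - cz * nx * ny;
    int cy = rem / nx;
    int cx = rem - cy * nx;
    bool keep = true;
    for (int k = 0; k < no && keep; ++k) {
      int x = cx + offsets(k, 0), y = cy + offsets(k, 1), z = cz + offsets(k, 2);
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) {
        keep = false;
      } else if (!mask[lin(x, y, z, nx, ny)]) {
        keep = false;
      }
    }
    if (keep) out[i] = true;
  }
  return out;
}

// For each row of A (world coordinates, mm), the minimum Euclidean
// distance to any row of B.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      double d0 = ax - B(j, 0), d1 = ay - B(j, 1), d2 = az - B(j, 2);
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
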
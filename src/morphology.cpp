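#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3-D binary morphology kernels shared by the segmentation stage.
// Volumes are logical arrays in column-major (x fastest) order with
// dimensions (nx, ny, nz).

namespace {

struct Grid {
  int nx, ny, nz;
  R_xlen_t n;
  Grid(const IntegerVector &dim)
      : nx(dim[0]), ny(dim[1]), nz(dim[2]),
        n(static_cast<R_xlen_t>(dim[0]) * dim[1] * dim[2]) {}
  inline R_xlen_t idx(int x, int y, int z) const {
    return static_cast<R_xlen_t>(z) * nx * ny + static_cast<R_xlen_t>(y) * nx + x;
  }
};

inline void check_dim(const LogicalVector &mask, const IntegerVector &dim) {
  if (dim.size() != 3) stop("mask must be a 3-D array");
  R_xlen_t n = static_cast<R_xlen_t>(dim[0]) * dim[1] * dim[2];
  if (mask.size() != n) stop("mask length does not match its dimensions");
}

} // namespace

// Connected-component labelling, 26-neighbourhood.
// Returns an integer array: 0 background, 1..k component labels, ordered by
// first (column-major) voxel encountered so labelling is traversal-stable.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim) {
  check_dim(mask, dim);
  Grid g(dim);
  IntegerVector labels(g.n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t start = 0; start < g.n; ++start) {
    if (!mask[start] || labels[start]) continue;
    ++next_label;
    labels[start] = next_label;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = static_cast<int>(v / (static_cast<R_xlen_t>(g.nx) * g.ny));
      R_xlen_t rem = v - static_cast<R_xlen_t>(z) * g.nx * g.ny;
      int y = static_cast<int>(rem / g.nx);
      int x = static_cast<int>(rem % g.nx);
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= g.nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= g.ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx;
            if (xx < 0 || xx >= g.nx) continue;
            R_xlen_t w = g.idx(xx, yy, zz);
            if (mask[w] && !labels[w]) {
              labels[w] = next_label;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// Fill internal cavities: background is flood-filled (6-neighbourhood) from
// every face of the volume; unreachable background becomes foreground.
// [[Rcpp::export(name = ".fill_holes_3d")]]
LogicalVector fill_holes_3d(LogicalVector mask, IntegerVector dim) {
  check_dim(mask, dim);
  Grid g(dim);
  std::vector<char> outside(g.n, 0);
  std::vector<R_xlen_t> stack;
  auto seed = [&](int x, int y, int z) {
    R_xlen_t v = g.idx(x, y, z);
    if (!mask[v] && !outside[v]) {
      outside[v] = 1;
      stack.push_back(v);
    }
  };
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y) {
      seed(0, y, z);
      seed(g.nx - 1, y, z);
    }
  for (int z = 0; z < g.nz; ++z)
    for (int x = 0; x < g.nx; ++x) {
      seed(x, 0, z);
      seed(x, g.ny - 1, z);
    }
  for (int y = 0; y < g.ny; ++y)
    for (int x = 0; x < g.nx; ++x) {
      seed(x, y, 0);
      seed(x, y, g.nz - 1);
    }
  const int step[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                          {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
  while (!stack.empty()) {
    R_xlen_t v = stack.back();
    stack.pop_back();
    int z = static_cast<int>(v / (static_cast<R_xlen_t>(g.nx) * g.ny));
    R_xlen_t rem = v - static_cast<R_xlen_t>(z) * g.nx * g.ny;
    int y = static_cast<int>(rem / g.nx);
    int x = static_cast<int>(rem % g.nx);
    for (int k = 0; k < 6; ++k) {
      int xx = x + step[k][0], yy = y + step[k][1], zz = z + step[k][2];
      if (xx < 0 || xx >= g.nx || yy < 0 || yy >= g.ny || zz < 0 || zz >= g.nz)
        continue;
      R_xlen_t w = g.idx(xx, yy, zz);
      if (!mask[w] && !outside[w]) {
        outside[w] = 1;
        stack.push_back(w);
      }
    }
  }
  LogicalVector out(g.n);
  for (R_xlen_t v = 0; v < g.n; ++v) out[v] = mask[v] || !outside[v];
  out.attr("dim") = dim;
  return out;
}

// Iterated 6-neighbourhood erosion; voxels outside the grid count as
// background, so the volume border erodes too.
// [[Rcpp::export(name = ".erode_3d")]]
LogicalVector erode_3d(LogicalVector mask, IntegerVector dim, int iterations) {
  check_dim(mask, dim);
  if (iterations < 0) stop("iterations must be >= 0");
  Grid g(dim);
  std::vector<char> cur(g.n), nxt(g.n);
  for (R_xlen_t v = 0; v < g.n; ++v) cur[v] = mask[v] ? 1 : 0;
  for (int it = 0; it < iterations; ++it) {
    for (int z = 0; z < g.nz; ++z)
      for (int y = 0; y < g.ny; ++y)
        for (int x = 0; x < g.nx; ++x) {
          R_xlen_t v = g.idx(x, y, z);
          char keep = cur[v];
          if (keep) {
            keep = x > 0 && cur[v - 1] && x < g.nx - 1 && cur[v + 1] &&
                   y > 0 && cur[v - g.nx] && y < g.ny - 1 && cur[v + g.nx] &&
                   z > 0 && cur[v - static_cast<R_xlen_t>(g.nx) * g.ny] &&
                   z < g.nz - 1 && cur[v + static_cast<R_xlen_t>(g.nx) * g.ny];
          }
          nxt[v] = keep;
        }
    cur.swap(nxt);
  }
  LogicalVector out(g.n);
  for (R_xlen_t v = 0; v < g.n; ++v) out[v] = cur[v] != 0;
  out.attr("dim") = dim;
  return out;
}
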
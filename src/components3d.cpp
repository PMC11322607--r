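#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path compression
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[rb] = ra;
}

// 26-connected component labelling of a 3D logical mask.
// `mask` is a logical array with dim = c(ny, nx, nz) (column-major).
// Returns an integer array of the same shape: 0 = background, components
// labelled 1..K in raster (column-major first-voxel) order.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  std::vector<int> parent(n);
  for (R_xlen_t i = 0; i < n; ++i) parent[i] = (int)i;

  auto idx = [&](int y, int x, int z) -> R_xlen_t {
    return (R_xlen_t)z * ny * nx + (R_xlen_t)x * ny + y;
  };

  // union each foreground voxel with already-visited foreground neighbours
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        R_xlen_t i = idx(y, x, z);
        if (!mask[i]) continue;
        for (int dz = -1; dz <= 0; ++dz) {
          for (int dx = -1; dx <= 1; ++dx) {
            for (int dy = -1; dy <= 1; ++dy) {
              if (dz == 0 && (dx > 0 || (dx == 0 && dy >= 0))) continue;
              int yy = y + dy, xx = x + dx, zz = z + dz;
              if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0) continue;
              R_xlen_t j = idx(yy, xx, zz);
              if (mask[j]) uf_union(parent, (int)i, (int)j);
            }
          }
        }
      }
    }
  }

  IntegerVector out(n, 0);
  std::vector<int> label(n, 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int r = uf_find(parent, (int)i);
    if (label[r] == 0) label[r] = ++next;
    out[i] = label[r];
  }
  out.attr("dim") = dims;
  return out;
}

// Linear sum assignment (Jonker-Volgenant shortest augmenting path) for a
// square cost matrix. Returns, for each row, the assigned column (1-based).
// O(n^3); costs must be finite.
// [[Rcpp::export(name = ".lsap_cpp")]]
IntegerVector lsap_cpp(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  // 1-based internal arrays per the classical formulation
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector match(n);
  for (int j = 1; j <= n; ++j) if (p[j] > 0) match[p[j] - 1] = j;
  return match;
}
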
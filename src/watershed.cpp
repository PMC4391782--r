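#include <Rcpp.h>
#include <queue>
#include <utility>
using namespace Rcpp;

// Marker-based watershed flooding (Meyer's algorithm) on a 3D scalar
// landscape with 6-connectivity. Deterministic: the flooding queue is
// ordered by (landscape value, linear voxel index) ascending, and a voxel's
// label is fixed at the moment it is first reached (first push wins). The
// pure-R brute-force oracle in the test suite replicates exactly these
// semantics.
//
// grad:    landscape values (gradient magnitude), length nx*ny*nz
// markers: integer labels, 0 = unlabeled
// mask:    logical, flooding restricted to TRUE voxels
// [[Rcpp::export(name = ".watershed_flood")]]
IntegerVector watershed_flood(NumericVector grad, IntegerVector markers,
                              LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (grad.size() != n || markers.size() != n || mask.size() != n)
    stop("dimension mismatch");

  IntegerVector label = clone(markers);
  std::vector<int> pending(n, 0);

  typedef std::pair<double, R_xlen_t> Entry;  // (value, index)
  std::priority_queue<Entry, std::vector<Entry>, std::greater<Entry> > pq;

  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  // push unlabeled masked neighbors of voxel v with pending label lab
  #define PUSH_NEIGHBORS(v)                                                 \
    {                                                                       \
      R_xlen_t x = (v) % nx, y = ((v) / nx) % ny, z = (v) / sz;             \
      R_xlen_t nb[6]; int cnt = 0;                                          \
      if (x > 0)      nb[cnt++] = (v) - sx;                                 \
      if (x < nx - 1) nb[cnt++] = (v) + sx;                                 \
      if (y > 0)      nb[cnt++] = (v) - sy;                                 \
      if (y < ny - 1) nb[cnt++] = (v) + sy;                                 \
      if (z > 0)      nb[cnt++] = (v) - sz;                                 \
      if (z < nz - 1) nb[cnt++] = (v) + sz;                                 \
      for (int k = 0; k < cnt; ++k) {                                       \
        R_xlen_t u = nb[k];                                                 \
        if (mask[u] && label[u] == 0 && pending[u] == 0) {                  \
          pending[u] = label[v];                                            \
          pq.push(Entry(grad[u], u));                                       \
        }                                                                   \
      }                                                                     \
    }

  for (R_xlen_t v = 0; v < n; ++v)
    if (label[v] != 0 && mask[v]) PUSH_NEIGHBORS(v)

  while (!pq.empty()) {
    R_xlen_t v = pq.top().second;
    pq.pop();
    if (label[v] != 0) continue;
    label[v] = pending[v];
    PUSH_NEIGHBORS(v)
  }
  #undef PUSH_NEIGHBORS

  return label;
}
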
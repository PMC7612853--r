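#include <Rcpp.h>
#include <array>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

static inline int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Connected-component labeling of a binary D-dimensional array (D <= 3,
// column-major) by union-find.  max_conn selects the full 3^D - 1
// neighbourhood (8-connectivity in 2D, 26 in 3D); otherwise only face
// neighbours are used (4 in 2D, 6 in 3D).  periodic identifies opposite
// faces (torus adjacency).  Labels are assigned 1..K in scan order of the
// first voxel of each component; background is 0.
//
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   bool max_conn, bool periodic) {
  const int D = dims.size();
  if (D < 1 || D > 3) stop("dims must have length 1..3");
  const int d0 = dims[0];
  const int d1 = D > 1 ? dims[1] : 1;
  const int d2 = D > 2 ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  if (mask.size() != n) stop("mask length does not match dims");

  // scan-preceding half of the neighbourhood
  std::vector<std::array<int, 3>> offs;
  const int lo1 = D > 1 ? -1 : 0, hi1 = D > 1 ? 1 : 0;
  const int lo2 = D > 2 ? -1 : 0, hi2 = D > 2 ? 1 : 0;
  for (int dz = lo2; dz <= hi2; ++dz)
    for (int dy = lo1; dy <= hi1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        bool preceding = (dz < 0) || (dz == 0 && (dy < 0 || (dy == 0 && dx < 0)));
        if (!preceding) continue;
        int nnz = (dx != 0) + (dy != 0) + (dz != 0);
        if (!max_conn && nnz > 1) continue;
        offs.push_back({dx, dy, dz});
      }

  std::vector<int> parent(n);
  for (R_xlen_t i = 0; i < n; ++i) parent[i] = (int)i;

  for (int z = 0; z < d2; ++z)
    for (int y = 0; y < d1; ++y)
      for (int x = 0; x < d0; ++x) {
        R_xlen_t i = x + (R_xlen_t)d0 * (y + (R_xlen_t)d1 * z);
        if (!mask[i]) continue;
        for (const auto &o : offs) {
          int nx = x + o[0], ny = y + o[1], nz = z + o[2];
          if (periodic) {
            nx = (nx + d0) % d0;
            ny = (ny + d1) % d1;
            nz = (nz + d2) % d2;
          } else if (nx < 0 || nx >= d0 || ny < 0 || ny >= d1 ||
                     nz < 0 || nz >= d2) {
            continue;
          }
          R_xlen_t j = nx + (R_xlen_t)d0 * (ny + (R_xlen_t)d1 * nz);
          if (!mask[j]) continue;
          int ri = find_root(parent, (int)i), rj = find_root(parent, (int)j);
          if (ri != rj) parent[ri > rj ? ri : rj] = ri > rj ? rj : ri;
        }
      }

  IntegerVector labels(n);
  std::unordered_map<int, int> root2lab;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) {
      labels[i] = 0;
      continue;
    }
    int r = find_root(parent, (int)i);
    auto it = root2lab.find(r);
    if (it == root2lab.end()) {
      root2lab.emplace(r, ++next);
      labels[i] = next;
    } else {
      labels[i] = it->second;
    }
  }
  return labels;
}
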
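#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Label 3D connected components among a set of foreground voxels.
//
// dim:  volume dimensions (3 ints)
// idx0: 0-based linear indices of foreground voxels (column-major)
// connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners)
//
// Returns an integer vector parallel to idx0 with component labels 1..K.
// Components are discovered by iterative depth-first search over a dense
// marker array, so labels are deterministic in scan order; callers re-rank
// by size for reporting.
// [[Rcpp::export]]
IntegerVector cc_label_3d(IntegerVector dim, IntegerVector idx0,
                          int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t nfg = idx0.size();

  // neighbour offsets in (dx, dy, dz)
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2))
          continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }

  // map linear index -> position in idx0 (+1), 0 = background
  std::vector<int> pos(nvox, 0);
  for (R_xlen_t i = 0; i < nfg; ++i) {
    R_xlen_t v = idx0[i];
    if (v < 0 || v >= nvox) stop("voxel index out of range");
    pos[v] = (int)(i + 1);
  }

  IntegerVector labels(nfg, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t i = 0; i < nfg; ++i) {
    if (labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    stack.push_back(idx0[i]);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < dxs.size(); ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        int pw = pos[w];
        if (pw == 0) continue;
        if (labels[pw - 1] == 0) {
          labels[pw - 1] = next_label;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}
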
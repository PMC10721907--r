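#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Connected components of the voxel graph given an edge list (1-based voxel
// indices).  Returns a component id per voxel (voxels with no edges keep a
// singleton id).
// [[Rcpp::export(name = ".uf_components")]]
IntegerVector uf_components(IntegerVector lo, IntegerVector hi, int n) {
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  R_xlen_t m = lo.size();
  for (R_xlen_t e = 0; e < m; ++e) {
    int a = uf_find(parent, lo[e] - 1), b = uf_find(parent, hi[e] - 1);
    if (a != b) parent[a] = b;
  }
  IntegerVector comp(n);
  for (int i = 0; i < n; ++i) comp[i] = uf_find(parent, i) + 1;
  return comp;
}
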
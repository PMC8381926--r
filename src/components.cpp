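#include <Rcpp.h>
#include <vector>

// 26-connectivity labelling of a 3-d logical mask. Labels are assigned in
// raster-scan order of each component's first voxel, starting at 1;
// background is 0.

// [[Rcpp::export(name = ".cc_label26")]]
Rcpp::IntegerVector cc_label26(Rcpp::LogicalVector mask,
                               Rcpp::IntegerVector dim) {
  if (dim.size() != 3) Rcpp::stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  if (mask.size() != ntot) Rcpp::stop("mask length does not match dim");

  Rcpp::IntegerVector labels(ntot, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t s = 0; s < ntot; ++s) {
    if (mask[s] != TRUE || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[w] == TRUE && labels[w] == 0) {
              labels[w] = next_label;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}
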
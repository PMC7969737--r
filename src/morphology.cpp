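#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling on a (nz, ny, nx) logical array stored in
// R column-major order (z fastest). connectivity: 6 (faces), 18 (faces +
// edges) or 26 (faces + edges + corners). Labels are assigned in order of
// first encounter along the linear scan, so they are contiguous from 1 and
// deterministic.
// [[Rcpp::export(name = ".label_cc")]]
IntegerVector label_cc(LogicalVector mask, IntegerVector dims,
                       int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> dz, dy, dx;
  for (int az = -1; az <= 1; ++az)
    for (int ay = -1; ay <= 1; ++ay)
      for (int ax = -1; ax <= 1; ++ax) {
        int s = std::abs(az) + std::abs(ay) + std::abs(ax);
        if (s == 0) continue;
        if ((connectivity == 6 && s > 1) || (connectivity == 18 && s > 2))
          continue;
        dz.push_back(az); dy.push_back(ay); dx.push_back(ax);
      }
  const int noff = (int)dz.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> queue;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i]) continue;
    ++next;
    labels[i] = next;
    queue.clear();
    queue.push_back(i);
    while (!queue.empty()) {
      R_xlen_t cur = queue.back();
      queue.pop_back();
      int z = (int)(cur % nz);
      int y = (int)((cur / nz) % ny);
      int x = (int)(cur / ((R_xlen_t)nz * ny));
      for (int k = 0; k < noff; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[j] && !labels[j]) {
          labels[j] = next;
          queue.push_back(j);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

static inline int at(const std::vector<int> &img, int nr, int r, int c) {
  return img[(size_t)r + (size_t)nr * c];
}

// Guo-Hall two-subiteration thinning of a 2D logical matrix down to a
// 1-pixel-wide, topology-preserving skeleton.
// [[Rcpp::export(name = ".guo_hall_thin")]]
LogicalMatrix guo_hall_thin(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> img((size_t)nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      img[(size_t)r + (size_t)nr * c] = mask(r, c) ? 1 : 0;

  std::vector<size_t> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!at(img, nr, r, c)) continue;
          // 8-neighbourhood, p2 = north, clockwise
          int p2 = (r > 0) ? at(img, nr, r - 1, c) : 0;
          int p3 = (r > 0 && c < nc - 1) ? at(img, nr, r - 1, c + 1) : 0;
          int p4 = (c < nc - 1) ? at(img, nr, r, c + 1) : 0;
          int p5 = (r < nr - 1 && c < nc - 1) ? at(img, nr, r + 1, c + 1) : 0;
          int p6 = (r < nr - 1) ? at(img, nr, r + 1, c) : 0;
          int p7 = (r < nr - 1 && c > 0) ? at(img, nr, r + 1, c - 1) : 0;
          int p8 = (c > 0) ? at(img, nr, r, c - 1) : 0;
          int p9 = (r > 0 && c > 0) ? at(img, nr, r - 1, c - 1) : 0;

          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = N1 < N2 ? N1 : N2;
          int m = (iter == 0) ? ((p6 | p7 | (!p9)) & p8)
                              : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && m == 0)
            kill.push_back((size_t)r + (size_t)nr * c);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t k = 0; k < kill.size(); ++k) img[kill[k]] = 0;
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = img[(size_t)r + (size_t)nr * c] != 0;
  return out;
}
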
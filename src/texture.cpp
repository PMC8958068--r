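// Gray-level texture matrix builders on 3D discretized ROIs.
// `levels` is a column-major integer array; 0 marks voxels outside the ROI,
// in-ROI voxels carry levels 1..ng. Directions are integer offsets, one per
// unique axis of the 26-neighborhood.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline bool inb(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}
static inline size_t idx3(int x, int y, int z, int nx, int ny) {
  return (size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z);
}

// co-occurrence counts at Chebyshev distance 1; each pair counted in both
// orders so every directional matrix is symmetric
// [[Rcpp::export]]
IntegerVector glcm_cpp(IntegerVector levels, IntegerVector dim, int ng,
                       IntegerMatrix dirs) {
  int nx = dim[0], ny = dim[1], nz = dim[2], nd = dirs.nrow();
  IntegerVector out((R_xlen_t)ng * ng * nd);
  for (int d = 0; d < nd; ++d) {
    int dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = levels[idx3(x, y, z, nx, ny)];
          if (a == 0) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (!inb(x2, y2, z2, nx, ny, nz)) continue;
          int b = levels[idx3(x2, y2, z2, nx, ny)];
          if (b == 0) continue;
          out[(a - 1) + ng * (size_t)((b - 1) + ng * (size_t)d)] += 1;
          out[(b - 1) + ng * (size_t)((a - 1) + ng * (size_t)d)] += 1;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, nd);
  return out;
}

// maximal same-level runs along each direction, clipped by the ROI boundary
// [[Rcpp::export]]
IntegerVector glrlm_cpp(IntegerVector levels, IntegerVector dim, int ng,
                        IntegerMatrix dirs) {
  int nx = dim[0], ny = dim[1], nz = dim[2], nd = dirs.nrow();
  int rmax = std::max(nx, std::max(ny, nz));
  IntegerVector out((R_xlen_t)ng * rmax * nd);
  for (int d = 0; d < nd; ++d) {
    int dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = levels[idx3(x, y, z, nx, ny)];
          if (a == 0) continue;
          // run starts here iff the backward neighbor is not part of a run
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (inb(xp, yp, zp, nx, ny, nz) && levels[idx3(xp, yp, zp, nx, ny)] == a)
            continue;
          int len = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (inb(xn, yn, zn, nx, ny, nz) && levels[idx3(xn, yn, zn, nx, ny)] == a) {
            ++len; xn += dx; yn += dy; zn += dz;
          }
          out[(a - 1) + ng * (size_t)((len - 1) + rmax * (size_t)d)] += 1;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, rmax, nd);
  return out;
}

// 26-connected zones of equal level
// [[Rcpp::export]]
IntegerMatrix glszm_cpp(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<char> seen(nvox, 0);
  std::vector<std::pair<int, int> > zones; // (level, size)
  std::vector<size_t> stack;
  int smax = 1;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i0 = idx3(x, y, z, nx, ny);
        int lev = levels[i0];
        if (lev == 0 || seen[i0]) continue;
        int size = 0;
        stack.clear();
        stack.push_back(i0);
        seen[i0] = 1;
        while (!stack.empty()) {
          size_t c = stack.back(); stack.pop_back();
          ++size;
          int cx = (int)(c % nx), cy = (int)((c / nx) % ny), cz = (int)(c / ((size_t)nx * ny));
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
                if (!inb(x2, y2, z2, nx, ny, nz)) continue;
                size_t i2 = idx3(x2, y2, z2, nx, ny);
                if (!seen[i2] && levels[i2] == lev) { seen[i2] = 1; stack.push_back(i2); }
              }
        }
        zones.push_back(std::make_pair(lev, size));
        if (size > smax) smax = size;
      }
  IntegerMatrix out(ng, smax);
  for (size_t k = 0; k < zones.size(); ++k)
    out(zones[k].first - 1, zones[k].second - 1) += 1;
  return out;
}

// label 26-connected components of a binary mask (0 = background);
// labels are 1..ncomp in first-encounter order
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  IntegerVector lab(nvox);
  std::vector<size_t> stack;
  int cur = 0;
  for (size_t i0 = 0; i0 < nvox; ++i0) {
    if (mask[i0] == 0 || lab[i0] != 0) continue;
    ++cur;
    stack.clear(); stack.push_back(i0); lab[i0] = cur;
    while (!stack.empty()) {
      size_t c = stack.back(); stack.pop_back();
      int cx = (int)(c % nx), cy = (int)((c / nx) % ny), cz = (int)(c / ((size_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
            if (!inb(x2, y2, z2, nx, ny, nz)) continue;
            size_t i2 = idx3(x2, y2, z2, nx, ny);
            if (mask[i2] != 0 && lab[i2] == 0) { lab[i2] = cur; stack.push_back(i2); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// dependence counts: in-ROI Chebyshev-1 neighbors with |level diff| <= alpha;
// column j stores dependence d = j - 1
// [[Rcpp::export]]
IntegerMatrix gldm_cpp(IntegerVector levels, IntegerVector dim, int ng, int alpha) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerMatrix out(ng, 27); // dependence 0..26
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (!inb(x2, y2, z2, nx, ny, nz)) continue;
              int b = levels[idx3(x2, y2, z2, nx, ny)];
              if (b != 0 && std::abs(a - b) <= alpha) ++dep;
            }
        out(a - 1, dep) += 1;
      }
  return out;
}

// per-level neighbor-difference sums: n_i (count of voxels of level i with
// at least one in-ROI neighbor) and s_i = sum |i - mean(in-ROI neighbors)|
// [[Rcpp::export]]
NumericMatrix ngtdm_cpp(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2); // col 0: n_i, col 1: s_i
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (!inb(x2, y2, z2, nx, ny, nz)) continue;
              int b = levels[idx3(x2, y2, z2, nx, ny)];
              if (b != 0) { sum += b; ++cnt; }
            }
        if (cnt > 0) {
          out(a - 1, 0) += 1;
          out(a - 1, 1) += std::fabs((double)a - sum / cnt);
        }
      }
  return out;
}
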
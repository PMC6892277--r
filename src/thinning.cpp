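#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Distance-ordered homotopic thinning: foreground voxels are visited in
// increasing order of their Euclidean distance to the background and removed
// when they are simple points (deletion preserves topology in the (26, 6)
// digital-topology sense) and not curve endpoints. The survivors form a
// one-voxel-wide centred medial curve.

namespace {

// offsets of the 26-neighbourhood, index = (dz+1) + 3*(dy+1) + 9*(dx+1)
inline int nbindex(int dz, int dy, int dx) {
  return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
}

// number of 26-connected components of the object voxels within the
// 26-neighbourhood (centre excluded)
int object_components(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  for (int s = 0; s < 27; s++) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    comps++;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top > 0) {
      int c = stack[--top];
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            int z2 = cz + dz, y2 = cy + dy, x2 = cx + dx;
            if (z2 < 0 || z2 > 2 || y2 < 0 || y2 > 2 || x2 < 0 || x2 > 2)
              continue;
            int j = z2 + 3 * y2 + 9 * x2;
            if (j == 13 || j == c || seen[j] || !nb[j]) continue;
            seen[j] = true;
            stack[top++] = j;
          }
    }
  }
  return comps;
}

// number of 6-connected components of background voxels within the
// 18-neighbourhood that touch a face neighbour of the centre
int background_components(const bool nb[27]) {
  // 18-neighbourhood: offsets with |dz|+|dy|+|dx| <= 2 (centre excluded)
  bool in18[27] = {false};
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m >= 1 && m <= 2) in18[nbindex(dz, dy, dx)] = true;
      }
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (std::abs(dz) + std::abs(dy) + std::abs(dx) != 1) continue;
        int s = nbindex(dz, dy, dx); // face neighbour
        if (nb[s] || seen[s]) continue;
        comps++;
        int top = 0;
        stack[top++] = s;
        seen[s] = true;
        while (top > 0) {
          int c = stack[--top];
          int cz = c % 3 - 1, cy = (c / 3) % 3 - 1, cx = c / 9 - 1;
          const int face[6][3] = {{-1, 0, 0}, {1, 0, 0},  {0, -1, 0},
                                  {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
          for (int f = 0; f < 6; f++) {
            int z2 = cz + face[f][0], y2 = cy + face[f][1], x2 = cx + face[f][2];
            if (z2 < -1 || z2 > 1 || y2 < -1 || y2 > 1 || x2 < -1 || x2 > 1)
              continue;
            int j = nbindex(z2, y2, x2);
            if (!in18[j] || seen[j] || nb[j]) continue;
            seen[j] = true;
            stack[top++] = j;
          }
        }
      }
  return comps;
}

inline bool is_simple(const bool nb[27]) {
  return object_components(nb) == 1 && background_components(nb) == 1;
}

struct QEntry {
  double d;
  R_xlen_t order;
  R_xlen_t idx;
};
struct QCompare {
  bool operator()(const QEntry &a, const QEntry &b) const {
    if (a.d != b.d) return a.d > b.d; // min-heap on distance
    return a.order > b.order;         // FIFO tie-break: deterministic
  }
};

} // namespace

//' @noRd
// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dims,
                              NumericVector edt) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n || edt.size() != n)
    stop("mask/edt length does not match dims");
  std::vector<char> m(mask.begin(), mask.end());

  std::priority_queue<QEntry, std::vector<QEntry>, QCompare> pq;
  R_xlen_t order = 0;
  for (R_xlen_t i = 0; i < n; i++)
    if (m[i]) pq.push({edt[i], order++, i});

  R_xlen_t stride_y = nz, stride_x = (R_xlen_t)nz * ny;
  bool nb[27];

  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    R_xlen_t i = e.idx;
    if (!m[i]) continue;
    int zc = (int)(i % nz);
    int yc = (int)((i / nz) % ny);
    int xc = (int)(i / stride_x);
    int count = 0;
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          int j = nbindex(dz, dy, dx);
          if (!dz && !dy && !dx) {
            nb[j] = true;
            continue;
          }
          int z2 = zc + dz, y2 = yc + dy, x2 = xc + dx;
          bool v = false;
          if (z2 >= 0 && z2 < nz && y2 >= 0 && y2 < ny && x2 >= 0 && x2 < nx)
            v = m[z2 + stride_y * y2 + stride_x * x2] != 0;
          nb[j] = v;
          if (v) count++;
        }
    if (count <= 1) continue; // endpoint or isolated voxel: keep
    if (!is_simple(nb)) continue;
    m[i] = 0;
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          if (!dz && !dy && !dx) continue;
          int z2 = zc + dz, y2 = yc + dy, x2 = xc + dx;
          if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
            continue;
          R_xlen_t j = z2 + stride_y * y2 + stride_x * x2;
          if (m[j]) pq.push({edt[j], order++, j});
        }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = m[i] != 0;
  out.attr("dim") = dims;
  return out;
}
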
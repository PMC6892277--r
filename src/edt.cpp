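#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable squared Euclidean distance transform (lower-envelope of
// parabolas), with propagation of the argmin seed index so the same pass
// structure yields both the distance map and the feature (nearest-seed)
// transform. BIG is finite so that differences of "infinite" parabola
// heights stay numerically exact for grids up to ~2^12 per side.
static const double BIG = 1e15;

static void dt1d(const std::vector<double> &f, const std::vector<int> &idin,
                 int n, std::vector<double> &d, std::vector<int> &idout,
                 std::vector<int> &v, std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k] && k > 0) {
        k--;
      } else {
        break;
      }
    }
    if (s <= z[k]) { // k == 0: replace
      v[0] = q;
      z[0] = -BIG;
      z[1] = BIG;
    } else {
      k++;
      v[k] = q;
      z[k] = s;
      z[k + 1] = BIG;
    }
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
    idout[q] = idin[v[k]];
  }
}

// run the three axis passes over a (nz, ny, nx) column-major volume where
// sq holds 0 at seeds and BIG elsewhere; id holds the 1-based linear index
// of the seed (or 0). On return sq is the squared distance to the nearest
// seed and id its index.
static void edt3d_core(std::vector<double> &sq, std::vector<int> &id, int nz,
                       int ny, int nx) {
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> idin(nmax), idout(nmax), v(nmax);

  // pass along z (fastest-varying)
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int q = 0; q < nz; q++) {
        f[q] = sq[base + q];
        idin[q] = id[base + q];
      }
      dt1d(f, idin, nz, d, idout, v, z);
      for (int q = 0; q < nz; q++) {
        sq[base + q] = d[q];
        id[base + q] = idout[q];
      }
    }
  // pass along y
  for (int x = 0; x < nx; x++)
    for (int zc = 0; zc < nz; zc++) {
      R_xlen_t base = zc + (R_xlen_t)nz * ny * x;
      for (int q = 0; q < ny; q++) {
        f[q] = sq[base + (R_xlen_t)nz * q];
        idin[q] = id[base + (R_xlen_t)nz * q];
      }
      dt1d(f, idin, ny, d, idout, v, z);
      for (int q = 0; q < ny; q++) {
        sq[base + (R_xlen_t)nz * q] = d[q];
        id[base + (R_xlen_t)nz * q] = idout[q];
      }
    }
  // pass along x
  for (int y = 0; y < ny; y++)
    for (int zc = 0; zc < nz; zc++) {
      R_xlen_t base = zc + (R_xlen_t)nz * y;
      R_xlen_t stride = (R_xlen_t)nz * ny;
      for (int q = 0; q < nx; q++) {
        f[q] = sq[base + stride * q];
        idin[q] = id[base + stride * q];
      }
      dt1d(f, idin, nx, d, idout, v, z);
      for (int q = 0; q < nx; q++) {
        sq[base + stride * q] = d[q];
        id[base + stride * q] = idout[q];
      }
    }
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<double> sq(n);
  std::vector<int> id(n, 0);
  bool any_bg = false;
  for (R_xlen_t i = 0; i < n; i++) {
    if (mask[i]) {
      sq[i] = BIG;
    } else {
      sq[i] = 0.0;
      id[i] = (int)(i + 1);
      any_bg = true;
    }
  }
  NumericVector out(n);
  if (!any_bg) {
    // no background anywhere: distance is unbounded; report a large value
    std::fill(out.begin(), out.end(), std::sqrt(BIG));
    out.attr("dim") = dims;
    return out;
  }
  edt3d_core(sq, id, nz, ny, nx);
  for (R_xlen_t i = 0; i < n; i++) out[i] = std::sqrt(sq[i]);
  out.attr("dim") = dims;
  return out;
}

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_nearest_seed(IntegerVector seed_idx, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (seed_idx.size() == 0) stop("no seed voxels supplied");
  std::vector<double> sq(n, BIG);
  std::vector<int> id(n, 0);
  for (R_xlen_t k = 0; k < seed_idx.size(); k++) {
    R_xlen_t i = (R_xlen_t)seed_idx[k] - 1;
    if (i < 0 || i >= n) stop("seed index out of range");
    sq[i] = 0.0;
    id[i] = seed_idx[k];
  }
  edt3d_core(sq, id, nz, ny, nx);
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = id[i];
  out.attr("dim") = dims;
  return out;
}

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || lab[i] != 0) continue;
    next++;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      int zc = (int)(c % nz);
      int yc = (int)((c / nz) % ny);
      int xc = (int)(c / ((R_xlen_t)nz * ny));
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (!dz && !dy && !dx) continue;
            int z2 = zc + dz, y2 = yc + dy, x2 = xc + dx;
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
              continue;
            R_xlen_t j = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  return lab;
}
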
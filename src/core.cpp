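#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cstdint>

using namespace Rcpp;

// arrays arrive as flat vectors in R's column-major layout with dims
// (z, y, x); index = z + nz * (y + ny * x), all 0-based here.

static inline int64_t idx3(int z, int y, int x, int nz, int ny) {
  return (int64_t)z + (int64_t)nz * ((int64_t)y + (int64_t)ny * (int64_t)x);
}

// 6-connected components of equal nonzero values.
// [[Rcpp::export(name = ".cc_labels_cpp")]]
IntegerVector cc_labels_cpp(IntegerVector labels, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int64_t n = (int64_t)nz * ny * nx;
  IntegerVector out(n);
  std::vector<int64_t> stack;
  int next_id = 0;
  const int dz[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, -1, 1};
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int64_t i = idx3(z, y, x, nz, ny);
        if (labels[i] == 0 || out[i] != 0) continue;
        int value = labels[i];
        int id = ++next_id;
        out[i] = id;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int64_t c = stack.back(); stack.pop_back();
          int cz = (int)(c % nz);
          int64_t rest = c / nz;
          int cy = (int)(rest % ny);
          int cx = (int)(rest / ny);
          for (int k = 0; k < 6; ++k) {
            int pz = cz + dz[k], py = cy + dy[k], px = cx + dx[k];
            if (pz < 0 || pz >= nz || py < 0 || py >= ny ||
                px < 0 || px >= nx) continue;
            int64_t p = idx3(pz, py, px, nz, ny);
            if (out[p] == 0 && labels[p] == value) {
              out[p] = id;
              stack.push_back(p);
            }
          }
        }
      }
  out.attr("dim") = dims;
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with sample
// spacing `s`; f is read/written in place through strided access.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb,
                 int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    while (true) {
      double xv = v[k] * s;
      double sep = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (sep <= zb[k]) { --k; continue; }
      ++k;
      v[k] = q;
      zb[k] = sep;
      zb[k + 1] = INF;
      break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (zb[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// anisotropy-aware squared Euclidean distance (nm^2) to the nearest
// background (mask == 0) voxel; voxels outside the mask get 0.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(IntegerVector mask, IntegerVector dims,
                         NumericVector voxel_size) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int64_t n = (int64_t)nz * ny * nx;
  // large finite stand-in for "no background reachable": keeps the 1D
  // transform's parabola arithmetic free of inf-inf NaNs
  const double LARGE = 1e30;
  NumericVector g(n);
  for (int64_t i = 0; i < n; ++i) g[i] = mask[i] ? LARGE : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> zb(nmax + 1);

  // axis z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = g[idx3(z, y, x, nz, ny)];
      dt1d(f, d, v, zb, nz, voxel_size[0]);
      for (int z = 0; z < nz; ++z) g[idx3(z, y, x, nz, ny)] = d[z];
    }
  // axis y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = g[idx3(z, y, x, nz, ny)];
      dt1d(f, d, v, zb, ny, voxel_size[1]);
      for (int y = 0; y < ny; ++y) g[idx3(z, y, x, nz, ny)] = d[y];
    }
  // axis x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = g[idx3(z, y, x, nz, ny)];
      dt1d(f, d, v, zb, nx, voxel_size[2]);
      for (int x = 0; x < nx; ++x) g[idx3(z, y, x, nz, ny)] = d[x];
    }
  for (int64_t i = 0; i < n; ++i) if (!mask[i]) g[i] = 0.0;
  g.attr("dim") = dims;
  return g;
}

struct QItem {
  double prio;      // DT value: flood from high to low
  int64_t order;    // insertion counter, for deterministic ties
  int64_t idx;
  int label;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.prio != b.prio) return a.prio < b.prio;  // max-heap on prio
    return a.order > b.order;                      // FIFO within ties
  }
};

// seeded watershed: flood the masked region from the seeds in order of
// decreasing distance-transform value (equivalently, ascending -DT).
// [[Rcpp::export(name = ".watershed_flood_cpp")]]
IntegerVector watershed_flood_cpp(NumericVector dt, IntegerVector mask,
                                  IntegerVector seeds, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int64_t n = (int64_t)nz * ny * nx;
  IntegerVector out(n);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  std::vector<char> queued(n, 0);
  int64_t counter = 0;

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int64_t i = idx3(z, y, x, nz, ny);
        if (seeds[i] > 0 && mask[i]) {
          pq.push({dt[i], counter++, i, seeds[i]});
          queued[i] = 1;
        }
      }

  const int dz[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, -1, 1};
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    if (out[it.idx] != 0) continue;
    out[it.idx] = it.label;
    int cz = (int)(it.idx % nz);
    int64_t rest = it.idx / nz;
    int cy = (int)(rest % ny);
    int cx = (int)(rest / ny);
    for (int k = 0; k < 6; ++k) {
      int pz = cz + dz[k], py = cy + dy[k], px = cx + dx[k];
      if (pz < 0 || pz >= nz || py < 0 || py >= ny ||
          px < 0 || px >= nx) continue;
      int64_t p = idx3(pz, py, px, nz, ny);
      if (!queued[p] && mask[p] && out[p] == 0) {
        pq.push({dt[p], counter++, p, it.label});
        queued[p] = 1;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
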
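#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Volumes are passed as numeric vectors with dim = c(nz, ny, nx), z fastest.

static inline int reflect(int i, int n) {
  // mirror boundary without repeating the edge sample; safe for any i
  if (n == 1) return 0;
  int period = 2 * n - 2;
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - i;
}

// [[Rcpp::export]]
NumericVector median_filter_3d_cpp(NumericVector vol, IntegerVector dim,
                                   int radius) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(vol.size());
  if (radius <= 0) {
    std::copy(vol.begin(), vol.end(), out.begin());
    return out;
  }
  std::vector<double> buf;
  buf.reserve((2 * radius + 1) * (2 * radius + 1) * (2 * radius + 1));
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        buf.clear();
        // neighbourhood truncated at the volume faces
        const int z0 = std::max(0, z - radius), z1 = std::min(nz - 1, z + radius);
        const int y0 = std::max(0, y - radius), y1 = std::min(ny - 1, y + radius);
        const int x0 = std::max(0, x - radius), x1 = std::min(nx - 1, x + radius);
        for (int xx = x0; xx <= x1; ++xx)
          for (int yy = y0; yy <= y1; ++yy)
            for (int zz = z0; zz <= z1; ++zz)
              buf.push_back(vol[zz + (size_t)nz * (yy + (size_t)ny * xx)]);
        const size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + m);
          med = 0.5 * (med + lo);
        }
        out[z + (size_t)nz * (y + (size_t)ny * x)] = med;
      }
    }
  }
  return out;
}

static void blur_axis(std::vector<double> &v, int nz, int ny, int nx,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &w : k) w /= s;
  const int n = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  std::vector<double> line(n);
  const size_t stride = (axis == 0) ? 1 : (axis == 1) ? (size_t)nz
                                                      : (size_t)nz * ny;
  // iterate over all lines along `axis`
  const int na = (axis == 0) ? ny : nz;
  const int nb = (axis == 2) ? ny : nx;
  for (int b = 0; b < nb; ++b) {
    for (int a = 0; a < na; ++a) {
      size_t base;
      if (axis == 0)       base = (size_t)nz * (a + (size_t)ny * b);
      else if (axis == 1)  base = a + (size_t)nz * ny * b;
      else                 base = a + (size_t)nz * b;
      for (int i = 0; i < n; ++i) line[i] = v[base + stride * i];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = -r; j <= r; ++j) acc += k[j + r] * line[reflect(i + j, n)];
        v[base + stride * i] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector gaussian_blur_3d_cpp(NumericVector vol, IntegerVector dim,
                                   NumericVector sigma) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  blur_axis(v, nz, ny, nx, 0, sigma[0]);
  blur_axis(v, nz, ny, nx, 1, sigma[1]);
  blur_axis(v, nz, ny, nx, 2, sigma[2]);
  return NumericVector(v.begin(), v.end());
}

// 26-connected component labelling of a logical mask.
// [[Rcpp::export]]
IntegerVector label_components_3d_cpp(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const size_t N = (size_t)nz * ny * nx;
  IntegerVector lab(N, 0);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t seed = 0; seed < N; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++next;
    lab[seed] = next;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int z = cur % nz, rem = cur / nz;
      int y = rem % ny, x = rem / ny;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            size_t q = zz + (size_t)nz * (yy + (size_t)ny * xx);
            if (mask[q] && lab[q] == 0) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
    }
  }
  return lab;
}

struct UnionFind {
  std::vector<int> parent;
  std::vector<double> peak;
  int find(int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  }
  int unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return a;
    parent[b] = a;
    peak[a] = std::max(peak[a], peak[b]);
    return a;
  }
};

// Watershed-style splitting of pre-labelled components along a blob response.
// Voxels are flooded in order of decreasing response; a fresh regional
// maximum opens a new region. Two regions meeting at a saddle are merged
// when the saddle depth below the shallower peak is at most `frac` times
// that peak's own height above the parent component's floor (`comp_min`),
// so frac = 1 never splits and frac = 0 splits at every regional maximum.
// [[Rcpp::export]]
IntegerVector watershed_split_cpp(NumericVector resp, IntegerVector comp,
                                  IntegerVector dim, NumericVector comp_min,
                                  double frac) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const size_t N = (size_t)nz * ny * nx;
  std::vector<size_t> order;
  for (size_t i = 0; i < N; ++i)
    if (comp[i] > 0) order.push_back(i);
  std::stable_sort(order.begin(), order.end(), [&](size_t a, size_t b) {
    return resp[a] > resp[b];
  });
  std::vector<int> lab(N, 0);
  UnionFind uf;
  uf.parent.push_back(0);  // region ids are 1-based
  uf.peak.push_back(0.0);
  std::vector<int> roots;
  for (size_t idx : order) {
    int z = idx % nz, rem = idx / nz;
    int y = rem % ny, x = rem / ny;
    roots.clear();
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (!dx && !dy && !dz) continue;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          size_t q = zz + (size_t)nz * (yy + (size_t)ny * xx);
          if (lab[q] > 0) {
            int r = uf.find(lab[q]);
            if (std::find(roots.begin(), roots.end(), r) == roots.end())
              roots.push_back(r);
          }
        }
    if (roots.empty()) {
      int id = (int)uf.parent.size();
      uf.parent.push_back(id);
      uf.peak.push_back(resp[idx]);
      lab[idx] = id;
    } else {
      // attach to the region with the highest peak; merge shallow neighbours
      int best = roots[0];
      for (int r : roots)
        if (uf.peak[r] > uf.peak[best]) best = r;
      double floorv = comp_min[comp[idx] - 1];
      for (int r : roots) {
        if (r == best) continue;
        double shallow = std::min(uf.peak[r], uf.peak[best]);
        double depth = shallow - resp[idx];
        if (depth <= frac * (shallow - floorv)) best = uf.unite(best, r);
      }
      lab[idx] = uf.find(best);
    }
  }
  // compress to consecutive labels
  std::vector<int> remap(uf.parent.size(), 0);
  int next = 0;
  IntegerVector out(N, 0);
  for (size_t i = 0; i < N; ++i) {
    if (lab[i] == 0) continue;
    int r = uf.find(lab[i]);
    if (remap[r] == 0) remap[r] = ++next;
    out[i] = remap[r];
  }
  return out;
}
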
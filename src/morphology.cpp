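// 3D grid primitives used by segmentation and landmark estimation:
// seeded region growing, boundary-connected background flood (hole filling),
// connected-component labelling and an anisotropic chamfer distance
// transform. All operate on R arrays in column-major order.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  Grid(const IntegerVector& dim) : nx(dim[0]), ny(dim[1]), nz(dim[2]) {}
  inline R_xlen_t idx(int x, int y, int z) const {
    return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
  }
  inline bool inside(int x, int y, int z) const {
    return x >= 0 && y >= 0 && z >= 0 && x < nx && y < ny && z < nz;
  }
};

// Neighbourhood offsets for 6- or 26-connectivity.
std::vector<std::array<int, 3>> offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m != 1) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

} // namespace

// [[Rcpp::export(name = ".region_grow_cpp")]]
LogicalVector region_grow_cpp(NumericVector values, IntegerVector dim,
                              IntegerVector seed, double hu_low,
                              double hu_high, int connectivity) {
  Grid g(dim);
  LogicalVector out(values.size(), false);
  auto off = offsets(connectivity);
  std::queue<std::array<int, 3>> q;
  R_xlen_t s = g.idx(seed[0], seed[1], seed[2]);
  out[s] = true;
  q.push({seed[0], seed[1], seed[2]});
  while (!q.empty()) {
    auto v = q.front();
    q.pop();
    for (const auto& d : off) {
      int x = v[0] + d[0], y = v[1] + d[1], z = v[2] + d[2];
      if (!g.inside(x, y, z)) continue;
      R_xlen_t i = g.idx(x, y, z);
      if (out[i]) continue;
      double hu = values[i];
      if (hu < hu_low || hu > hu_high) continue;
      out[i] = true;
      q.push({x, y, z});
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Flood the complement of `mask` from every boundary voxel (6-connectivity,
// the topological dual of 26-connected foreground); voxels never reached are
// enclosed cavities.
// [[Rcpp::export(name = ".fill_interior_cpp")]]
LogicalVector fill_interior_cpp(LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  std::vector<char> outside(mask.size(), 0);
  auto off = offsets(6);
  std::queue<std::array<int, 3>> q;
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        if (x > 0 && y > 0 && z > 0 && x < g.nx - 1 && y < g.ny - 1 &&
            z < g.nz - 1)
          continue;
        R_xlen_t i = g.idx(x, y, z);
        if (!mask[i] && !outside[i]) {
          outside[i] = 1;
          q.push({x, y, z});
        }
      }
  while (!q.empty()) {
    auto v = q.front();
    q.pop();
    for (const auto& d : off) {
      int x = v[0] + d[0], y = v[1] + d[1], z = v[2] + d[2];
      if (!g.inside(x, y, z)) continue;
      R_xlen_t i = g.idx(x, y, z);
      if (mask[i] || outside[i]) continue;
      outside[i] = 1;
      q.push({x, y, z});
    }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = mask[i] || !outside[i];
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  Grid g(dim);
  IntegerVector lab(mask.size(), 0);
  auto off = offsets(connectivity);
  int next = 0;
  std::queue<std::array<int, 3>> q;
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        R_xlen_t i0 = g.idx(x, y, z);
        if (!mask[i0] || lab[i0]) continue;
        lab[i0] = ++next;
        q.push({x, y, z});
        while (!q.empty()) {
          auto v = q.front();
          q.pop();
          for (const auto& d : off) {
            int xx = v[0] + d[0], yy = v[1] + d[1], zz = v[2] + d[2];
            if (!g.inside(xx, yy, zz)) continue;
            R_xlen_t i = g.idx(xx, yy, zz);
            if (!mask[i] || lab[i]) continue;
            lab[i] = next;
            q.push({xx, yy, zz});
          }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}

// Two-pass chamfer distance transform: distance (mm) from each foreground
// voxel to the nearest background voxel, with anisotropic neighbour weights
// equal to the Euclidean length of each 26-neighbourhood step.
// [[Rcpp::export(name = ".chamfer_dt_cpp")]]
NumericVector chamfer_dt_cpp(LogicalVector mask, IntegerVector dim,
                             NumericVector spacing) {
  Grid g(dim);
  const double INF = 1e30;
  NumericVector d(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) d[i] = mask[i] ? INF : 0.0;
  auto off = offsets(26);
  std::vector<double> w(off.size());
  for (size_t k = 0; k < off.size(); ++k) {
    double dx = off[k][0] * spacing[0], dy = off[k][1] * spacing[1],
           dz = off[k][2] * spacing[2];
    w[k] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  // forward pass: neighbours preceding in scan order; backward: the rest
  for (int pass = 0; pass < 2; ++pass) {
    bool fwd = pass == 0;
    int z0 = fwd ? 0 : g.nz - 1, z1 = fwd ? g.nz : -1, zs = fwd ? 1 : -1;
    for (int z = z0; z != z1; z += zs)
      for (int y = fwd ? 0 : g.ny - 1; fwd ? y < g.ny : y >= 0; y += zs)
        for (int x = fwd ? 0 : g.nx - 1; fwd ? x < g.nx : x >= 0; x += zs) {
          R_xlen_t i = g.idx(x, y, z);
          if (d[i] == 0.0) continue;
          double best = d[i];
          for (size_t k = 0; k < off.size(); ++k) {
            int ord = off[k][2] * 9 + off[k][1] * 3 + off[k][0];
            if (fwd ? ord >= 0 : ord <= 0) continue;
            int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
            if (!g.inside(xx, yy, zz)) continue;
            double cand = d[g.idx(xx, yy, zz)] + w[k];
            if (cand < best) best = cand;
          }
          d[i] = best;
        }
  }
  // voxels on the array border with no background anywhere keep INF; clamp
  // to distance to the grid edge so the argmax stays meaningful
  for (R_xlen_t i = 0; i < d.size(); ++i)
    if (d[i] >= INF) d[i] = INF;
  d.attr("dim") = dim;
  return d;
}
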
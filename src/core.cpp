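#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// 26-connected component labeling of a binary 3D array.
// Returns an integer array of the same shape: 0 for background, 1..n for
// components. Label values follow discovery order of a raster scan; the R
// wrapper re-orders lesions deterministically afterwards.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_26(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;

  // 26-neighbourhood offsets
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        if (dx || dy || dz) off.push_back({dx, dy, dz});

  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < off.size(); ++k) {
        int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t idx = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[idx] != 0 && lab[idx] == 0) {
          lab[idx] = next;
          stack.push_back(idx);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Isosurface mesher for binary volumes at iso-level 0.5.
//
// Per grid cell (cube of 8 voxel centers) the iso-contour is built on each of
// the six faces with marching squares; face-saddle configurations (diagonal
// foreground corners) are resolved by a fixed rule that separates the
// foreground corners. Because the rule depends only on the shared face values,
// the two cells adjacent to a face always produce identical face segments,
// which makes the mesh watertight by construction -- including the
// corner-/edge-touching voxel configurations that arise under 26-connectivity.
// Segments are stitched into closed loops per cell and fan-triangulated from
// the loop centroid, with winding chosen so that normals point away from the
// cell's foreground voxels.
//
// Vertex coordinates are in 0-based index space of the input array (crossing
// points lie on voxel-center lattice edges at midpoints); the R wrapper
// applies padding offsets and voxel spacing.
// ---------------------------------------------------------------------------

static inline int64_t vkey(double x, double y, double z) {
  // edge-midpoint coordinates are multiples of 0.5; key on doubled coords
  int64_t ix = (int64_t)std::llround(x * 2.0);
  int64_t iy = (int64_t)std::llround(y * 2.0);
  int64_t iz = (int64_t)std::llround(z * 2.0);
  return (ix * 1048576 + iy) * 1048576 + iz;
}

// [[Rcpp::export]]
List cpp_mesh_cells(IntegerVector vol, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto at = [&](int x, int y, int z) -> int {
    return vol[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x];
  };

  // cube corners (unit offsets); faces listed counter-clockwise as seen from
  // OUTSIDE the cube, so the directed face contours (foreground kept on the
  // left) orient consistently across the whole mesh
  static const int CORNER[8][3] = {{0,0,0},{1,0,0},{0,1,0},{1,1,0},
                                   {0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  static const int FACE[6][4] = {{0,2,3,1},{4,5,7,6},{0,1,5,4},
                                 {2,6,7,3},{0,4,6,2},{1,3,7,5}};

  std::unordered_map<int64_t, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> f1, f2, f3;

  auto add_vertex = [&](double x, double y, double z, bool dedup) -> int {
    if (dedup) {
      int64_t key = vkey(x, y, z);
      auto it = vmap.find(key);
      if (it != vmap.end()) return it->second;
      int id = (int)vx.size();
      vmap[key] = id;
      vx.push_back(x); vy.push_back(y); vz.push_back(z);
      return id;
    }
    int id = (int)vx.size();
    vx.push_back(x); vy.push_back(y); vz.push_back(z);
    return id;
  };

  struct Pt { double x, y, z; };

  for (int cz = 0; cz < nz - 1; ++cz)
    for (int cy = 0; cy < ny - 1; ++cy)
      for (int cx = 0; cx < nx - 1; ++cx) {
        bool ins[8];
        int nin = 0;
        for (int c = 0; c < 8; ++c) {
          ins[c] = at(cx + CORNER[c][0], cy + CORNER[c][1], cz + CORNER[c][2]) != 0;
          if (ins[c]) ++nin;
        }
        if (nin == 0 || nin == 8) continue;

        // collect DIRECTED face contour segments (endpoints are edge
        // midpoints): in each face's outward counter-clockwise frame the
        // segment runs from the foreground->background crossing to the
        // background->foreground crossing, keeping foreground on the left.
        // Saddles (diagonal foreground corners) are split so the foreground
        // corners are separated; the rule depends only on face values, so the
        // two cells sharing a face emit the same segment with opposite
        // directions and the global orientation is consistent.
        std::vector<std::pair<Pt, Pt>> segs;
        for (int f = 0; f < 6; ++f) {
          const int *fc = FACE[f];
          bool b[4];
          Pt p[4];
          for (int c = 0; c < 4; ++c) {
            b[c] = ins[fc[c]];
            p[c] = {(double)(cx + CORNER[fc[c]][0]),
                    (double)(cy + CORNER[fc[c]][1]),
                    (double)(cz + CORNER[fc[c]][2])};
          }
          auto mid = [&](int e) -> Pt {  // midpoint of face edge e -> e+1
            int a = e, bb = (e + 1) % 4;
            return {(p[a].x + p[bb].x) / 2.0,
                    (p[a].y + p[bb].y) / 2.0,
                    (p[a].z + p[bb].z) / 2.0};
          };
          int out_e[2], in_e[2], nout = 0, nin_ = 0;
          for (int e = 0; e < 4; ++e) {
            bool be = b[e], bn = b[(e + 1) % 4];
            if (be && !bn) out_e[nout++] = e;
            else if (!be && bn) in_e[nin_++] = e;
          }
          if (nout == 1) {
            segs.push_back({mid(out_e[0]), mid(in_e[0])});
          } else if (nout == 2) {
            // saddle: pair each foreground corner's outgoing crossing (c,c+1)
            // with its incoming crossing (c-1,c)
            for (int c = 0; c < 4; ++c) {
              if (!b[c]) continue;
              segs.push_back({mid(c), mid((c + 3) % 4)});
            }
          }
        }
        if (segs.empty()) continue;

        // chain directed segments into closed loops: within a cell every
        // crossing-edge midpoint has exactly one incoming and one outgoing
        // segment
        int m = (int)segs.size();
        std::vector<int64_t> ka(m), kb(m);
        std::unordered_map<int64_t, int> starts;  // start key -> seg id
        for (int s = 0; s < m; ++s) {
          ka[s] = vkey(segs[s].first.x, segs[s].first.y, segs[s].first.z);
          kb[s] = vkey(segs[s].second.x, segs[s].second.y, segs[s].second.z);
          starts[ka[s]] = s;
        }
        std::vector<bool> used(m, false);
        for (int s0 = 0; s0 < m; ++s0) {
          if (used[s0]) continue;
          std::vector<Pt> loop;
          int cur = s0;
          while (!used[cur]) {
            used[cur] = true;
            loop.push_back(segs[cur].first);
            auto it = starts.find(kb[cur]);
            if (it == starts.end()) break;  // defensive; cannot happen
            cur = it->second;
          }
          int L = (int)loop.size();
          if (L < 3) continue;

          double gx = 0, gy = 0, gz = 0;
          for (auto &q : loop) { gx += q.x; gy += q.y; gz += q.z; }
          gx /= L; gy /= L; gz /= L;

          int cen = add_vertex(gx, gy, gz, false);
          std::vector<int> ids(L);
          for (int t = 0; t < L; ++t)
            ids[t] = add_vertex(loop[t].x, loop[t].y, loop[t].z, true);
          for (int t = 0; t < L; ++t) {
            // (next, current, centroid): outward winding for the
            // foreground-on-the-left contour convention
            f1.push_back(ids[(t + 1) % L] + 1);
            f2.push_back(ids[t] + 1);
            f3.push_back(cen + 1);
          }
        }
      }

  int nv = (int)vx.size(), nf = (int)f1.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i];
  }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = f1[i]; F(i, 1) = f2[i]; F(i, 2) = f3[i];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Exact anisotropic Euclidean distance transform (squared-distance lower
// envelope, one separable pass per axis). Input: binary array marking the
// target structure; output: for every voxel, the Euclidean distance in mm to
// the nearest target voxel center, honoring per-axis spacing.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double> &f, double s) {
  const int n = (int)f.size();
  static const double INF = 1e20;
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    while (true) {
      double xv = v[k] * s;
      double sep = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (sep <= z[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        z[k] = sep;
        z[k + 1] = INF;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
  f = d;
}

// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector target, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = target[i] != 0 ? 0.0 : 1e20;

  std::vector<double> line;
  // x axis
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) line[x] = g[base + x];
      dt1d(line, spacing[0]);
      for (int x = 0; x < nx; ++x) g[base + x] = line[x];
    }
  // y axis
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) line[y] = g[base + (R_xlen_t)y * nx];
      dt1d(line, spacing[1]);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)y * nx] = line[y];
    }
  // z axis
  line.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) line[z] = g[base + (R_xlen_t)z * nx * ny];
      dt1d(line, spacing[2]);
      for (int z = 0; z < nz; ++z) g[base + (R_xlen_t)z * nx * ny] = line[z];
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Exact maximum pairwise distance between points (3D caliper diameter).
// Ties broken by the lexicographically smallest (i, j) index pair, which the
// scan order yields by only accepting strictly larger distances.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_max_pair(NumericMatrix pts) {
  const int n = pts.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pts(i, 0); y[i] = pts(i, 1); z[i] = pts(i, 2);
  }
  double best = -1.0;
  int bi = 1, bj = 1;
  for (int i = 0; i < n - 1; ++i) {
    const double xi = x[i], yi = y[i], zi = z[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[j] - xi, dy = y[j] - yi, dz = z[j] - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) {
        best = d2;
        bi = i + 1;
        bj = j + 1;
      }
    }
  }
  return List::create(_["length"] = std::sqrt(best < 0 ? 0.0 : best),
                      _["i"] = bi, _["j"] = bj);
}
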
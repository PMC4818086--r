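#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <utility>
#include <vector>
using namespace Rcpp;

// All volumes are R arrays with dim = (nz, ny, nx); the element (z, y, x)
// (0-based here) sits at linear index z + nz * (y + ny * x) because R arrays
// are column-major.  Every kernel below sticks to that convention.

static inline R_xlen_t lin(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// symmetric (mirror) boundary handling: -1 -> 0, n -> n-1, ...
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// one separable min/max pass along a single axis (axis: 0=z, 1=y, 2=x)
static void minmax_pass(const std::vector<double>& in, std::vector<double>& out,
                        int nz, int ny, int nx, int axis, int r, bool ismax) {
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        double best = ismax ? -1e300 : 1e300;
        for (int k = -r; k <= r; ++k) {
          int zz = z, yy = y, xx = x;
          if (axis == 0) zz = reflect(z + k, nz);
          else if (axis == 1) yy = reflect(y + k, ny);
          else xx = reflect(x + k, nx);
          double v = in[lin(zz, yy, xx, nz, ny)];
          if (ismax ? (v > best) : (v < best)) best = v;
        }
        out[lin(z, y, x, nz, ny)] = best;
      }
    }
  }
}

// kind: 0 = minimum, 1 = maximum, 2 = median, 3 = variance.
// radius = (rz, ry, rx): box half-widths per axis (box neighbourhood).
// [[Rcpp::export]]
NumericVector cpp_rank_filter(NumericVector vol, IntegerVector dim,
                              IntegerVector radius, int kind) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int rz = radius[0], ry = radius[1], rx = radius[2];
  std::vector<double> cur(vol.begin(), vol.end());

  if (kind == 0 || kind == 1) {
    // min/max over a box is separable
    std::vector<double> tmp(cur.size());
    if (rz > 0) { minmax_pass(cur, tmp, nz, ny, nx, 0, rz, kind == 1); cur.swap(tmp); }
    if (ry > 0) { minmax_pass(cur, tmp, nz, ny, nx, 1, ry, kind == 1); cur.swap(tmp); }
    if (rx > 0) { minmax_pass(cur, tmp, nz, ny, nx, 2, rx, kind == 1); cur.swap(tmp); }
    NumericVector out(cur.begin(), cur.end());
    return out;
  }

  NumericVector out(vol.size());
  const int nn = (2 * rz + 1) * (2 * ry + 1) * (2 * rx + 1);
  std::vector<double> buf(nn);
  // precomputed linear offsets for the interior fast path
  std::vector<R_xlen_t> off;
  off.reserve(nn);
  for (int dx = -rx; dx <= rx; ++dx)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dz = -rz; dz <= rz; ++dz)
        off.push_back(lin(dz, dy, dx, nz, ny));
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        int k = 0;
        if (z >= rz && z < nz - rz && y >= ry && y < ny - ry && x >= rx &&
            x < nx - rx) {
          R_xlen_t c = lin(z, y, x, nz, ny);
          for (int i = 0; i < nn; ++i) buf[i] = cur[c + off[i]];
          k = nn;
        } else {
          for (int dx = -rx; dx <= rx; ++dx) {
            int xx = reflect(x + dx, nx);
            for (int dy = -ry; dy <= ry; ++dy) {
              int yy = reflect(y + dy, ny);
              for (int dz = -rz; dz <= rz; ++dz) {
                buf[k++] = cur[lin(reflect(z + dz, nz), yy, xx, nz, ny)];
              }
            }
          }
        }
        if (kind == 2) {
          // constant neighbourhoods (most of a sparse stack) skip the
          // selection entirely
          bool flat = true;
          for (int i = 1; i < nn; ++i) {
            if (buf[i] != buf[0]) { flat = false; break; }
          }
          if (flat) {
            out[lin(z, y, x, nz, ny)] = buf[0];
          } else {
            std::nth_element(buf.begin(), buf.begin() + nn / 2, buf.end());
            out[lin(z, y, x, nz, ny)] = buf[nn / 2];
          }
        } else {
          double s = 0, s2 = 0;
          for (int i = 0; i < nn; ++i) { s += buf[i]; s2 += buf[i] * buf[i]; }
          double m = s / nn;
          double v = s2 / nn - m * m;
          out[lin(z, y, x, nz, ny)] = v > 0 ? v : 0;
        }
      }
    }
  }
  return out;
}

static void conv_pass(const std::vector<double>& in, std::vector<double>& out,
                      int nz, int ny, int nx, int axis,
                      const std::vector<double>& ker) {
  int r = ((int)ker.size() - 1) / 2;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        double acc = 0;
        for (int k = -r; k <= r; ++k) {
          int zz = z, yy = y, xx = x;
          if (axis == 0) zz = reflect(z + k, nz);
          else if (axis == 1) yy = reflect(y + k, ny);
          else xx = reflect(x + k, nx);
          acc += ker[k + r] * in[lin(zz, yy, xx, nz, ny)];
        }
        out[lin(z, y, x, nz, ny)] = acc;
      }
    }
  }
}

// separable convolution with mirrored edges; a length-1 kernel skips its pass
// [[Rcpp::export]]
NumericVector cpp_convolve_sep(NumericVector vol, IntegerVector dim,
                               NumericVector kz, NumericVector ky,
                               NumericVector kx) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> cur(vol.begin(), vol.end()), tmp(cur.size());
  std::vector<double> vkz(kz.begin(), kz.end()), vky(ky.begin(), ky.end()),
      vkx(kx.begin(), kx.end());
  if (vkz.size() > 1) { conv_pass(cur, tmp, nz, ny, nx, 0, vkz); cur.swap(tmp); }
  if (vky.size() > 1) { conv_pass(cur, tmp, nz, ny, nx, 1, vky); cur.swap(tmp); }
  if (vkx.size() > 1) { conv_pass(cur, tmp, nz, ny, nx, 2, vkx); cur.swap(tmp); }
  return NumericVector(cur.begin(), cur.end());
}

// connected-component labeling; connectivity 26 or 6; labels are in scan
// order of first encounter (the R side renumbers by component size)
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> offz, offy, offx;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int man = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && man != 1) continue;
        offz.push_back(dz); offy.push_back(dy); offx.push_back(dx);
      }
  const int noff = (int)offz.size();
  IntegerVector lab(mask.size(), 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        R_xlen_t idx = lin(z, y, x, nz, ny);
        if (!mask[idx] || lab[idx]) continue;
        ++next;
        lab[idx] = next;
        stack.clear();
        stack.push_back(idx);
        while (!stack.empty()) {
          R_xlen_t c = stack.back();
          stack.pop_back();
          int cx = (int)(c / ((R_xlen_t)nz * ny));
          int rem = (int)(c % ((R_xlen_t)nz * ny));
          int cy = rem / nz, cz = rem % nz;
          for (int o = 0; o < noff; ++o) {
            int zz = cz + offz[o], yy = cy + offy[o], xx = cx + offx[o];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            R_xlen_t j = lin(zz, yy, xx, nz, ny);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
    }
  }
  return lab;
}

// mark a Chebyshev dilation (box radius r) of the given 1-based voxel
// coordinates into a logical occupancy grid, in place
// [[Rcpp::export]]
LogicalVector cpp_mark_dilated(LogicalVector occ, IntegerVector dim,
                               IntegerMatrix coords, int r) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  for (int i = 0; i < coords.nrow(); ++i) {
    int z0 = coords(i, 0) - 1, y0 = coords(i, 1) - 1, x0 = coords(i, 2) - 1;
    for (int dx = -r; dx <= r; ++dx) {
      int xx = x0 + dx; if (xx < 0 || xx >= nx) continue;
      for (int dy = -r; dy <= r; ++dy) {
        int yy = y0 + dy; if (yy < 0 || yy >= ny) continue;
        for (int dz = -r; dz <= r; ++dz) {
          int zz = z0 + dz; if (zz < 0 || zz >= nz) continue;
          occ[lin(zz, yy, xx, nz, ny)] = true;
        }
      }
    }
  }
  return occ;
}

// number of 26-connected components among the foreground cells of a 3x3x3
// neighbourhood (center excluded); nb index = z + 3*y + 9*x, z/y/x in 0..2
static int fg_components_26(const unsigned char* nb) {
  bool seen[27] = {false};
  int ncomp = 0, stack[27];
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++ncomp;
    int sp = 0;
    stack[sp++] = i;
    seen[i] = true;
    while (sp) {
      int c = stack[--sp];
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int j = 0; j < 27; ++j) {
        if (j == 13 || !nb[j] || seen[j]) continue;
        int jz = j % 3, jy = (j / 3) % 3, jx = j / 9;
        if (std::abs(jz - cz) <= 1 && std::abs(jy - cy) <= 1 &&
            std::abs(jx - cx) <= 1) {
          seen[j] = true;
          stack[sp++] = j;
        }
      }
    }
  }
  return ncomp;
}

// number of 6-connected components of background cells within the
// 18-neighbourhood that touch a face neighbour of the center (the classic
// (26, 6) simple-point background condition)
static int bg_components_6(const unsigned char* nb) {
  // N18 = cells with Manhattan offset 1 or 2 (corners excluded)
  bool in18[27], seen[27] = {false};
  for (int i = 0; i < 27; ++i) {
    int z = i % 3, y = (i / 3) % 3, x = i / 9;
    int man = std::abs(z - 1) + std::abs(y - 1) + std::abs(x - 1);
    in18[i] = (man == 1 || man == 2);
  }
  int ncomp = 0, stack[27];
  for (int i = 0; i < 27; ++i) {
    if (!in18[i] || nb[i] || seen[i]) continue;
    int z = i % 3, y = (i / 3) % 3, x = i / 9;
    if (std::abs(z - 1) + std::abs(y - 1) + std::abs(x - 1) != 1) continue;
    // start BFS only from face neighbours so each counted component is
    // 6-adjacent to the center
    ++ncomp;
    int sp = 0;
    stack[sp++] = i;
    seen[i] = true;
    while (sp) {
      int c = stack[--sp];
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int j = 0; j < 27; ++j) {
        if (!in18[j] || nb[j] || seen[j]) continue;
        int jz = j % 3, jy = (j / 3) % 3, jx = j / 9;
        if (std::abs(jz - cz) + std::abs(jy - cy) + std::abs(jx - cx) == 1) {
          seen[j] = true;
          stack[sp++] = j;
        }
      }
    }
  }
  return ncomp;
}

// Topology-preserving curve thinning.  A foreground voxel may be deleted
// when (a) it is a border voxel in the current sweep direction, (b) it has
// at least two 26-neighbours (curve endpoints are preserved), and (c) it is
// a (26, 6) simple point: its foreground 26-neighbours form one 26-connected
// component and the background within its 18-neighbourhood forms one
// 6-connected component touching a face — so deletion can never split or
// remove a component, nor open a tunnel.  Six directional sub-iterations
// with sequential re-checking are repeated until stable, which keeps the
// skeleton centred; solids collapse to their medial curves via rim erosion.
// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<unsigned char> img(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) img[i] = mask[i] ? 1 : 0;

  auto at = [&](int z, int y, int x) -> unsigned char {
    if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) return 0;
    return img[lin(z, y, x, nz, ny)];
  };
  auto deletable = [&](int z, int y, int x) -> bool {
    unsigned char nb[27];
    int cnt = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int i = (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
          nb[i] = at(z + dz, y + dy, x + dx);
          if (i != 13) cnt += nb[i];
        }
    if (cnt < 2) return false;  // endpoint or isolated voxel: keep
    return fg_components_26(nb) == 1 && bg_components_6(nb) == 1;
  };

  const int dirs[6][3] = {{-1, 0, 0}, {1, 0, 0},  {0, -1, 0},
                          {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            R_xlen_t idx = lin(z, y, x, nz, ny);
            if (!img[idx]) continue;
            if (at(z + dirs[d][0], y + dirs[d][1], x + dirs[d][2])) continue;
            if (deletable(z, y, x)) cand.push_back(idx);
          }
      for (R_xlen_t idx : cand) {
        int x = (int)(idx / ((R_xlen_t)nz * ny));
        int rem = (int)(idx % ((R_xlen_t)nz * ny));
        int y = rem / nz, z = rem % nz;
        if (deletable(z, y, x)) {
          img[idx] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = img[i] != 0;
  return out;
}

// multi-source Dijkstra over the foreground 26-neighbourhood graph with
// Euclidean step weights (1, sqrt 2, sqrt 3); `sources` are 1-based linear
// indices.  Returns geodesic distances (-1 unreachable) and 1-based
// shortest-path-tree parents (0 for sources/unreached), for centreline
// extraction.  Euclidean weights keep paths straight: hop-count-shortest
// paths zigzag diagonally, inflating lengths and folding onto themselves.
// [[Rcpp::export]]
List cpp_geodesic_dijkstra(LogicalVector mask, IntegerVector dim,
                           IntegerVector sources) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector dist(mask.size(), -1.0);
  IntegerVector parent(mask.size(), 0);
  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int i = 0; i < sources.size(); ++i) {
    R_xlen_t s = sources[i] - 1;
    if (s >= 0 && s < mask.size() && mask[s]) {
      dist[s] = 0.0;
      pq.push(QE(0.0, s));
    }
  }
  static const double wlen[4] = {0.0, 1.0, 1.4142135623730951,
                                 1.7320508075688772};
  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    R_xlen_t c = top.second;
    if (top.first > dist[c] + 1e-12) continue;
    int cx = (int)(c / ((R_xlen_t)nz * ny));
    int rem = (int)(c % ((R_xlen_t)nz * ny));
    int cy = rem / nz, cz = rem % nz;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (!dx && !dy && !dz) continue;
          int zz = cz + dz, yy = cy + dy, xx = cx + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
              xx >= nx)
            continue;
          R_xlen_t j = lin(zz, yy, xx, nz, ny);
          if (!mask[j]) continue;
          double nd = dist[c] +
            wlen[std::abs(dx) + std::abs(dy) + std::abs(dz)];
          if (dist[j] < 0 || nd < dist[j] - 1e-12) {
            dist[j] = nd;
            parent[j] = (int)(c + 1);
            pq.push(QE(nd, j));
          }
        }
  }
  return List::create(Named("dist") = dist, Named("parent") = parent);
}
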
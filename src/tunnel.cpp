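// grid clearance fill and maximin (widest-path) tunnel search
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// per-voxel clearance: min over atoms of (distance to atom center - vdw radius);
// negative inside an atom. Voxel centers: origin + index * spacing (0-based).
// [[Rcpp::export]]
NumericVector clearance_grid_cpp(NumericMatrix coords, NumericVector radii,
                                 NumericVector origin, double spacing,
                                 IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nv = (R_xlen_t)nx * ny * nz;
  NumericVector out(nv, R_PosInf);
  const int na = coords.nrow();
  for (int a = 0; a < na; ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    const double r = radii[a];
    R_xlen_t id = 0;
    for (int k = 0; k < nz; ++k) {
      const double dz = origin[2] + k * spacing - az;
      const double dz2 = dz * dz;
      for (int j = 0; j < ny; ++j) {
        const double dy = origin[1] + j * spacing - ay;
        const double dyz = dy * dy + dz2;
        for (int i = 0; i < nx; ++i, ++id) {
          const double dx = origin[0] + i * spacing - ax;
          const double c = std::sqrt(dx * dx + dyz) - r;
          if (c < out[id]) out[id] = c;
        }
      }
    }
  }
  return out;
}

static inline bool on_boundary(int i, int j, int k, int nx, int ny, int nz) {
  return i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 || k == nz - 1;
}

// maximin path from seed voxel to any grid-boundary voxel over 6-connected
// voxels with clearance >= probe. Stage 1: best-first expansion in decreasing
// path-width order; the first boundary voxel popped fixes the optimal
// bottleneck b*. Stage 2: BFS on the subgraph {clearance >= b*} gives the
// shortest such path; exit ties broken by smallest linear index, backtracking
// picks the smallest-index predecessor.
// [[Rcpp::export]]
List widest_path_cpp(NumericVector clearance, IntegerVector dims,
                     int seed_idx, double probe) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nv = (R_xlen_t)nx * ny * nz;
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};

  if (clearance[seed_idx] < probe)
    return List::create(_["found"] = false, _["reason"] = "seed_blocked");

  // stage 1: widest path (Dijkstra with max-min objective)
  std::vector<double> width(nv, -1.0);
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node> pq;
  width[seed_idx] = clearance[seed_idx];
  pq.push(Node(width[seed_idx], seed_idx));
  double bottleneck = -1.0;
  std::vector<char> done(nv, 0);
  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    R_xlen_t u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    const int ui = u % nx, uj = (u / nx) % ny, uk = u / ((R_xlen_t)nx * ny);
    if (on_boundary(ui, uj, uk, nx, ny, nz)) { bottleneck = top.first; break; }
    for (int d = 0; d < 6; ++d) {
      const int vi = ui + dx[d], vj = uj + dy[d], vk = uk + dz[d];
      if (vi < 0 || vj < 0 || vk < 0 || vi >= nx || vj >= ny || vk >= nz) continue;
      const R_xlen_t v = vi + (R_xlen_t)nx * (vj + (R_xlen_t)ny * vk);
      if (done[v] || clearance[v] < probe) continue;
      const double w = std::min(top.first, clearance[v]);
      if (w > width[v]) { width[v] = w; pq.push(Node(w, v)); }
    }
  }
  if (bottleneck < 0)
    return List::create(_["found"] = false, _["reason"] = "no_path");

  // stage 2: BFS on {clearance >= bottleneck}
  const double thr = bottleneck - 1e-12;
  std::vector<int> dist(nv, -1);
  std::queue<R_xlen_t> q;
  dist[seed_idx] = 0;
  q.push(seed_idx);
  R_xlen_t exit_idx = -1;
  int exit_dist = -1;
  {
    const int si = seed_idx % nx, sj = (seed_idx / nx) % ny,
              sk = seed_idx / ((R_xlen_t)nx * ny);
    if (on_boundary(si, sj, sk, nx, ny, nz)) { exit_idx = seed_idx; exit_dist = 0; }
  }
  while (!q.empty() && exit_idx < 0) {
    // process whole BFS level so the smallest-index boundary voxel at the
    // first reachable depth wins
    size_t level = q.size();
    R_xlen_t best = -1;
    for (size_t s = 0; s < level; ++s) {
      R_xlen_t u = q.front(); q.pop();
      const int ui = u % nx, uj = (u / nx) % ny, uk = u / ((R_xlen_t)nx * ny);
      for (int d = 0; d < 6; ++d) {
        const int vi = ui + dx[d], vj = uj + dy[d], vk = uk + dz[d];
        if (vi < 0 || vj < 0 || vk < 0 || vi >= nx || vj >= ny || vk >= nz) continue;
        const R_xlen_t v = vi + (R_xlen_t)nx * (vj + (R_xlen_t)ny * vk);
        if (dist[v] >= 0 || clearance[v] < thr) continue;
        dist[v] = dist[u] + 1;
        if (on_boundary(vi, vj, vk, nx, ny, nz) && (best < 0 || v < best))
          best = v;
        q.push(v);
      }
    }
    if (best >= 0) { exit_idx = best; exit_dist = dist[best]; }
  }
  if (exit_idx < 0)  // cannot happen: stage 1 reached a boundary
    return List::create(_["found"] = false, _["reason"] = "no_path");

  // backtrack, preferring smallest linear index at each step
  std::vector<R_xlen_t> path;
  R_xlen_t cur = exit_idx;
  path.push_back(cur);
  while (dist[cur] > 0) {
    const int ui = cur % nx, uj = (cur / nx) % ny, uk = cur / ((R_xlen_t)nx * ny);
    R_xlen_t pick = -1;
    for (int d = 0; d < 6; ++d) {
      const int vi = ui + dx[d], vj = uj + dy[d], vk = uk + dz[d];
      if (vi < 0 || vj < 0 || vk < 0 || vi >= nx || vj >= ny || vk >= nz) continue;
      const R_xlen_t v = vi + (R_xlen_t)nx * (vj + (R_xlen_t)ny * vk);
      if (dist[v] == dist[cur] - 1 && (pick < 0 || v < pick)) pick = v;
    }
    cur = pick;
    path.push_back(cur);
  }
  std::reverse(path.begin(), path.end());
  IntegerVector pout(path.size());
  for (size_t s = 0; s < path.size(); ++s) pout[s] = (int)path[s];
  (void)exit_dist;
  return List::create(_["found"] = true, _["bottleneck"] = bottleneck,
                      _["path"] = pout);
}
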
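// Compiled kernels: exact Euclidean distance transform, cell-list nearest-bead
// search, lattice union-find, anchored self-avoiding-walk growth, excluded-volume
// crankshaft relaxation, inter-chain contact detection, the explicit-Euler
// Smoluchowski first-passage stepper and overdamped Brownian-dynamics oracles.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double BIG = 1e30;

// ---------------------------------------------------------------------------
// 1D squared-distance transform (lower envelope of parabolas), sample spacing s.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb, int n, double s) {
  if (n == 1) { d[0] = f[0]; return; }
  int k = 0;
  v[0] = 0; zb[0] = -BIG; zb[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * s, sp = 0.0;
    while (true) {
      double xv = v[k] * s;
      sp = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (k > 0 && sp <= zb[k]) { --k; } else break;
    }
    ++k; v[k] = q; zb[k] = sp; zb[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (zb[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = f[v[k]] + (xq - xv) * (xq - xv);
  }
}

// Squared distance (center-to-center, anisotropic spacing) from every voxel to
// the nearest voxel where mask is TRUE.  BIG where no TRUE voxel exists.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : BIG;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)(k * ny + j) * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, v, zb, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * ny * nx + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, v, zb, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  R_xlen_t slab = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * slab];
      dt1d(f, d, v, zb, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * slab] = d[k];
    }
  for (R_xlen_t i = 0; i < n; ++i) if (out[i] > BIG / 2) out[i] = BIG;
  return out;
}

// ---------------------------------------------------------------------------
// Cell-linked list over scattered points.
struct CellList {
  double ox, oy, oz, c;
  int nx, ny, nz;
  std::vector<int> head, nxt;
  std::vector<double> X, Y, Z;
  int M;

  void build(const NumericMatrix& coords, double cell) {
    M = coords.nrow();
    c = cell;
    X.resize(M); Y.resize(M); Z.resize(M);
    double lox = BIG, loy = BIG, loz = BIG, hix = -BIG, hiy = -BIG, hiz = -BIG;
    for (int m = 0; m < M; ++m) {
      X[m] = coords(m, 0); Y[m] = coords(m, 1); Z[m] = coords(m, 2);
      lox = std::min(lox, X[m]); hix = std::max(hix, X[m]);
      loy = std::min(loy, Y[m]); hiy = std::max(hiy, Y[m]);
      loz = std::min(loz, Z[m]); hiz = std::max(hiz, Z[m]);
    }
    if (M == 0) { lox = loy = loz = 0; hix = hiy = hiz = 0; }
    ox = lox - 0.5 * c; oy = loy - 0.5 * c; oz = loz - 0.5 * c;
    nx = std::max(1, (int)std::floor((hix - ox) / c) + 1);
    ny = std::max(1, (int)std::floor((hiy - oy) / c) + 1);
    nz = std::max(1, (int)std::floor((hiz - oz) / c) + 1);
    head.assign((size_t)nx * ny * nz, -1);
    nxt.assign(M, -1);
    for (int m = 0; m < M; ++m) {
      int i = (int)std::floor((X[m] - ox) / c);
      int j = (int)std::floor((Y[m] - oy) / c);
      int k = (int)std::floor((Z[m] - oz) / c);
      size_t idx = ((size_t)k * ny + j) * nx + i;
      nxt[m] = head[idx]; head[idx] = m;
    }
  }

  // Nearest squared distance from p to any point; search pruned once no ring
  // can beat the current best or the caller-supplied cap.
  double nearest_sq(double px, double py, double pz, double cap) const {
    if (M == 0) return BIG;
    int ci = (int)std::floor((px - ox) / c);
    int cj = (int)std::floor((py - oy) / c);
    int ck = (int)std::floor((pz - oz) / c);
    double best = BIG;
    int kmax = std::max(nx, std::max(ny, nz)) +
               std::max(std::max(std::abs(ci), std::abs(cj)), std::abs(ck)) + 2;
    for (int ring = 0; ring <= kmax; ++ring) {
      double ringmin = (ring - 1) * c;  // min distance from p to any cell in this ring
      if (ringmin > 0) {
        double lim = std::min(cap, best < BIG ? std::sqrt(best) : BIG);
        if (ringmin > lim) break;
      }
      for (int dk = -ring; dk <= ring; ++dk) {
        int k = ck + dk; if (k < 0 || k >= nz) continue;
        for (int dj = -ring; dj <= ring; ++dj) {
          int j = cj + dj; if (j < 0 || j >= ny) continue;
          bool edge_kj = (std::abs(dk) == ring) || (std::abs(dj) == ring);
          int step = edge_kj ? 1 : 2 * ring;
          if (step <= 0) step = 1;
          for (int di = -ring; di <= ring; di += step) {
            int i = ci + di; if (i < 0 || i >= nx) continue;
            int m = head[((size_t)k * ny + j) * nx + i];
            while (m >= 0) {
              double dx = X[m] - px, dy = Y[m] - py, dz = Z[m] - pz;
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best) best = d2;
              m = nxt[m];
            }
          }
        }
      }
    }
    return best;
  }

  bool any_within(double px, double py, double pz, double r) const {
    if (M == 0) return false;
    double d2 = nearest_sq(px, py, pz, r + c);
    return d2 <= r * r;
  }
};

// Distance from every voxel center to the nearest bead surface (center distance
// minus bead_radius; may be negative inside a bead).  cap[i]: once the bead
// center distance provably exceeds cap[i] + bead_radius the voxel keeps BIG
// (an upper bound supplied by the exclusion-grid distance; the combined
// min(d_bead, d_excl) is unaffected).  Pass a single BIG cap for exact maps.
// [[Rcpp::export]]
NumericVector cpp_rmax_bead(NumericMatrix coords, double bead_radius,
                            NumericVector origin, NumericVector spacing,
                            IntegerVector dim, NumericVector cap, double cell) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  if (coords.nrow() == 0) {
    for (R_xlen_t i = 0; i < n; ++i) out[i] = BIG;
    return out;
  }
  CellList cl; cl.build(coords, cell);
  bool scalar_cap = (cap.size() == 1);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double pz = origin[2] + (k + 0.5) * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double py = origin[1] + (j + 0.5) * spacing[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        double px = origin[0] + (i + 0.5) * spacing[0];
        double cp = scalar_cap ? cap[0] : cap[idx];
        double d2 = cl.nearest_sq(px, py, pz, cp + bead_radius);
        out[idx] = (d2 >= BIG / 2) ? BIG : std::sqrt(d2) - bead_radius;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Union-find with path compression over an accessibility lattice.
struct UF {
  std::vector<int> parent, sz;
  void init(R_xlen_t n) { parent.resize(n); sz.assign(n, 1);
    for (R_xlen_t i = 0; i < n; ++i) parent[i] = (int)i; }
  int find(int a) {
    int root = a;
    while (parent[root] != root) root = parent[root];
    while (parent[a] != root) { int nx_ = parent[a]; parent[a] = root; a = nx_; }
    return root;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (sz[a] < sz[b]) std::swap(a, b);
    parent[b] = a; sz[a] += sz[b];
  }
};

// Labels: 0 for inaccessible voxels, 1..K for components (first-touch order).
// connectivity: 6 (face) or 26 (face+edge+corner).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector acc, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  UF uf; uf.init(n);
  std::vector<std::array<int,3>> offs;
  if (connectivity == 6) {
    offs = {{{-1,0,0}}, {{0,-1,0}}, {{0,0,-1}}};
  } else {
    for (int dk = -1; dk <= 0; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (dk == 0 && (dj > 0 || (dj == 0 && di >= 0))) continue;
          offs.push_back({{di, dj, dk}});
        }
  }
  R_xlen_t slab = (R_xlen_t)nx * ny;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = (R_xlen_t)k * slab + (R_xlen_t)j * nx + i;
        if (!acc[idx]) continue;
        for (auto& o : offs) {
          int i2 = i + o[0], j2 = j + o[1], k2 = k + o[2];
          if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz) continue;
          R_xlen_t idx2 = (R_xlen_t)k2 * slab + (R_xlen_t)j2 * nx + i2;
          if (acc[idx2]) uf.unite((int)idx, (int)idx2);
        }
      }
  IntegerVector lab(n);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!acc[i]) { lab[i] = 0; continue; }
    int r = uf.find((int)i);
    if (remap[r] == 0) remap[r] = ++next;
    lab[i] = remap[r];
  }
  lab.attr("n_components") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Scaffold-clearance grid sampling (nearest voxel; outside the grid counts as
// unobstructed, i.e. clearance BIG).
struct ClearGrid {
  bool active = false;
  double ox, oy, oz, sx, sy, sz;
  int nx, ny, nz;
  const double* val = nullptr;
  double at(double px, double py, double pz) const {
    if (!active) return BIG;
    int i = (int)std::floor((px - ox) / sx);
    int j = (int)std::floor((py - oy) / sy);
    int k = (int)std::floor((pz - oz) / sz);
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return BIG;
    return val[((R_xlen_t)k * ny + j) * nx + i];
  }
};

static void rand_dir(double& dx, double& dy, double& dz) {
  double n2;
  do {
    dx = norm_rand(); dy = norm_rand(); dz = norm_rand();
    n2 = dx * dx + dy * dy + dz * dz;
  } while (n2 < 1e-12);
  double inv = 1.0 / std::sqrt(n2);
  dx *= inv; dy *= inv; dz *= inv;
}

// Anchored self-avoiding-walk chain with fixed bond length, inter-chain clash
// distance against `obstacles`, intra-chain excluded volume (non-bonded beads),
// optional scaffold clearance (beads >= anchor_skip residues from the anchor
// must keep >= scaffold_clear from any excluded voxel) and optional second
// anchor (`target`) reached by reachability-constrained biased growth.
// [[Rcpp::export]]
List cpp_saw_chain(NumericVector anchor, Nullable<NumericVector> target_, int n_beads,
                   double bond, double clash, double intra,
                   NumericMatrix obstacles, Nullable<List> cleargrid_,
                   double scaffold_clear, int anchor_skip,
                   int max_trials, int max_backtrack) {
  bool has_target = target_.isNotNull();
  NumericVector target = has_target ? NumericVector(target_) : NumericVector(3);
  ClearGrid cg;
  if (cleargrid_.isNotNull()) {
    List g(cleargrid_);
    NumericVector o = g["origin"], s = g["spacing"], vv = g["values"];
    IntegerVector d = g["dim"];
    cg.active = true;
    cg.ox = o[0]; cg.oy = o[1]; cg.oz = o[2];
    cg.sx = s[0]; cg.sy = s[1]; cg.sz = s[2];
    cg.nx = d[0]; cg.ny = d[1]; cg.nz = d[2];
    cg.val = REAL(vv);
  }
  CellList cl;
  double cell = std::max(clash, intra) * 1.0001;
  cl.build(obstacles, cell);

  std::vector<double> px(n_beads), py(n_beads), pz(n_beads);
  px[0] = anchor[0]; py[0] = anchor[1]; pz[0] = anchor[2];
  if (n_beads == 1)
    return List::create(_["status"] = "ok",
                        _["coords"] = NumericMatrix(1, 3, anchor.begin()));

  auto ok_bead = [&](double x, double y, double z, int i) -> bool {
    // inter-chain clash
    if (cl.any_within(x, y, z, clash)) return false;
    // intra-chain excluded volume (skip bonded neighbour i-1)
    for (int m = 0; m <= i - 2; ++m) {
      double dx = px[m] - x, dy = py[m] - y, dz = pz[m] - z;
      if (dx * dx + dy * dy + dz * dz < intra * intra) return false;
    }
    // scaffold clearance for beads far enough from the anchor
    if (i >= anchor_skip && cg.active && cg.at(x, y, z) < scaffold_clear) return false;
    return true;
  };

  int backtracks = 0;
  int i = 1;
  while (i < n_beads) {
    bool placed = false;
    int remaining = n_beads - 1 - i;  // steps left after placing bead i
    for (int t = 0; t < max_trials; ++t) {
      double x, y, z;
      if (has_target && remaining == 0) {
        x = target[0]; y = target[1]; z = target[2];
        double dx = x - px[i-1], dy = y - py[i-1], dz = z - pz[i-1];
        double d = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (std::fabs(d - bond) > 1e-6) break;   // unreachable: force backtrack
      } else if (has_target && remaining == 1) {
        // bead i must sit on the circle where spheres of radius `bond`
        // around p[i-1] and around the target intersect
        double ax = px[i-1], ay = py[i-1], az = pz[i-1];
        double bx = target[0], by = target[1], bz = target[2];
        double dx = bx - ax, dy = by - ay, dz = bz - az;
        double dab = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (dab > 2.0 * bond || dab < 1e-9) break;
        double nxv = dx / dab, nyv = dy / dab, nzv = dz / dab;
        double rc2 = bond * bond - 0.25 * dab * dab;
        double rc = rc2 > 0 ? std::sqrt(rc2) : 0.0;
        // orthonormal basis of the circle plane
        double ux, uy, uz;
        if (std::fabs(nxv) < 0.9) { ux = 1; uy = 0; uz = 0; } else { ux = 0; uy = 1; uz = 0; }
        double wx = nyv * uz - nzv * uy, wy = nzv * ux - nxv * uz, wz = nxv * uy - nyv * ux;
        double wn = std::sqrt(wx*wx + wy*wy + wz*wz);
        wx /= wn; wy /= wn; wz /= wn;
        double vx = nyv * wz - nzv * wy, vy = nzv * wx - nxv * wz, vz = nxv * wy - nyv * wx;
        double th = 2.0 * M_PI * unif_rand();
        double cx = 0.5 * (ax + bx), cy = 0.5 * (ay + by), cz = 0.5 * (az + bz);
        x = cx + rc * (std::cos(th) * wx + std::sin(th) * vx);
        y = cy + rc * (std::cos(th) * wy + std::sin(th) * vy);
        z = cz + rc * (std::cos(th) * wz + std::sin(th) * vz);
      } else {
        double dx, dy, dz;
        rand_dir(dx, dy, dz);
        x = px[i-1] + bond * dx; y = py[i-1] + bond * dy; z = pz[i-1] + bond * dz;
        if (has_target) {
          double tx = target[0] - x, ty = target[1] - y, tz = target[2] - z;
          double dt2 = tx*tx + ty*ty + tz*tz;
          double reach = bond * remaining;
          if (dt2 > reach * reach) continue;  // target no longer reachable
        }
      }
      if (!ok_bead(x, y, z, i)) continue;
      px[i] = x; py[i] = y; pz[i] = z;
      placed = true;
      break;
    }
    if (placed) { ++i; continue; }
    // backtrack
    if (i <= 1 || backtracks >= max_backtrack)
      return List::create(_["status"] = "fail", _["fail_index"] = i + 1);
    ++backtracks;
    i -= 1;
  }
  NumericMatrix out(n_beads, 3);
  for (int m = 0; m < n_beads; ++m) { out(m,0) = px[m]; out(m,1) = py[m]; out(m,2) = pz[m]; }
  return List::create(_["status"] = "ok", _["coords"] = out,
                      _["backtracks"] = backtracks);
}

// ---------------------------------------------------------------------------
// Excluded-volume crankshaft relaxation: rotate a random non-anchor bead about
// the axis through its neighbours (chain ends pivot about their neighbour);
// accept when no clash/overlap/scaffold violation arises.  Bond lengths are
// preserved exactly.  O(M) clash check per move (meant for toy ensembles).
// [[Rcpp::export]]
NumericMatrix cpp_relax_mesh(NumericMatrix coords, IntegerVector chain,
                             IntegerVector anchor_flag, double clash, double intra,
                             Nullable<List> cleargrid_, double scaffold_clear,
                             IntegerVector anchor_dist, int anchor_skip, int steps) {
  int M = coords.nrow();
  std::vector<double> X(M), Y(M), Z(M);
  for (int m = 0; m < M; ++m) { X[m] = coords(m,0); Y[m] = coords(m,1); Z[m] = coords(m,2); }
  ClearGrid cg;
  if (cleargrid_.isNotNull()) {
    List g(cleargrid_);
    NumericVector o = g["origin"], s = g["spacing"], vv = g["values"];
    IntegerVector d = g["dim"];
    cg.active = true;
    cg.ox = o[0]; cg.oy = o[1]; cg.oz = o[2];
    cg.sx = s[0]; cg.sy = s[1]; cg.sz = s[2];
    cg.nx = d[0]; cg.ny = d[1]; cg.nz = d[2];
    cg.val = REAL(vv);
  }
  auto ok_at = [&](int m, double x, double y, double z) -> bool {
    for (int q = 0; q < M; ++q) {
      if (q == m) continue;
      double lim = (chain[q] == chain[m])
        ? ((std::abs(q - m) == 1) ? 0.0 : intra) : clash;
      if (lim <= 0) continue;
      double dx = X[q] - x, dy = Y[q] - y, dz = Z[q] - z;
      if (dx*dx + dy*dy + dz*dz < lim * lim) return false;
    }
    if (anchor_dist[m] >= anchor_skip && cg.active && cg.at(x, y, z) < scaffold_clear)
      return false;
    return true;
  };
  for (int s_ = 0; s_ < steps; ++s_) {
    int m = (int)std::floor(unif_rand() * M);
    if (m >= M) m = M - 1;
    if (anchor_flag[m]) continue;
    // axis endpoints: same-chain neighbours (or neighbour + random axis at ends)
    int lo = m - 1, hi = m + 1;
    bool has_lo = lo >= 0 && chain[lo] == chain[m];
    bool has_hi = hi < M && chain[hi] == chain[m];
    double ax, ay, az, nxv, nyv, nzv;
    if (has_lo && has_hi) {
      ax = X[lo]; ay = Y[lo]; az = Z[lo];
      nxv = X[hi] - X[lo]; nyv = Y[hi] - Y[lo]; nzv = Z[hi] - Z[lo];
    } else if (has_lo || has_hi) {
      int nb = has_lo ? lo : hi;
      ax = X[nb]; ay = Y[nb]; az = Z[nb];
      rand_dir(nxv, nyv, nzv);
    } else continue;
    double nn = std::sqrt(nxv*nxv + nyv*nyv + nzv*nzv);
    if (nn < 1e-9) continue;
    nxv /= nn; nyv /= nn; nzv /= nn;
    double th = (unif_rand() - 0.5) * M_PI;  // up to +-90 degrees
    double ct = std::cos(th), st = std::sin(th);
    double rx = X[m] - ax, ry = Y[m] - ay, rz = Z[m] - az;
    double dot = rx*nxv + ry*nyv + rz*nzv;
    double cxv = nyv*rz - nzv*ry, cyv = nzv*rx - nxv*rz, czv = nxv*ry - nyv*rx;
    double qx = ax + rx*ct + cxv*st + nxv*dot*(1-ct);
    double qy = ay + ry*ct + cyv*st + nyv*dot*(1-ct);
    double qz = az + rz*ct + czv*st + nzv*dot*(1-ct);
    if (ok_at(m, qx, qy, qz)) { X[m] = qx; Y[m] = qy; Z[m] = qz; }
  }
  NumericMatrix out(M, 3);
  for (int m = 0; m < M; ++m) { out(m,0) = X[m]; out(m,1) = Y[m]; out(m,2) = Z[m]; }
  return out;
}

// Per-bead flag: has at least one bead of a different chain within cutoff.
// [[Rcpp::export]]
LogicalVector cpp_interchain_contact(NumericMatrix coords, IntegerVector chain,
                                     double cutoff) {
  int M = coords.nrow();
  LogicalVector out(M);
  CellList cl; cl.build(coords, std::max(cutoff, 1e-6) * 1.0001);
  double c2 = cutoff * cutoff;
  for (int m = 0; m < M; ++m) {
    double pxv = coords(m,0), pyv = coords(m,1), pzv = coords(m,2);
    int ci = (int)std::floor((pxv - cl.ox) / cl.c);
    int cj = (int)std::floor((pyv - cl.oy) / cl.c);
    int ck = (int)std::floor((pzv - cl.oz) / cl.c);
    bool found = false;
    for (int dk = -1; dk <= 1 && !found; ++dk) {
      int k = ck + dk; if (k < 0 || k >= cl.nz) continue;
      for (int dj = -1; dj <= 1 && !found; ++dj) {
        int j = cj + dj; if (j < 0 || j >= cl.ny) continue;
        for (int di = -1; di <= 1 && !found; ++di) {
          int i = ci + di; if (i < 0 || i >= cl.nx) continue;
          int q = cl.head[((size_t)k * cl.ny + j) * cl.nx + i];
          while (q >= 0) {
            if (chain[q] != chain[m]) {
              double dx = cl.X[q]-pxv, dy = cl.Y[q]-pyv, dz = cl.Z[q]-pzv;
              if (dx*dx + dy*dy + dz*dz <= c2) { found = true; break; }
            }
            q = cl.nxt[q];
          }
        }
      }
    }
    out[m] = found;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Explicit-Euler stepping of the discretised 1D Smoluchowski master equation.
// up[n]: rate n -> n+1 (up[N-1] is the absorption rate into the sink);
// dn[n]: rate n -> n-1 (dn[0] = 0, reflecting).  Rates in 1/us, dt in us.
// Records absorbed-mass increments into bins of width dt*out_stride and the
// survival probability at each bin boundary; stops once survival < tol_resid
// or max_steps is reached.
// [[Rcpp::export]]
List cpp_solve_fpt(NumericVector up, NumericVector dn, int start, double dt,
                   int out_stride, double tol_resid, double max_steps_d) {
  int N = up.size();
  std::vector<double> rho(N, 0.0), rho2(N, 0.0), ktot(N);
  rho[start] = 1.0;
  const double* kup = REAL(up);
  const double* kdn = REAL(dn);
  for (int n = 0; n < N; ++n) ktot[n] = dt * (kup[n] + kdn[n]);
  std::vector<double> kupd(N), kdnd(N);
  for (int n = 0; n < N; ++n) { kupd[n] = dt * kup[n]; kdnd[n] = dt * kdn[n]; }
  std::vector<double> gbin, surv;
  double absorbed = 0.0, binacc = 0.0, max_drift = 0.0;
  double step = 0.0;
  double survival = 1.0;
  long long istep = 0;
  while (true) {
    // one Euler step (branch-free interior)
    double tot = 0.0;
    double abs_inc = kupd[N-1] * rho[N-1];
    double* r = rho.data(); double* r2 = rho2.data();
    const double* ku = kupd.data(); const double* kd = kdnd.data();
    const double* kt = ktot.data();
    r2[0] = r[0] + (N > 1 ? kd[1] * r[1] : 0.0) - kt[0] * r[0];
    for (int n = 1; n < N - 1; ++n)
      r2[n] = r[n] + ku[n-1] * r[n-1] + kd[n+1] * r[n+1] - kt[n] * r[n];
    if (N > 1)
      r2[N-1] = r[N-1] + ku[N-2] * r[N-2] - kt[N-1] * r[N-1];
    for (int n = 0; n < N; ++n) tot += r2[n];
    std::swap(rho, rho2);
    absorbed += abs_inc;
    binacc += abs_inc;
    survival = tot;
    double drift = std::fabs(survival + absorbed - 1.0);
    if (drift > max_drift) max_drift = drift;
    ++istep;
    if (istep % out_stride == 0) {
      gbin.push_back(binacc); binacc = 0.0;
      surv.push_back(survival);
      if (survival < tol_resid) break;
    }
    if ((double)istep >= max_steps_d) break;
    if (istep % 1048576 == 0) Rcpp::checkUserInterrupt();
  }
  if (binacc > 0) { gbin.push_back(binacc); surv.push_back(survival); }
  step = (double)istep;
  return List::create(_["g_mass"] = NumericVector(gbin.begin(), gbin.end()),
                      _["survival"] = NumericVector(surv.begin(), surv.end()),
                      _["bin_dt"] = dt * out_stride,
                      _["dt"] = dt,
                      _["absorbed"] = absorbed,
                      _["survival_end"] = survival,
                      _["t_end"] = step * dt,
                      _["steps"] = step,
                      _["max_drift"] = max_drift);
}

// ---------------------------------------------------------------------------
// Linear interpolation on a uniform grid, clamped at the ends.
static inline double lin_at(const double* v, int n, double z0, double dz, double z) {
  double u = (z - z0) / dz;
  if (u <= 0) return v[0];
  if (u >= n - 1) return v[n - 1];
  int i = (int)std::floor(u);
  double f = u - i;
  return v[i] * (1 - f) + v[i + 1] * f;
}

// Overdamped Euler-Maruyama walkers with the spurious-drift term for
// position-dependent D; reflecting at z_lo, absorbing at z_hi.  drift and D
// are profiles on the uniform grid (z0, dz, n).  Returns first-passage times
// (-1 for walkers that did not absorb within max_steps).
// [[Rcpp::export]]
NumericVector cpp_bd_mfpt(NumericVector driftv, NumericVector Dv, double z0g,
                          double dzg, double z_start, double z_lo, double z_hi,
                          double dt, int n_walkers, double max_steps_d) {
  int n = Dv.size();
  const double* dr = REAL(driftv);
  const double* Dp = REAL(Dv);
  NumericVector out(n_walkers);
  for (int w = 0; w < n_walkers; ++w) {
    double z = z_start;
    double t = -1.0;
    long long steps = 0;
    while ((double)steps < max_steps_d) {
      double D = lin_at(Dp, n, z0g, dzg, z);
      double a = lin_at(dr, n, z0g, dzg, z);
      z += a * dt + std::sqrt(2.0 * D * dt) * norm_rand();
      ++steps;
      if (z < z_lo) z = 2.0 * z_lo - z;
      if (z >= z_hi) { t = steps * dt; break; }
    }
    out[w] = t;
    if (w % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Equilibrium Brownian-dynamics trace on a 1D potential: both ends reflecting,
// positions sampled every sample_stride steps.
// [[Rcpp::export]]
NumericVector cpp_bd_trace(NumericVector driftv, NumericVector Dv, double z0g,
                           double dzg, double z_start, double z_lo, double z_hi,
                           double dt, double n_steps_d, int sample_stride) {
  int n = Dv.size();
  const double* dr = REAL(driftv);
  const double* Dp = REAL(Dv);
  long long n_steps = (long long)n_steps_d;
  std::vector<double> samples;
  samples.reserve((size_t)(n_steps / sample_stride) + 1);
  double z = z_start;
  for (long long s = 1; s <= n_steps; ++s) {
    double D = lin_at(Dp, n, z0g, dzg, z);
    double a = lin_at(dr, n, z0g, dzg, z);
    z += a * dt + std::sqrt(2.0 * D * dt) * norm_rand();
    if (z < z_lo) z = 2.0 * z_lo - z;
    if (z > z_hi) z = 2.0 * z_hi - z;
    if (z < z_lo) z = z_lo;  // pathological double reflection
    if (s % sample_stride == 0) samples.push_back(z);
    if (s % 1048576 == 0) Rcpp::checkUserInterrupt();
  }
  return NumericVector(samples.begin(), samples.end());
}
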
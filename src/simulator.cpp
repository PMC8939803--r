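#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <climits>
using namespace Rcpp;

// Particle transport and deposition kernels for the shear-device platelet
// model.  All randomness comes from R's RNG (RNGScope), so runs are
// reproducible under set.seed().  Lengths are in micrometres, times in
// seconds.  The xy-domain is exactly nx*side x ny*side and periodic; z is
// reflected at the top wall (height H) and absorbing at z = 0, where a
// particle becomes a trapped deposition candidate of the cell under it.

static inline double wrap_coord(double x, double w) {
  double r = x - w * std::floor(x / w);
  if (r >= w) r -= w; // guards the floating-point edge case r == w
  return r;
}

// Moves bulk particles of one species; returns the surviving positions.
// trapped (nx x ny) is incremented in place for particles hitting z = 0.
static NumericMatrix transport_species(const NumericMatrix& pos, double v,
                                       double shear, double dt, double H,
                                       IntegerMatrix trapped, double side) {
  const int n = pos.nrow();
  const int nx = trapped.nrow(), ny = trapped.ncol();
  const double wx = nx * side, wy = ny * side;
  std::vector<double> xs, ys, zs;
  xs.reserve(n); ys.reserve(n); zs.reserve(n);
  for (int i = 0; i < n; ++i) {
    double s = std::fabs(norm_rand());
    double lambda = (unif_rand() < 0.5) ? -1.0 : 1.0;
    double r = unif_rand();
    double z = pos(i, 2);
    double dz = lambda * v * s * dt;
    double dx = v * s * std::cos(2.0 * M_PI * r) * dt + shear * z * dt;
    double dy = v * s * std::sin(2.0 * M_PI * r) * dt;
    double x = wrap_coord(pos(i, 0) + dx, wx);
    double y = wrap_coord(pos(i, 1) + dy, wy);
    double zn = z + dz;
    // bounce back at the top; repeated folding covers jumps > H
    while (zn > H) {
      zn = 2.0 * H - zn;
    }
    if (!std::isfinite(x) || !std::isfinite(y) || !std::isfinite(zn))
      stop("non-finite position for particle %d after transport step", i + 1);
    if (zn < 0) {
      // crossed the wall: candidate for deposition, never re-injected
      int ix = std::min((int)std::floor(x / side), nx - 1);
      int iy = std::min((int)std::floor(y / side), ny - 1);
      trapped(ix, iy) += 1;
    } else {
      xs.push_back(x); ys.push_back(y); zs.push_back(zn);
    }
  }
  NumericMatrix out(xs.size(), 3);
  for (size_t i = 0; i < xs.size(); ++i) {
    out(i, 0) = xs[i]; out(i, 1) = ys[i]; out(i, 2) = zs[i];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_transport(NumericMatrix ap, NumericMatrix nap, double v_ap,
                   double v_nap, double shear, double dt, double H,
                   IntegerMatrix trapped_ap, IntegerMatrix trapped_nap,
                   double side) {
  RNGScope scope;
  IntegerMatrix tap = clone(trapped_ap), tnap = clone(trapped_nap);
  NumericMatrix ap2 = transport_species(ap, v_ap, shear, dt, H, tap, side);
  NumericMatrix nap2 = transport_species(nap, v_nap, shear, dt, H, tnap, side);
  return List::create(_["ap"] = ap2, _["nap"] = nap2,
                      _["trapped_ap"] = tap, _["trapped_nap"] = tnap);
}

static inline double clamp_prob(double p, bool* clamped) {
  if (p < 0) stop("negative deposition probability: invariant breach upstream");
  if (p > 1) { *clamped = true; return 1.0; }
  return p;
}

struct DepositCounts { int ap; int nap; bool clamped; };

// One deposition sweep.  Phases: (a) mean-field albumin fill, (b) activated
// platelets seed clusters on free cells, (c) AP+NAP aggregate on cells
// adjacent to deposits (adjacency frozen at phase start), (d) platelets pile
// on top of occupied cells (occupancy frozen at phase start).  Candidate
// species order within a cell is randomized each sweep.
static DepositCounts deposit_sweep(IntegerMatrix trapped_ap,
                                   IntegerMatrix trapped_nap,
                                   IntegerMatrix substrate,
                                   NumericMatrix rho_al, double p_ad,
                                   double p_ag, double p_t, double p_f,
                                   double a_t, double dt, double rho_max,
                                   int connectivity) {
  const int nx = substrate.nrow(), ny = substrate.ncol();
  DepositCounts cnt = {0, 0, false};
  // (a) albumin: d rho/dt = p_f (rho_max - rho), explicit Euler
  double f = p_f * dt;
  if (f > 1) { f = 1.0; cnt.clamped = true; }
  if (f < 0) stop("negative albumin fill rate");
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      rho_al(i, j) += f * (rho_max - rho_al(i, j));

  // (b) adhesion: AP seed new clusters on platelet-free cells
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (substrate(i, j) != 0 || trapped_ap(i, j) == 0) continue;
      double q = clamp_prob(p_ad * std::exp(-a_t * rho_al(i, j) / rho_max) * dt,
                            &cnt.clamped);
      int n = trapped_ap(i, j);
      for (int k = 0; k < n; ++k) {
        if (unif_rand() < q) {
          substrate(i, j) = 1;
          trapped_ap(i, j) -= 1;
          cnt.ap += 1;
          break; // cell no longer free; the rest wait
        }
      }
    }
  }

  // (c) aggregation next to a deposited platelet; adjacency from a snapshot
  const int dx4[] = {1, -1, 0, 0}, dy4[] = {0, 0, 1, -1};
  const int dx8[] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int* ddx = (connectivity == 8) ? dx8 : dx4;
  const int* ddy = (connectivity == 8) ? dy8 : dy4;
  const int nd = (connectivity == 8) ? 8 : 4;
  IntegerMatrix occ = clone(substrate);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (occ(i, j) != 0) continue;
      int n_ap = trapped_ap(i, j), n_nap = trapped_nap(i, j);
      if (n_ap + n_nap == 0) continue;
      bool adj = false;
      for (int d = 0; d < nd && !adj; ++d) {
        int ii = (i + ddx[d] + nx) % nx, jj = (j + ddy[d] + ny) % ny;
        if (occ(ii, jj) > 0) adj = true;
      }
      if (!adj) continue;
      double r = clamp_prob(p_ag * std::exp(-a_t * rho_al(i, j) / rho_max) * dt,
                            &cnt.clamped);
      int total = n_ap + n_nap;
      for (int k = 0; k < total; ++k) {
        // draw the species of the k-th candidate without replacement
        bool is_ap = (unif_rand() * (n_ap + n_nap) < n_ap);
        if (is_ap) n_ap--; else n_nap--;
        if (unif_rand() < r) {
          substrate(i, j) = 1;
          if (is_ap) { trapped_ap(i, j) -= 1; cnt.ap += 1; }
          else { trapped_nap(i, j) -= 1; cnt.nap += 1; }
          break;
        }
      }
    }
  }

  // (d) deposit on top of existing clusters; occupancy from a snapshot
  double pt = clamp_prob(p_t * dt, &cnt.clamped);
  IntegerMatrix occ2 = clone(substrate);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (occ2(i, j) == 0) continue;
      int n_ap = trapped_ap(i, j), n_nap = trapped_nap(i, j);
      for (int k = n_ap + n_nap; k > 0; --k) {
        bool is_ap = (unif_rand() * (n_ap + n_nap) < n_ap);
        if (unif_rand() < pt) {
          substrate(i, j) += 1;
          if (is_ap) { trapped_ap(i, j) -= 1; cnt.ap += 1; }
          else { trapped_nap(i, j) -= 1; cnt.nap += 1; }
        }
        if (is_ap) n_ap--; else n_nap--;
      }
    }
  }
  return cnt;
}

// [[Rcpp::export]]
List cpp_deposit(IntegerMatrix trapped_ap, IntegerMatrix trapped_nap,
                 IntegerMatrix substrate, NumericMatrix rho_al, double p_ad,
                 double p_ag, double p_t, double p_f, double a_t, double dt,
                 double rho_max, int connectivity) {
  RNGScope scope;
  IntegerMatrix tap = clone(trapped_ap), tnap = clone(trapped_nap);
  IntegerMatrix sub = clone(substrate);
  NumericMatrix rho = clone(rho_al);
  DepositCounts cnt = deposit_sweep(tap, tnap, sub, rho, p_ad, p_ag, p_t, p_f,
                                    a_t, dt, rho_max, connectivity);
  return List::create(_["trapped_ap"] = tap, _["trapped_nap"] = tnap,
                      _["substrate"] = sub, _["rho_al"] = rho,
                      _["deposited_ap"] = cnt.ap, _["deposited_nap"] = cnt.nap,
                      _["clamped"] = cnt.clamped);
}

// Connected components of occupied cells (height >= 1) by flood fill.
// [[Rcpp::export]]
List cpp_cluster_stats(IntegerMatrix substrate, int connectivity, bool wrap) {
  const int nx = substrate.nrow(), ny = substrate.ncol();
  const int dx4[] = {1, -1, 0, 0}, dy4[] = {0, 0, 1, -1};
  const int dx8[] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int* ddx = (connectivity == 8) ? dx8 : dx4;
  const int* ddy = (connectivity == 8) ? dy8 : dy4;
  const int nd = (connectivity == 8) ? 8 : 4;
  std::vector<char> seen(nx * ny, 0);
  int n_clusters = 0;
  long total_cells = 0;
  std::vector<int> stack;
  for (int j0 = 0; j0 < ny; ++j0) {
    for (int i0 = 0; i0 < nx; ++i0) {
      if (substrate(i0, j0) <= 0 || seen[i0 + nx * j0]) continue;
      ++n_clusters;
      stack.clear();
      stack.push_back(i0 + nx * j0);
      seen[i0 + nx * j0] = 1;
      while (!stack.empty()) {
        int id = stack.back(); stack.pop_back();
        ++total_cells;
        int i = id % nx, j = id / nx;
        for (int d = 0; d < nd; ++d) {
          int ii = i + ddx[d], jj = j + ddy[d];
          if (wrap) { ii = (ii + nx) % nx; jj = (jj + ny) % ny; }
          else if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
          int nid = ii + nx * jj;
          if (substrate(ii, jj) > 0 && !seen[nid]) {
            seen[nid] = 1;
            stack.push_back(nid);
          }
        }
      }
    }
  }
  double mean_size = (n_clusters > 0) ? (double)total_cells / n_clusters : 0.0;
  return List::create(_["n_clusters"] = n_clusters, _["mean_size"] = mean_size);
}

// ---------------------------------------------------------------------------
// Fast internal engine for full runs.  Semantics are identical to the
// step-function path above; the differences are purely computational:
//  * a counter-based xoshiro256++ RNG seeded once from R's RNG (so runs are
//    still reproducible under set.seed) replaces per-draw calls into R,
//  * the mean-field albumin density, which is spatially uniform by
//    construction, is carried as a scalar,
//  * deposition sweeps only visit cells that actually hold trapped
//    candidates (active list) instead of scanning the whole grid.

struct Xoshiro {
  uint64_t s[4];
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  void seed_from_r() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (i + 1));
    }
    if ((s[0] | s[1] | s[2] | s[3]) == 0) s[0] = 1;
  }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double runif() { return (next() >> 11) * 1.1102230246251565e-16; }
  bool has_cached = false;
  double cached = 0.0;
  double rnorm() {
    if (has_cached) { has_cached = false; return cached; }
    double u1 = runif(), u2 = runif();
    while (u1 <= 0) u1 = runif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
    cached = r * std::sin(a); has_cached = true;
    return r * std::cos(a);
  }
};

// Full forward run: alternates transport and deposition sweeps and records
// the three observables at the requested step indices (0 = initial state).
// [[Rcpp::export]]
List cpp_simulate(int n_ap, int n_nap, double v_ap, double v_nap, double shear,
                  double dt, int n_steps, double H, int nx, int ny, double side,
                  double p_ad, double p_ag, double p_t, double p_f, double a_t,
                  double rho_max, int connectivity, IntegerVector obs_steps,
                  double area_mm2, double volume_ul, bool count_trapped) {
  RNGScope scope;
  Xoshiro rng;
  rng.seed_from_r();
  const double wx = nx * side, wy = ny * side;
  const int ncell = nx * ny;
  std::vector<double> apx(n_ap), apy(n_ap), apz(n_ap);
  std::vector<double> napx(n_nap), napy(n_nap), napz(n_nap);
  for (int i = 0; i < n_ap; ++i) {
    apx[i] = rng.runif() * wx; apy[i] = rng.runif() * wy;
    apz[i] = rng.runif() * H;
  }
  for (int i = 0; i < n_nap; ++i) {
    napx[i] = rng.runif() * wx; napy[i] = rng.runif() * wy;
    napz[i] = rng.runif() * H;
  }
  std::vector<int> tap(ncell, 0), tnap(ncell, 0), sub(ncell, 0);
  std::vector<int> active; active.reserve(256);
  std::vector<char> in_active(ncell, 0);
  double rho = 0.0;
  int dep_ap = 0, dep_nap = 0;
  bool clamped = false;

  const int dx4[] = {1, -1, 0, 0}, dy4[] = {0, 0, 1, -1};
  const int dx8[] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int* ddx = (connectivity == 8) ? dx8 : dx4;
  const int* ddy = (connectivity == 8) ? dy8 : dy4;
  const int nd = (connectivity == 8) ? 8 : 4;

  // moves one species, trapping wall-crossers into cells (active list kept)
  auto transport = [&](std::vector<double>& x, std::vector<double>& y,
                       std::vector<double>& z, double v,
                       std::vector<int>& trapped) {
    size_t i = 0;
    while (i < x.size()) {
      double s = std::fabs(rng.rnorm());
      double lambda = (rng.runif() < 0.5) ? -1.0 : 1.0;
      double r = rng.runif();
      double dz = lambda * v * s * dt;
      double ang = 2.0 * M_PI * r;
      double xn = wrap_coord(x[i] + v * s * std::cos(ang) * dt +
                             shear * z[i] * dt, wx);
      double yn = wrap_coord(y[i] + v * s * std::sin(ang) * dt, wy);
      double zn = z[i] + dz;
      while (zn > H) zn = 2.0 * H - zn;
      if (!std::isfinite(xn) || !std::isfinite(yn) || !std::isfinite(zn))
        stop("non-finite position for particle %d after transport step",
             (int)i + 1);
      if (zn < 0) {
        int ix = std::min((int)std::floor(xn / side), nx - 1);
        int iy = std::min((int)std::floor(yn / side), ny - 1);
        int c = ix + nx * iy;
        trapped[c] += 1;
        if (!in_active[c]) { in_active[c] = 1; active.push_back(c); }
        x[i] = x.back(); y[i] = y.back(); z[i] = z.back();
        x.pop_back(); y.pop_back(); z.pop_back();
      } else {
        x[i] = xn; y[i] = yn; z[i] = zn;
        ++i;
      }
    }
  };

  auto clampp = [&](double p) {
    if (p < 0) stop("negative deposition probability");
    if (p > 1) { clamped = true; return 1.0; }
    return p;
  };

  std::vector<char> adj_flag; adj_flag.reserve(256);

  const int n_obs = obs_steps.size();
  NumericVector out_nclust(n_obs), out_size(n_obs), out_nplat(n_obs);
  int obs_idx = 0;
  IntegerMatrix sub_mat(nx, ny);
  for (int step = 0; step <= n_steps; ++step) {
    if (obs_idx < n_obs && obs_steps[obs_idx] == step) {
      std::copy(sub.begin(), sub.end(), sub_mat.begin());
      List cs = cpp_cluster_stats(sub_mat, connectivity, true);
      out_nclust[obs_idx] = as<int>(cs["n_clusters"]) / area_mm2;
      out_size[obs_idx] = as<double>(cs["mean_size"]);
      // "still in suspension": with count_trapped, everything not yet
      // deposited; otherwise only the platelets still in the bulk
      out_nplat[obs_idx] = (count_trapped ? (double)(n_nap - dep_nap)
                                          : (double)napx.size()) / volume_ul;
      ++obs_idx;
    }
    if (step == n_steps) break;

    transport(apx, apy, apz, v_ap, tap);
    transport(napx, napy, napz, v_nap, tnap);

    // (a) albumin (uniform mean field)
    double f = p_f * dt;
    if (f > 1) { f = 1.0; clamped = true; }
    if (f < 0) stop("negative albumin fill rate");
    rho += f * (rho_max - rho);
    double att = std::exp(-a_t * rho / rho_max);
    double q = clampp(p_ad * att * dt);
    double rr = clampp(p_ag * att * dt);
    double pt = clampp(p_t * dt);

    // index of the first success among a run of Bernoulli(p) candidates
    // (geometric waiting time; distributionally identical to looping)
    auto first_success = [&](double p) -> long {
      if (p >= 1.0) return 0;
      if (p <= 0.0) return LONG_MAX;
      return (long)std::floor(std::log(rng.runif()) / std::log1p(-p));
    };
    // Binomial(n, p) by skipping geometric gaps: O(successes + 1)
    auto rbinom_skip = [&](int n, double p) -> int {
      if (p <= 0.0 || n <= 0) return 0;
      if (p >= 1.0) return n;
      int k = 0;
      long pos = first_success(p);
      while (pos < n) {
        ++k;
        pos += 1 + first_success(p);
      }
      return k;
    };

    // (b) adhesion on free cells: first successful AP candidate seeds
    for (int c : active) {
      if (sub[c] != 0 || tap[c] == 0) continue;
      if (first_success(q) < tap[c]) { sub[c] = 1; tap[c] -= 1; dep_ap += 1; }
    }

    // (c) aggregation; adjacency frozen at phase start
    adj_flag.assign(active.size(), 0);
    for (size_t a = 0; a < active.size(); ++a) {
      int c = active[a];
      if (sub[c] != 0 || tap[c] + tnap[c] == 0) continue;
      int i = c % nx, j = c / nx;
      for (int d = 0; d < nd; ++d) {
        int ii = (i + ddx[d] + nx) % nx, jj = (j + ddy[d] + ny) % ny;
        if (sub[ii + nx * jj] > 0) { adj_flag[a] = 1; break; }
      }
    }
    for (size_t a = 0; a < active.size(); ++a) {
      if (!adj_flag[a]) continue;
      int c = active[a];
      int total = tap[c] + tnap[c];
      // candidates are a random species interleaving; by exchangeability
      // the first successful one is AP with probability tap/total
      if (first_success(rr) < total) {
        sub[c] = 1;
        bool is_ap = (rng.runif() * total < tap[c]);
        if (is_ap) { tap[c] -= 1; dep_ap += 1; }
        else { tnap[c] -= 1; dep_nap += 1; }
      }
    }

    // (d) on-top deposition; every candidate over an occupied cell attempts
    // independently, so the per-species deposit counts are Binomial
    for (int c : active) {
      if (sub[c] == 0 || tap[c] + tnap[c] == 0) continue;
      int ka = rbinom_skip(tap[c], pt);
      int kn = rbinom_skip(tnap[c], pt);
      sub[c] += ka + kn;
      tap[c] -= ka; tnap[c] -= kn;
      dep_ap += ka; dep_nap += kn;
    }

    // compact the active list
    size_t w = 0;
    for (size_t a = 0; a < active.size(); ++a) {
      int c = active[a];
      if (tap[c] + tnap[c] > 0) active[w++] = c;
      else in_active[c] = 0;
    }
    active.resize(w);
  }

  std::copy(sub.begin(), sub.end(), sub_mat.begin());
  IntegerMatrix tap_mat(nx, ny), tnap_mat(nx, ny);
  std::copy(tap.begin(), tap.end(), tap_mat.begin());
  std::copy(tnap.begin(), tnap.end(), tnap_mat.begin());
  NumericMatrix rho_mat(nx, ny);
  std::fill(rho_mat.begin(), rho_mat.end(), rho);
  return List::create(_["n_clusters"] = out_nclust,
                      _["mean_cluster_size"] = out_size,
                      _["n_platelet"] = out_nplat,
                      _["substrate"] = sub_mat, _["rho_al"] = rho_mat,
                      _["trapped_ap"] = tap_mat,
                      _["trapped_nap"] = tnap_mat,
                      _["bulk_ap"] = (int)apx.size(),
                      _["bulk_nap"] = (int)napx.size(),
                      _["deposited_ap"] = dep_ap, _["deposited_nap"] = dep_nap,
                      _["clamped"] = clamped);
}
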
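#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Self-contained counter-seeded RNG (splitmix64 seeding + xoshiro256++),
// so that run j of a batch with master seed s is reproducible and
// independent of R's RNG state and of the other runs.
namespace {

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // uniform in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  int unif_int(int n) { return (int)(next() % (uint64_t)n); }
};

struct Pools {
  // mutant/resident membership with O(1) insert/remove
  std::vector<int> mut, res, pos_mut, pos_res;
  std::vector<char> type;
  explicit Pools(int n, const std::vector<char>& start)
      : pos_mut(n, -1), pos_res(n, -1), type(start) {
    for (int v = 0; v < n; ++v) {
      if (type[v]) { pos_mut[v] = mut.size(); mut.push_back(v); }
      else { pos_res[v] = res.size(); res.push_back(v); }
    }
  }
  void flip(int v) {
    if (type[v]) {
      int p = pos_mut[v], last = mut.back();
      mut[p] = last; pos_mut[last] = p; mut.pop_back(); pos_mut[v] = -1;
      pos_res[v] = res.size(); res.push_back(v); type[v] = 0;
    } else {
      int p = pos_res[v], last = res.back();
      res[p] = last; pos_res[last] = p; res.pop_back(); pos_res[v] = -1;
      pos_mut[v] = mut.size(); mut.push_back(v); type[v] = 1;
    }
  }
};

// Sample target v from the cumulative kernel row of u (binary search).
int sample_target(const NumericMatrix& cumW, int u, double un) {
  const int n = cumW.ncol();
  int lo = 0, hi = n - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cumW(u, mid) < un) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// One trajectory until absorption. Returns steps (>0) and sets fixed.
// fast_forward: lump runs of no-change steps by sampling their number from
// a geometric law, then draw a type-changing event directly; the joint
// distribution of (outcome, step count) is unchanged.
double run_one(const NumericMatrix& W, const NumericMatrix& cumW, double r,
               const std::vector<char>& start, Rng& rng, bool fast_forward,
               double step_cap, bool& fixed, bool& capped) {
  const int n = W.nrow();
  Pools pool(n, start);
  double steps = 0.0;
  capped = false;

  while (!pool.mut.empty() && !pool.res.empty()) {
    if (steps >= step_cap) { capped = true; fixed = false; return steps; }
    const int k = pool.mut.size();
    const double F = n + (r - 1.0) * k;

    if (!fast_forward) {
      const bool umut = rng.unif() * F < r * k;
      const int u = umut ? pool.mut[rng.unif_int(k)]
                         : pool.res[rng.unif_int(n - k)];
      const int v = sample_target(cumW, u, rng.unif());
      steps += 1.0;
      if (pool.type[v] != pool.type[u]) pool.flip(v);
    } else {
      // per-vertex probability of a type-changing event
      double total = 0.0;
      std::vector<double> pc(n, 0.0);
      for (int u = 0; u < n; ++u) {
        double cross = 0.0;
        for (int v = 0; v < n; ++v)
          if (W(u, v) > 0.0 && pool.type[v] != pool.type[u]) cross += W(u, v);
        pc[u] = (pool.type[u] ? r : 1.0) / F * cross;
        total += pc[u];
      }
      // number of held (no-change) steps before the event: geometric
      const double q0 = 1.0 - total;
      double g = 0.0;
      if (q0 > 0.0) g = std::floor(std::log(rng.unif()) / std::log(q0));
      steps += g + 1.0;
      if (steps > step_cap) { capped = true; fixed = false; return steps; }
      double z = rng.unif() * total;
      int u = -1, last_pos = -1;
      for (int cand = 0; cand < n; ++cand) {
        if (pc[cand] <= 0.0) continue;
        last_pos = cand;
        if (z < pc[cand]) { u = cand; break; }
        z -= pc[cand];
      }
      if (u < 0) u = last_pos;  // guard against rounding drift
      // target among opposite-type neighbours, proportional to weight
      double cross = 0.0;
      for (int v = 0; v < n; ++v)
        if (W(u, v) > 0.0 && pool.type[v] != pool.type[u]) cross += W(u, v);
      double zt = rng.unif() * cross;
      int tgt = -1;
      for (int v = 0; v < n; ++v) {
        if (W(u, v) > 0.0 && pool.type[v] != pool.type[u]) {
          if (zt < W(u, v)) { tgt = v; break; }
          zt -= W(u, v);
        }
      }
      if (tgt < 0) tgt = n - 1;
      pool.flip(tgt);
    }
  }
  fixed = pool.res.empty();
  return steps;
}

}  // namespace

// [[Rcpp::export]]
List simulate_moran_cpp(NumericMatrix W, double r, IntegerVector start0,
                        double seed, bool fast_forward, double step_cap) {
  const int n = W.nrow();
  NumericMatrix cumW(n, n);
  for (int u = 0; u < n; ++u) {
    double acc = 0.0;
    for (int v = 0; v < n; ++v) { acc += W(u, v); cumW(u, v) = acc; }
    cumW(u, n - 1) = 1.0 + 1e-9;
  }
  std::vector<char> start(n, 0);
  for (int i = 0; i < start0.size(); ++i) start[start0[i]] = 1;
  Rng rng((uint64_t)seed);
  bool fixed = false, capped = false;
  double steps = run_one(W, cumW, r, start, rng, fast_forward, step_cap,
                         fixed, capped);
  if (capped) stop("step cap exceeded (runaway trajectory)");
  return List::create(_["fixed"] = fixed, _["steps"] = steps);
}

// Batch of independent runs; run j uses seed master_seed * 2^20 + j so
// batches are reproducible and extendable.
// [[Rcpp::export]]
List simulate_batch_cpp(NumericMatrix W, double r, NumericVector init_cum,
                        int n_runs, double master_seed, bool fast_forward,
                        double step_cap) {
  const int n = W.nrow();
  NumericMatrix cumW(n, n);
  for (int u = 0; u < n; ++u) {
    double acc = 0.0;
    for (int v = 0; v < n; ++v) { acc += W(u, v); cumW(u, v) = acc; }
    cumW(u, n - 1) = 1.0 + 1e-9;
  }
  LogicalVector fixed_out(n_runs);
  NumericVector steps_out(n_runs);
  for (int j = 0; j < n_runs; ++j) {
    Rng rng(((uint64_t)master_seed << 20) + (uint64_t)j);
    // sample the starting vertex from the initialization distribution
    double u01 = rng.unif();
    int v0 = 0;
    while (v0 < n - 1 && init_cum[v0] < u01) ++v0;
    std::vector<char> start(n, 0);
    start[v0] = 1;
    bool fixed = false, capped = false;
    double steps = run_one(W, cumW, r, start, rng, fast_forward, step_cap,
                           fixed, capped);
    if (capped) stop("step cap exceeded in run %d", j + 1);
    fixed_out[j] = fixed;
    steps_out[j] = steps;
    if (j % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["fixed"] = fixed_out, _["steps"] = steps_out);
}
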
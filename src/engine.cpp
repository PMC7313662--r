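// Forward-in-time diploid Wright-Fisher engine with recombination, mutation,
// bottlenecks, fixation-conditioned selective sweeps and psi-sweepstakes
// reproduction episodes.
//
// Haplotypes live in a reference-counted pool of sorted derived-allele
// position vectors (infinite-sites on discrete positions, collision redraw).
// A transmitted gamete with no crossover and no new mutation shares its
// parent's pool entry, so a generation is mostly pointer bookkeeping.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----
// xoshiro256++ seeded through splitmix64; self-contained so that replicate
// streams are independent of R's RNG and bit-reproducible across platforms.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // Lemire bounded draw, n >= 1
  inline uint32_t bounded(uint32_t n) {
    uint64_t x = next();
    __uint128_t m = (__uint128_t)x * (__uint128_t)n;
    uint64_t l = (uint64_t)m;
    if (l < n) {
      uint64_t t = (0 - (uint64_t)n) % n;
      while (l < t) {
        x = next();
        m = (__uint128_t)x * (__uint128_t)n;
        l = (uint64_t)m;
      }
    }
    return (uint32_t)(m >> 64);
  }
  int poisson(double lambda) {
    if (lambda <= 0.0) return 0;
    if (lambda < 30.0) {
      double thr = std::exp(-lambda);
      int k = 0;
      double p = 1.0;
      do { ++k; p *= unif(); } while (p > thr);
      return k - 1;
    }
    // sum of independent halves keeps the exact distribution
    return poisson(lambda / 2.0) + poisson(lambda / 2.0);
  }
};

// ---------------------------------------------------------- population ----
struct Pop {
  int L = 0;
  long gen = 0;
  int tracked = -1;                      // focal derived-allele position, -1 if none
  std::vector<std::vector<int>> pool;    // sorted derived positions
  std::vector<int> refcnt;
  std::vector<char> carries;             // pool entry carries tracked allele
  std::vector<int> freelist;
  std::vector<int> hap;                  // 2N pool indices
  std::unordered_map<int, long> origin;  // position -> origin generation

  int n_hap() const { return (int)hap.size(); }
  int n_ind() const { return (int)hap.size() / 2; }

  int alloc() {
    if (!freelist.empty()) {
      int i = freelist.back();
      freelist.pop_back();
      return i;
    }
    pool.emplace_back();
    refcnt.push_back(0);
    carries.push_back(0);
    return (int)pool.size() - 1;
  }
  inline void retain(int i) { ++refcnt[i]; }
  inline void release(int i) {
    if (--refcnt[i] == 0) {
      pool[i].clear();
      carries[i] = 0;
      freelist.push_back(i);
    }
  }
  void set_tracked(int pos) {
    tracked = pos;
    for (size_t i = 0; i < pool.size(); ++i)
      carries[i] = (refcnt[i] > 0) && pos >= 0 &&
        std::binary_search(pool[i].begin(), pool[i].end(), pos);
  }
  long tracked_count() const {
    if (tracked < 0) return 0;
    long c = 0;
    for (int h : hap) c += carries[h];
    return c;
  }
};

struct Snapshot {
  std::vector<int> hap;
  long gen;
  int tracked;
  std::unordered_map<int, long> origin;
};

static Snapshot take_snapshot(Pop& P) {
  Snapshot s;
  s.hap = P.hap;
  s.gen = P.gen;
  s.tracked = P.tracked;
  s.origin = P.origin;
  for (int h : s.hap) P.retain(h);
  return s;
}

static void restore_snapshot(Pop& P, const Snapshot& s) {
  for (int h : P.hap) P.release(h);
  P.hap = s.hap;
  for (int h : P.hap) P.retain(h);
  P.gen = s.gen;
  P.origin = s.origin;
  P.set_tracked(s.tracked);
}

static void drop_snapshot(Pop& P, Snapshot& s) {
  for (int h : s.hap) P.release(h);
  s.hap.clear();
}

// Count references of each pool entry in the current generation, then tally
// per-position derived counts into a flat array indexed by position.
static void count_positions(Pop& P, std::vector<long>& uses,
                            std::vector<long>& cnt) {
  uses.assign(P.pool.size(), 0);
  for (int h : P.hap) ++uses[h];
  cnt.assign(P.L, 0);
  for (size_t e = 0; e < P.pool.size(); ++e)
    if (uses[e] > 0)
      for (int pos : P.pool[e]) cnt[pos] += uses[e];
}

// Remove bookkeeping for variants that are lost, and strip variants fixed in
// the whole population (they become part of the ancestral background; their
// positions are freed for reuse). Never called while a snapshot is held.
static void prune(Pop& P) {
  static thread_local std::vector<long> uses, cnt;
  count_positions(P, uses, cnt);
  long tot = P.n_hap();
  std::vector<int> fixed;
  for (auto it = P.origin.begin(); it != P.origin.end();) {
    long c = cnt[it->first];
    if (c == 0) {
      it = P.origin.erase(it);
    } else if (c == tot && it->first != P.tracked) {
      fixed.push_back(it->first);
      it = P.origin.erase(it);
    } else {
      ++it;
    }
  }
  if (!fixed.empty()) {
    std::sort(fixed.begin(), fixed.end());
    for (size_t e = 0; e < P.pool.size(); ++e) {
      if (uses[e] == 0) continue;
      auto& v = P.pool[e];
      v.erase(std::remove_if(v.begin(), v.end(), [&](int p) {
        return std::binary_search(fixed.begin(), fixed.end(), p);
      }), v.end());
    }
  }
}

// Snapshot-safe partial prune used inside fixation-conditioned phases:
// frees positions of variants lost since the phase began (they cannot be in
// the snapshot), but never strips fixed variants from (possibly shared)
// haplotype vectors.
static void prune_lost(Pop& P, const Snapshot& snap) {
  static thread_local std::vector<long> uses, cnt;
  count_positions(P, uses, cnt);
  for (auto it = P.origin.begin(); it != P.origin.end();) {
    if (cnt[it->first] == 0 && !snap.origin.count(it->first))
      it = P.origin.erase(it);
    else
      ++it;
  }
}

// ------------------------------------------------------------- gametes ----
// Build one transmitted gamete from diploid parent `par` with `ncross`
// crossovers and `nmut` new mutations. Returns a pool index (retained once).
static int make_gamete(Pop& P, Xoshiro& rng, int par, int ncross, int nmut,
                       long gen_next, bool useA) {
  int hA = P.hap[2 * par], hB = P.hap[2 * par + 1];
  if (!useA) std::swap(hA, hB);
  if (ncross == 0 && nmut == 0) {
    P.retain(hA);
    return hA;
  }
  int ns = P.alloc();
  std::vector<int>& out = P.pool[ns];
  out.clear();
  if (ncross == 0) {
    out = P.pool[hA];
  } else {
    std::vector<int> bps(ncross);
    for (int i = 0; i < ncross; ++i) bps[i] = 1 + (int)rng.bounded(P.L - 1);
    std::sort(bps.begin(), bps.end());
    const std::vector<int>* src[2] = { &P.pool[hA], &P.pool[hB] };
    out.reserve(src[0]->size() + nmut + 8);
    int cur = 0, prev = 0;
    bps.push_back(P.L);
    for (int bp : bps) {
      const std::vector<int>& sv = *src[cur];
      auto lo = std::lower_bound(sv.begin(), sv.end(), prev);
      auto hi = std::lower_bound(lo, sv.end(), bp);
      out.insert(out.end(), lo, hi);
      cur ^= 1;
      prev = bp;
    }
  }
  for (int m = 0; m < nmut; ++m) {
    int pos;
    do { pos = (int)rng.bounded(P.L); } while (P.origin.count(pos));
    P.origin[pos] = gen_next;
    out.insert(std::lower_bound(out.begin(), out.end(), pos), pos);
  }
  P.refcnt[ns] = 1;
  P.carries[ns] = (P.tracked >= 0) &&
    std::binary_search(out.begin(), out.end(), P.tracked);
  return ns;
}

// ---------------------------------------------------------- generation ----
// One reproduction step producing 2*next_N haplotype slots.
//   sel_s > 0 : diploid fitness 1 : 1+hs : 1+s on the tracked genotype.
//   psi_k > 0 : one m2-carrier individual ("sweepstakes parent") transmits
//               exactly psi_k gametes (one per offspring individual for the
//               first psi_k individuals); it is excluded from the ordinary
//               parent pool for that generation, mirroring its placement in
//               a separate subpopulation.
static void do_generation(Pop& P, Xoshiro& rng, int next_N, double mu,
                          double rho, double sel_s, double sel_h, int psi_k) {
  int curN = P.n_ind();
  int slots = 2 * next_N;
  long gen_next = P.gen + 1;

  static thread_local std::vector<uint8_t> mut_cnt, cross_cnt;
  mut_cnt.assign(slots, 0);
  cross_cnt.assign(slots, 0);
  {
    int M = rng.poisson((double)slots * mu * P.L);
    for (int i = 0; i < M; ++i) {
      int s = rng.bounded(slots);
      if (mut_cnt[s] < 255) ++mut_cnt[s];
    }
    int C = rng.poisson((double)slots * rho * (P.L - 1));
    for (int i = 0; i < C; ++i) {
      int s = rng.bounded(slots);
      if (cross_cnt[s] < 255) ++cross_cnt[s];
    }
  }

  // selection: cumulative fitness over parent individuals
  std::vector<double> cum;
  double wtot = 0.0;
  bool weighted = sel_s > 0.0 && P.tracked >= 0;
  if (weighted) {
    cum.resize(curN);
    for (int i = 0; i < curN; ++i) {
      int g = P.carries[P.hap[2 * i]] + P.carries[P.hap[2 * i + 1]];
      double w = g == 0 ? 1.0 : (g == 1 ? 1.0 + sel_h * sel_s : 1.0 + sel_s);
      wtot += w;
      cum[i] = wtot;
    }
  }

  int psi_parent = -1;
  if (psi_k > 0) {
    std::vector<int> carriers;
    for (int i = 0; i < curN; ++i)
      if (P.carries[P.hap[2 * i]] || P.carries[P.hap[2 * i + 1]])
        carriers.push_back(i);
    if (carriers.empty())
      stop("psi generation requires a segregating m2 carrier");
    psi_parent = carriers[rng.bounded((uint32_t)carriers.size())];
  }

  auto pick_parent = [&](int exclude) -> int {
    if (weighted) {
      for (;;) {
        double u = rng.unif() * wtot;
        int p = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
        if (p >= curN) p = curN - 1;
        if (p != exclude) return p;
      }
    }
    if (exclude < 0) return (int)rng.bounded(curN);
    int p = (int)rng.bounded(curN - 1);
    return p >= exclude ? p + 1 : p;
  };

  std::vector<int> newhap(slots);
  int exclude = psi_k > 0 ? psi_parent : -1;
  if (psi_k > 0 && curN < 3)
    stop("psi generation requires at least three individuals");
  uint64_t bitbuf = 0;
  int bitcnt = 0;
  auto next_bit = [&]() -> bool {
    if (bitcnt == 0) { bitbuf = rng.next(); bitcnt = 64; }
    --bitcnt;
    bool b = bitbuf & 1;
    bitbuf >>= 1;
    return b;
  };
  bool plain = !weighted && exclude < 0;
  for (int j = 0; j < next_N; ++j) {
    int pa, pb;
    if (plain) {
      pa = (int)rng.bounded(curN);
      pb = pa + 1 + (int)rng.bounded(curN - 1);  // uniform over parents != pa
      if (pb >= curN) pb -= curN;
    } else {
      pa = pick_parent(exclude);
      do { pb = pick_parent(exclude); } while (pb == pa);
    }
    int srcA = (j < psi_k) ? psi_parent : pa;
    newhap[2 * j] = make_gamete(P, rng, srcA, cross_cnt[2 * j],
                                mut_cnt[2 * j], gen_next, next_bit());
    newhap[2 * j + 1] = make_gamete(P, rng, pb, cross_cnt[2 * j + 1],
                                    mut_cnt[2 * j + 1], gen_next, next_bit());
  }
  for (int h : P.hap) P.release(h);
  P.hap.swap(newhap);
  P.gen = gen_next;
}

// -------------------------------------------------- phases & scenarios ----
static void introduce_tracked(Pop& P, Xoshiro& rng, int pos) {
  // place the focal mutation at `pos`; nudge right past occupied positions
  while (P.origin.count(pos)) pos = (pos + 1) % P.L;
  int slot = rng.bounded((uint32_t)P.n_hap());
  int old = P.hap[slot];
  int ns = P.alloc();
  P.pool[ns] = P.pool[old];
  auto& v = P.pool[ns];
  v.insert(std::lower_bound(v.begin(), v.end(), pos), pos);
  P.refcnt[ns] = 1;
  P.release(old);
  P.hap[slot] = ns;
  P.origin[pos] = P.gen;
  P.set_tracked(pos);
}

static void neutral_gens(Pop& P, Xoshiro& rng, long gens, double mu,
                         double rho, int prune_every = 128) {
  int N = P.n_ind();
  for (long g = 0; g < gens; ++g) {
    do_generation(P, rng, N, mu, rho, 0.0, 0.0, 0);
    if (prune_every > 0 && (P.gen % prune_every) == 0) prune(P);
  }
}

// Iterate either a selective sweep (mode 1) or a psi episode (mode 2) until
// the focal allele fixes; losses restore the pre-episode state and restart
// with a fresh focal mutation. Returns generations in the successful episode.
struct PhaseResult { long phase_length; int restarts; };

static PhaseResult run_phase(Pop& P, Xoshiro& rng, int mode, double mu,
                             double rho, double s, double h, double psi,
                             int pos, int max_restarts) {
  int N = P.n_ind();
  int psi_k = mode == 2 ? (int)std::lround(2.0 * N * psi) : 0;
  Snapshot snap = take_snapshot(P);
  int restarts = 0;
  for (;;) {
    introduce_tracked(P, rng, pos);
    long start_gen = P.gen;
    long count = 1;  // one copy just introduced
    while (count > 0 && count < P.n_hap()) {
      if (mode == 1)
        do_generation(P, rng, N, mu, rho, s, h, 0);
      else
        do_generation(P, rng, N, mu, rho, 0.0, 0.0, psi_k);
      count = P.tracked_count();
      if ((P.gen % 64) == 0) prune_lost(P, snap);
    }
    if (count == P.n_hap()) {
      // the tracked allele stays set (fixed, frequency 1); prune skips it
      PhaseResult r{ P.gen - start_gen, restarts };
      drop_snapshot(P, snap);
      prune(P);
      return r;
    }
    if (++restarts > max_restarts) {
      drop_snapshot(P, snap);
      stop("fixation conditioning exceeded %d restarts", max_restarts);
    }
    restore_snapshot(P, snap);
  }
}

static void bottleneck_downsample(Pop& P, Xoshiro& rng, int Nb) {
  int curN = P.n_ind();
  std::vector<int> idx(curN);
  for (int i = 0; i < curN; ++i) idx[i] = i;
  for (int i = 0; i < Nb; ++i) {
    int j = i + rng.bounded(curN - i);
    std::swap(idx[i], idx[j]);
  }
  std::vector<int> newhap(2 * Nb);
  for (int i = 0; i < Nb; ++i) {
    newhap[2 * i] = P.hap[2 * idx[i]];
    newhap[2 * i + 1] = P.hap[2 * idx[i] + 1];
    P.retain(newhap[2 * i]);
    P.retain(newhap[2 * i + 1]);
  }
  for (int h : P.hap) P.release(h);
  P.hap.swap(newhap);
}

// ------------------------------------------------------------ sampling ----
static List sample_matrix(Pop& P, Xoshiro& rng, int n, int start, int end) {
  int tot = P.n_hap();
  std::vector<int> idx(tot);
  for (int i = 0; i < tot; ++i) idx[i] = i;
  for (int i = 0; i < n; ++i) {
    int j = i + rng.bounded(tot - i);
    std::swap(idx[i], idx[j]);
  }
  std::unordered_map<int, int> cnt;
  for (int i = 0; i < n; ++i)
    for (int pos : P.pool[P.hap[idx[i]]])
      if (pos >= start && pos < end) ++cnt[pos];
  std::vector<int> keep;
  for (auto& kv : cnt)
    if (kv.second > 0 && kv.second < n) keep.push_back(kv.first);
  std::sort(keep.begin(), keep.end());
  int S = (int)keep.size();
  IntegerMatrix M(n, S);
  for (int i = 0; i < n; ++i) {
    const std::vector<int>& v = P.pool[P.hap[idx[i]]];
    for (int j = 0; j < S; ++j)
      M(i, j) = std::binary_search(v.begin(), v.end(), keep[j]) ? 1 : 0;
  }
  return List::create(_["matrix"] = M,
                      _["positions"] = IntegerVector(keep.begin(), keep.end()));
}

// -------------------------------------------------------- R conversion ----
static List pop_to_list(Pop& P) {
  int n = P.n_hap();
  List haps(n);
  for (int i = 0; i < n; ++i) {
    const std::vector<int>& v = P.pool[P.hap[i]];
    haps[i] = IntegerVector(v.begin(), v.end());
  }
  std::vector<std::pair<int, long>> vars(P.origin.begin(), P.origin.end());
  std::sort(vars.begin(), vars.end());
  IntegerVector pos(vars.size()), org(vars.size());
  for (size_t i = 0; i < vars.size(); ++i) {
    pos[i] = vars[i].first;
    org[i] = (int)vars[i].second;
  }
  return List::create(_["generation"] = (double)P.gen,
                      _["L"] = P.L,
                      _["haplotypes"] = haps,
                      _["variant_pos"] = pos,
                      _["variant_origin"] = org,
                      _["tracked"] = P.tracked);
}

static void pop_from_list(Pop& P, List st) {
  P.L = as<int>(st["L"]);
  P.gen = (long)as<double>(st["generation"]);
  List haps = st["haplotypes"];
  int n = haps.size();
  P.pool.clear(); P.refcnt.clear(); P.carries.clear();
  P.freelist.clear(); P.hap.clear(); P.origin.clear();
  P.tracked = as<int>(st["tracked"]);
  P.hap.resize(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = haps[i];
    int ns = P.alloc();
    P.pool[ns].assign(v.begin(), v.end());
    P.refcnt[ns] = 1;
    P.hap[i] = ns;
  }
  IntegerVector pos = st["variant_pos"], org = st["variant_origin"];
  for (int i = 0; i < pos.size(); ++i) P.origin[pos[i]] = org[i];
  P.set_tracked(P.tracked);
}

// ------------------------------------------------------------- exports ----

// [[Rcpp::export]]
IntegerVector cpp_derive_seeds(double seed, int n) {
  Xoshiro rng((uint64_t)seed);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (int)(rng.next() >> 33);  // < 2^31
  return out;
}

// [[Rcpp::export]]
List cpp_pop_new(int N, int L) {
  Pop P;
  P.L = L;
  for (int i = 0; i < 2 * N; ++i) {
    int ns = P.alloc();
    P.refcnt[ns] = 1;
    P.hap.push_back(ns);
  }
  return pop_to_list(P);
}

// [[Rcpp::export]]
List cpp_pop_evolve(List st, double gens, double mu, double rho, double seed) {
  Pop P;
  pop_from_list(P, st);
  Xoshiro rng((uint64_t)seed);
  neutral_gens(P, rng, (long)gens, mu, rho);
  prune(P);
  return pop_to_list(P);
}

// [[Rcpp::export]]
List cpp_pop_step(List st, int next_N, double mu, double rho, double sel_s,
                  double sel_h, int psi_k, double seed) {
  Pop P;
  pop_from_list(P, st);
  Xoshiro rng((uint64_t)seed);
  do_generation(P, rng, next_N, mu, rho, sel_s, sel_h, psi_k);
  prune(P);  // keep long generation-by-generation loops bounded
  return pop_to_list(P);
}

// [[Rcpp::export]]
List cpp_pop_introduce(List st, int pos, double seed) {
  Pop P;
  pop_from_list(P, st);
  Xoshiro rng((uint64_t)seed);
  introduce_tracked(P, rng, pos);
  return pop_to_list(P);
}

// [[Rcpp::export]]
List cpp_pop_run_phase(List st, int mode, double mu, double rho, double s,
                       double h, double psi, int pos, int max_restarts,
                       double seed) {
  Pop P;
  pop_from_list(P, st);
  Xoshiro rng((uint64_t)seed);
  PhaseResult r = run_phase(P, rng, mode, mu, rho, s, h, psi, pos,
                            max_restarts);
  return List::create(_["state"] = pop_to_list(P),
                      _["phase_length"] = (double)r.phase_length,
                      _["restarts"] = r.restarts);
}

// [[Rcpp::export]]
List cpp_pop_bottleneck(List st, int Nb, double seed) {
  Pop P;
  pop_from_list(P, st);
  Xoshiro rng((uint64_t)seed);
  bottleneck_downsample(P, rng, Nb);
  prune(P);
  return pop_to_list(P);
}

// [[Rcpp::export]]
List cpp_pop_sample(List st, int n, int start, int end, double seed) {
  Pop P;
  pop_from_list(P, st);
  Xoshiro rng((uint64_t)seed);
  return sample_matrix(P, rng, n, start, end);
}

// [[Rcpp::export]]
double cpp_pop_tracked_freq(List st) {
  Pop P;
  pop_from_list(P, st);
  if (P.tracked < 0) return NA_REAL;
  return (double)P.tracked_count() / P.n_hap();
}

// Fused single-replicate pipeline: burn-in -> optional bottleneck ->
// scenario (neutral | sweep | psi episode) -> optional post-event neutral
// generations -> haplotype sample. Avoids R round-trips in bulk simulation.
// scenario: 0 = neutral, 1 = sweep, 2 = psi episode
// [[Rcpp::export]]
List cpp_simulate_replicate(int N, double mu, double rho, int L,
                            double burnin_gens, double beta,
                            double bn_duration, int scenario, double s,
                            double h, double psi, int focal_pos, double tau,
                            int n_sample, int max_restarts, double seed) {
  Pop P;
  P.L = L;
  for (int i = 0; i < 2 * N; ++i) {
    int ns = P.alloc();
    P.refcnt[ns] = 1;
    P.hap.push_back(ns);
  }
  Xoshiro rng((uint64_t)seed);
  neutral_gens(P, rng, (long)burnin_gens, mu, rho);

  if (beta < 1.0) {
    int Nb = (int)std::lround(beta * N);
    if (Nb < 2) stop("bottleneck size round(beta*N) below 2");
    bottleneck_downsample(P, rng, Nb);
    for (long g = 0; g < (long)bn_duration; ++g)
      do_generation(P, rng, Nb, mu, rho, 0.0, 0.0, 0);
    do_generation(P, rng, N, mu, rho, 0.0, 0.0, 0);  // instantaneous recovery
    prune(P);
  }

  double phase_length = NA_REAL;
  int restarts = 0;
  if (scenario == 1) {
    PhaseResult r = run_phase(P, rng, 1, mu, rho, s, h, 0.0, focal_pos,
                              max_restarts);
    phase_length = (double)r.phase_length;
    restarts = r.restarts;
  } else if (scenario == 2) {
    PhaseResult r = run_phase(P, rng, 2, mu, rho, 0.0, 0.0, psi, focal_pos,
                              max_restarts);
    phase_length = (double)r.phase_length;
    restarts = r.restarts;
  }
  P.set_tracked(-1);  // fixed focal allele becomes ordinary background
  if (tau > 0) neutral_gens(P, rng, (long)tau, mu, rho);
  prune(P);

  List samp = sample_matrix(P, rng, n_sample, 0, L);
  return List::create(_["matrix"] = samp["matrix"],
                      _["positions"] = samp["positions"],
                      _["generation"] = (double)P.gen,
                      _["phase_length"] = phase_length,
                      _["restarts"] = restarts);
}
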
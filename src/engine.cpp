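// Event-based simulation core for frequency-dependent cultural transmission.
//
// The core loop is deliberately self-contained: it uses its own counter-based
// RNG (xoshiro256++) rather than R's global stream so that every simulation
// in an ABC rejection run is an independent substream.  This makes the
// rejection loop invariant to execution order (serial, chunked or parallel)
// given the same per-draw seeds, and lets a run be resumed from a serialized
// RNG state (32 raw bytes) for exact pool chaining across engine calls.

#include <Rcpp.h>
#include <cstring>
#include <deque>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline uint64_t rotl64(uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

struct EngineRNG {
  uint64_t s[4];

  void seed(uint64_t sd) {
    // splitmix64 expansion of a single seed into the 256-bit state
    uint64_t z = sd;
    for (int i = 0; i < 4; i++) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }

  uint64_t next() {
    uint64_t r = rotl64(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl64(s[3], 45);
    return r;
  }

  // uniform on (0,1); 53-bit resolution, never exactly 0 or 1
  double unif() {
    return (double)((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  int below(int n) { // integer in [0, n)
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }

  double norm() {
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    return u * std::sqrt(-2.0 * std::log(s2) / s2);
  }

  // Marsaglia-Tsang; boosted for shape < 1
  double gamma(double shape) {
    if (shape < 1.0) {
      double u = unif();
      return gamma(shape + 1.0) * std::pow(u, 1.0 / shape);
    }
    double d = shape - 1.0 / 3.0;
    double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x, v;
      do {
        x = norm();
        v = 1.0 + c * x;
      } while (v <= 0.0);
      v = v * v * v;
      double u = unif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
    }
  }
};

static void rng_restore(EngineRNG &rng, Nullable<RawVector> state, double seed) {
  if (state.isNotNull()) {
    RawVector rv(state);
    if (rv.size() != 32) stop("rng state must be 32 raw bytes");
    std::memcpy(rng.s, RAW(rv), 32);
  } else {
    rng.seed((uint64_t)seed);
  }
}

static RawVector rng_save(const EngineRNG &rng) {
  RawVector rv(32);
  std::memcpy(RAW(rv), rng.s, 32);
  return rv;
}

// Multiset of the variants of the last w production events, with type counts
// kept incrementally and a compact list of the types currently present.
struct Pool {
  std::vector<int> counts;           // by type id
  std::vector<int> active;           // ids with count > 0
  std::vector<int> pos;              // id -> index in active, -1 if absent
  std::deque<std::vector<int>> ring; // stamped event outputs, oldest first
  std::vector<int> loose;            // unmarked entries (Dirichlet-seeded)
  long total = 0;

  void ensure(int id) {
    if ((int)counts.size() <= id) {
      counts.resize(id + 1, 0);
      pos.resize(id + 1, -1);
    }
  }
  void inc(int id) {
    ensure(id);
    if (counts[id]++ == 0) {
      pos[id] = (int)active.size();
      active.push_back(id);
    }
    total++;
  }
  void dec(int id) {
    if (--counts[id] == 0) {
      int i = pos[id];
      int last = active.back();
      active[i] = last;
      pos[last] = i;
      active.pop_back();
      pos[id] = -1;
    }
    total--;
  }
};

// type-count weights m^(1 - b), tabulated by integer count; log-space with a
// clamped exponent so extreme |b| saturates instead of overflowing
struct WeightTable {
  std::vector<double> tab;
  double a = 1.0;
  void set_b(double b) {
    a = 1.0 - b;
    tab.clear();
    tab.push_back(0.0); // count 0
  }
  double wt(int c) {
    while ((int)tab.size() <= c) {
      double e = a * std::log((double)tab.size());
      if (e > 700.0) e = 700.0;
      if (e < -700.0) e = -700.0;
      tab.push_back(std::exp(e));
    }
    return tab[c];
  }
};

struct Engine {
  Pool pool;
  WeightTable wtab;
  EngineRNG rng;
  int next_id;
  std::vector<double> cw; // cumulative weights buffer

  // one production event: v items, each an innovation (prob mu) or a copy
  // drawn with probability proportional to count^(1-b) over the pool
  void event(int v, double mu, int w, int del, std::vector<int> &out) {
    out.clear();
    int k = (int)pool.active.size();
    double W = 0.0;
    if (mu < 1.0) {
      if (pool.total == 0)
        stop("sampling pool is empty: seed the pool before transmission");
      cw.resize(k);
      for (int i = 0; i < k; i++) {
        W += wtab.wt(pool.counts[pool.active[i]]);
        cw[i] = W;
      }
    }
    for (int t = 0; t < v; t++) {
      if (mu > 0.0 && rng.unif() < mu) {
        out.push_back(next_id++);
      } else {
        double u = rng.unif() * W;
        int lo = 0, hi = k - 1;
        while (lo < hi) {
          int mid = (lo + hi) / 2;
          if (cw[mid] > u) hi = mid; else lo = mid + 1;
        }
        out.push_back(pool.active[lo]);
      }
    }
    // advance the sliding window
    pool.ring.push_back(out);
    for (int id : out) pool.inc(id);
    while ((int)pool.ring.size() > w) {
      for (int id : pool.ring.front()) pool.dec(id);
      pool.ring.pop_front();
    }
    // displace unmarked (chronology-free) initial entries, del per event
    int nd = (int)pool.loose.size();
    if (nd > 0) {
      if (del < nd) nd = del;
      for (int d = 0; d < nd; d++) {
        int j = rng.below((int)pool.loose.size());
        pool.dec(pool.loose[j]);
        pool.loose[j] = pool.loose.back();
        pool.loose.pop_back();
      }
    }
  }
};

// sample n without replacement from tokens (modified in place), tally by type
static void sample_tokens(std::vector<int> &tokens, int n, EngineRNG &rng,
                          std::vector<int> &tally, int n_types) {
  tally.assign(n_types, 0);
  int N = (int)tokens.size();
  for (int i = 0; i < n; i++) {
    int j = i + rng.below(N - i);
    std::swap(tokens[i], tokens[j]);
    tally[tokens[i]]++;
  }
}

static List sparse_counts(const std::vector<int> &tally) {
  int nz = 0;
  for (int c : tally) if (c > 0) nz++;
  IntegerVector ids(nz), cnt(nz);
  int j = 0;
  for (int i = 0; i < (int)tally.size(); i++) {
    if (tally[i] > 0) { ids[j] = i; cnt[j] = tally[i]; j++; }
  }
  return List::create(_["id"] = ids, _["count"] = cnt);
}

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(int n_seed_types, List init_events, IntegerVector init_loose,
                int del_per_event, int burn_in, int v_burn,
                IntegerVector eta, List v_sched,
                NumericVector mu, NumericVector b, IntegerVector w,
                IntegerVector n_sample, bool retain_pop,
                IntegerVector track_ids, bool sparse_out,
                Nullable<RawVector> rng_state, double seed) {
  int P = eta.size();
  if (v_sched.size() != P || mu.size() != P || b.size() != P ||
      w.size() != P || n_sample.size() != P)
    stop("per-phase argument length mismatch");

  Engine eng;
  rng_restore(eng.rng, rng_state, seed);
  eng.next_id = n_seed_types;

  // seed the pool: stamped event groups (oldest first) and unmarked tokens
  for (int e = 0; e < init_events.size(); e++) {
    IntegerVector ev = init_events[e];
    std::vector<int> grp(ev.begin(), ev.end());
    for (int id : grp) {
      if (id >= eng.next_id) eng.next_id = id + 1;
      eng.pool.inc(id);
    }
    eng.pool.ring.push_back(std::move(grp));
  }
  for (int i = 0; i < init_loose.size(); i++) {
    int id = init_loose[i];
    if (id >= eng.next_id) eng.next_id = id + 1;
    eng.pool.inc(id);
    eng.pool.loose.push_back(id);
  }

  std::vector<int> out;
  if (burn_in > 0) {
    eng.wtab.set_b(b[0]);
    for (int t = 0; t < burn_in; t++)
      eng.event(v_burn, mu[0], w[0], del_per_event, out);
  }

  List samples(P), populations(P);
  IntegerMatrix tracked(track_ids.size(), P);
  std::vector<int> pop, tally;

  for (int p = 0; p < P; p++) {
    eng.wtab.set_b(b[p]);
    IntegerVector vs = v_sched[p];
    if (vs.size() != eta[p]) stop("v schedule length must equal eta");
    pop.clear();
    for (int t = 0; t < eta[p]; t++) {
      eng.event(vs[t], mu[p], w[p], del_per_event, out);
      pop.insert(pop.end(), out.begin(), out.end());
    }
    int Np = (int)pop.size();
    if (n_sample[p] > Np)
      stop("sample size exceeds population size; recovery rate r must be >= 1");
    if (retain_pop) {
      tally.assign(eng.next_id, 0);
      for (int id : pop) tally[id]++;
      populations[p] = sparse_counts(tally);
    }
    sample_tokens(pop, n_sample[p], eng.rng, tally, eng.next_id);
    for (int i = 0; i < track_ids.size(); i++) {
      int id = track_ids[i];
      tracked(i, p) = (id < (int)tally.size()) ? tally[id] : 0;
    }
    if (sparse_out) samples[p] = sparse_counts(tally);
  }

  List final_events(eng.pool.ring.size());
  for (int e = 0; e < (int)eng.pool.ring.size(); e++)
    final_events[e] = IntegerVector(eng.pool.ring[e].begin(), eng.pool.ring[e].end());

  return List::create(
      _["samples"] = samples,
      _["populations"] = retain_pop ? (SEXP)populations : R_NilValue,
      _["tracked"] = tracked,
      _["final_events"] = final_events,
      _["final_loose"] = IntegerVector(eng.pool.loose.begin(), eng.pool.loose.end()),
      _["next_id"] = eng.next_id,
      _["rng_state"] = rng_save(eng.rng));
}

// Dirichlet-multinomial reconstruction of a plausible initial sampling pool
// from observed counts, under the constraint that every observed type is
// present.  Default enforcement is rejection (regenerate the draw); after
// max_retry failures missing types are force-inserted over random tokens of
// non-singleton types.
// [[Rcpp::export(name = ".engine_dirichlet_pool")]]
List engine_dirichlet_pool(NumericVector alpha, int pool_size, int max_retry,
                           Nullable<RawVector> rng_state, double seed) {
  int K = alpha.size();
  if (pool_size < K)
    stop("pool size w*v1 is smaller than the number of observed types");
  EngineRNG rng;
  rng_restore(rng, rng_state, seed);

  IntegerVector tokens(pool_size);
  if (pool_size == K) {
    // the constraint forces exactly one token per type
    for (int i = 0; i < K; i++) tokens[i] = i;
    return List::create(_["tokens"] = tokens, _["forced"] = false,
                        _["rng_state"] = rng_save(rng));
  }

  std::vector<double> cp(K);
  std::vector<int> tally(K);
  bool ok = false, forced = false;
  for (int attempt = 0; attempt <= max_retry && !ok; attempt++) {
    double tot = 0.0;
    for (int i = 0; i < K; i++) {
      cp[i] = rng.gamma(alpha[i]);
      tot += cp[i];
    }
    double acc = 0.0;
    for (int i = 0; i < K; i++) { acc += cp[i] / tot; cp[i] = acc; }
    cp[K - 1] = 1.0;
    std::fill(tally.begin(), tally.end(), 0);
    for (int t = 0; t < pool_size; t++) {
      double u = rng.unif();
      int lo = 0, hi = K - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cp[mid] > u) hi = mid; else lo = mid + 1;
      }
      tokens[t] = lo;
      tally[lo]++;
    }
    ok = true;
    for (int i = 0; i < K; i++) if (tally[i] == 0) { ok = false; break; }
  }
  if (!ok) {
    forced = true;
    for (int i = 0; i < K; i++) {
      while (tally[i] == 0) {
        int j = rng.below(pool_size);
        if (tally[tokens[j]] > 1) {
          tally[tokens[j]]--;
          tokens[j] = i;
          tally[i]++;
        }
      }
    }
  }
  return List::create(_["tokens"] = tokens, _["forced"] = forced,
                      _["rng_state"] = rng_save(rng));
}
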
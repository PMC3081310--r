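#include <Rcpp.h>
#include <vector>
#include <numeric>
#include <cmath>
using namespace Rcpp;

// Full-run engine. Consumes R's global RNG stream draw-for-draw identically
// to the pure-R reference (seed_population + advance_time_step), which the
// test suite relies on: per organism seeded, one uniform for the initial
// genome progress; per step, n-1 uniforms for the Fisher-Yates shuffle, then
// per replicating organism up to `rate` iterations of (hydrolysis draw,
// [error draw on success]), per dividing organism at most one sign draw, and
// finally the culling sequence of (accept draw, [victim draw]) pairs.

static inline int rand_index(int n) {
  return (int)(unif_rand() * n);
}

// [[Rcpp::export(name = ".run_engine_cpp")]]
List run_engine_cpp(IntegerVector seed_dir, IntegerVector seed_rate,
                    double temperature, int capacity, int genome_length,
                    int rate_min, int rate_max, double error_tolerance,
                    bool mutation_enabled, double cull_epsilon,
                    int n_steps, int sample_every, bool sqrt_rate_factor) {
  const int L = genome_length;
  const int span = rate_max - rate_min;
  const int nr = span + 1;

  // per-rate probability tables
  std::vector<double> ph_f(nr), ph_r(nr), pe(nr);
  const double hbase = std::exp(-1.0 / temperature);
  const double ebase = std::exp(-2.0 / temperature);
  for (int k = 0; k < nr; ++k) {
    const int r = rate_min + k;
    ph_f[k] = hbase;
    ph_r[k] = std::min(1.0, ((double)rate_max / r) * hbase);
    const double g = sqrt_rate_factor ? std::sqrt((double)r / rate_max)
                                      : (double)r / rate_max;
    pe[k] = mutation_enabled ? ebase * g : 0.0;
  }

  // structure-of-arrays population; state: 0 replicating, 1 dividing
  std::vector<int> dir, rate, copied, errors, state;
  const int reserve = capacity + 4;
  dir.reserve(reserve); rate.reserve(reserve); copied.reserve(reserve);
  errors.reserve(reserve); state.reserve(reserve);

  for (int i = 0; i < seed_dir.size(); ++i) {
    dir.push_back(seed_dir[i]);
    rate.push_back(seed_rate[i]);
    copied.push_back((int)(unif_rand() * L));  // random initial progress
    errors.push_back(0);
    state.push_back(0);
  }

  const int nsamp = n_steps / sample_every + 1;
  IntegerVector s_time(nsamp);
  IntegerVector census_f(nsamp), census_r(nsamp);
  NumericVector mrate_f(nsamp), mrate_r(nsamp);
  NumericVector mrc_f(nsamp), mrc_r(nsamp);

  double wsum[2] = {0.0, 0.0};
  long wcnt[2] = {0, 0};

  std::vector<int> bstep, bdelta, bdir;

  int si = 0;
  // record census/mean-rate/window statistics for the current state
  auto record = [&](int t) {
    long cnt[2] = {0, 0};
    double rsum[2] = {0.0, 0.0};
    for (size_t i = 0; i < dir.size(); ++i) {
      cnt[dir[i]]++;
      rsum[dir[i]] += rate[i];
    }
    s_time[si] = t;
    census_f[si] = (int)cnt[0];
    census_r[si] = (int)cnt[1];
    mrate_f[si] = cnt[0] > 0 ? rsum[0] / cnt[0] : NA_REAL;
    mrate_r[si] = cnt[1] > 0 ? rsum[1] / cnt[1] : NA_REAL;
    mrc_f[si] = wcnt[0] > 0 ? wsum[0] / wcnt[0] : 0.0;
    mrc_r[si] = wcnt[1] > 0 ? wsum[1] / wcnt[1] : 0.0;
    wsum[0] = wsum[1] = 0.0;
    wcnt[0] = wcnt[1] = 0;
    ++si;
  };

  record(0);

  std::vector<int> perm;
  perm.reserve(reserve);

  for (int t = 1; t <= n_steps; ++t) {
    const int n = (int)dir.size();
    perm.resize(n);
    std::iota(perm.begin(), perm.end(), 0);
    for (int i = n; i >= 2; --i) {
      const int j = rand_index(i);
      std::swap(perm[i - 1], perm[j]);
    }

    for (int k = 0; k < n; ++k) {
      const int i = perm[k];
      if (state[i] == 0) {
        const int r = rate[i];
        const int ri = r - rate_min;
        const double ph = dir[i] == 0 ? ph_f[ri] : ph_r[ri];
        const double per = pe[ri];
        for (int it = 0; it < r && copied[i] < L; ++it) {
          if (unif_rand() < ph) {
            if (dir[i] == 0) continue;  // forward: one addition spoiled
            else break;                 // reverse: stalled until next step
          }
          copied[i]++;
          if (unif_rand() < per) errors[i]++;
          if (copied[i] == L) { state[i] = 1; break; }
        }
      } else if ((int)dir.size() < capacity) {
        const int mrate = rate[i];
        int child = mrate;
        if (mutation_enabled) {
          double frac = ((double)errors[i] / L) / error_tolerance;
          if (frac > 1.0) frac = 1.0;
          const int delta = (int)std::floor(span * frac + 0.5);
          if (delta > 0) {
            const int up = mrate + delta, down = mrate - delta;
            const bool up_ok = up <= rate_max, down_ok = down >= rate_min;
            if (up_ok && down_ok) child = unif_rand() < 0.5 ? up : down;
            else if (up_ok) child = up;
            else if (down_ok) child = down;
            else {
              child = unif_rand() < 0.5 ? up : down;
              if (child > rate_max) child = rate_max;
              if (child < rate_min) child = rate_min;
            }
          }
        }
        const int d = dir[i];
        dir.push_back(d); rate.push_back(child);
        copied.push_back(0); errors.push_back(0); state.push_back(0);
        copied[i] = 0; errors[i] = 0; state[i] = 0;
        const int dlt = child - mrate;
        wsum[d] += dlt >= 0 ? dlt : -dlt;
        wcnt[d] += 1;
        bstep.push_back(t); bdir.push_back(d); bdelta.push_back(dlt);
      }
      // dividing at capacity: no change, no draw
    }

    // culling: re-drawn after every removal until the first failure
    for (;;) {
      const int m = (int)dir.size();
      if (m == 0) break;
      double p = 1.0 / (capacity - m + cull_epsilon);
      if (p > 1.0) p = 1.0;
      if (unif_rand() >= p) break;
      const int j = rand_index(m);
      dir[j] = dir.back();       dir.pop_back();
      rate[j] = rate.back();     rate.pop_back();
      copied[j] = copied.back(); copied.pop_back();
      errors[j] = errors.back(); errors.pop_back();
      state[j] = state.back();   state.pop_back();
    }

    if (t % sample_every == 0) record(t);
  }

  return List::create(
    _["time"] = s_time,
    _["census_forward"] = census_f,
    _["census_reverse"] = census_r,
    _["mean_rate_forward"] = mrate_f,
    _["mean_rate_reverse"] = mrate_r,
    _["mean_rate_change_forward"] = mrc_f,
    _["mean_rate_change_reverse"] = mrc_r,
    _["birth_step"] = IntegerVector(bstep.begin(), bstep.end()),
    _["birth_dir"] = IntegerVector(bdir.begin(), bdir.end()),
    _["birth_delta"] = IntegerVector(bdelta.begin(), bdelta.end()),
    _["final_census"] = (int)dir.size());
}
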
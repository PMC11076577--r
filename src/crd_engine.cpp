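#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// splitmix64: seed scrambler, also used to derive per-composition streams
static inline uint64_t sm64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Cfg {
  int N, r, L;                 // players, rounds, |action set|
  std::vector<double> act;     // action values, ascending
  std::vector<double> mid;     // midpoints between consecutive actions
  double E, p, thr;
};

// top-53-bit uniform; avoids implementation-defined std distributions
static inline double u01(std::mt19937_64 &g) {
  return (g() >> 11) * (1.0 / 9007199254740992.0);
}
static inline int runifint(std::mt19937_64 &g, int k) {
  int v = (int)(u01(g) * k);
  return v < k ? v : (k - 1);
}
// uniform over {0..k-1} \ {ex}
static inline int draw_other(std::mt19937_64 &g, int k, int ex) {
  int v = runifint(g, k - 1);
  return v >= ex ? v + 1 : v;
}

// nearest-anchor bin of the co-players' average; exact midpoints go up
static inline int bin_avg(const Cfg &c, double avg) {
  int i = 0;
  while (i < c.L - 1 && avg >= c.mid[i]) ++i;
  return i;
}

// error modes: 0 none, 1 execution, 2 program, 3 delegate
// one-shot pre-game realization of each player's effective profile
static void realize_eff(const Cfg &c, const int *intended, const int *modes,
                        const IntegerMatrix &pool, const int *pool_index,
                        double eps, std::mt19937_64 &g, int *eff) {
  const int W = 1 + c.L;
  for (int i = 0; i < c.N; ++i) {
    const int *src = intended + i * W;
    int *dst = eff + i * W;
    switch (modes[i]) {
    case 2: { // program: each parameter independently perturbed
      for (int t = 0; t < W; ++t) {
        int v = src[t];
        if (eps > 0.0 && u01(g) < eps) v = draw_other(g, c.L, v);
        dst[t] = v;
      }
      break;
    }
    case 3: { // delegate: whole-profile swap within the pool
      int K = pool.nrow();
      int pick = pool_index[i];
      if (eps > 0.0 && u01(g) < eps) pick = draw_other(g, K, pick);
      for (int t = 0; t < W; ++t) dst[t] = pool(pick, t);
      break;
    }
    default:
      for (int t = 0; t < W; ++t) dst[t] = src[t];
    }
  }
}

// one CRD game; contributions simultaneous within a round, threshold checked
// at round end, everyone stops once the target is reached
static void play_one(const Cfg &c, const int *intended, const int *eff,
                     const int *modes, double eps, std::mt19937_64 &g,
                     std::vector<double> &prev, std::vector<double> &cur,
                     double *contrib, double &pub, bool &success, int &rounds,
                     long long &dev, long long &tot, bool track) {
  const int N = c.N, W = 1 + c.L;
  for (int i = 0; i < N; ++i) contrib[i] = 0.0;
  pub = 0.0;
  success = false;
  rounds = 0;
  double prevTot = 0.0;
  for (int k = 0; k < c.r; ++k) {
    for (int i = 0; i < N; ++i) {
      int slot;
      if (k == 0) {
        slot = 0;
      } else {
        double oa = (prevTot - prev[i]) / (double)(N - 1);
        slot = 1 + bin_avg(c, oa);
      }
      int a_int = intended[i * W + slot];
      int emit;
      if (modes[i] == 1) { // execution: fresh draw every round
        emit = a_int;
        if (eps > 0.0 && u01(g) < eps) emit = draw_other(g, c.L, a_int);
      } else {
        emit = eff[i * W + slot];
      }
      if (track) {
        ++tot;
        if (emit != a_int) ++dev;
      }
      double v = c.act[emit];
      cur[i] = v;
      contrib[i] += v;
      pub += v;
    }
    rounds = k + 1;
    std::swap(prev, cur);
    prevTot = 0.0;
    for (int i = 0; i < N; ++i) prevTot += prev[i];
    if (pub >= c.thr) {
      success = true;
      break;
    }
  }
  if (!success) success = (pub >= c.thr);
}

static Cfg make_cfg(int N, int r, const NumericVector &actions, double E,
                    double p, double threshold) {
  Cfg c;
  c.N = N;
  c.r = r;
  c.L = actions.size();
  c.act = as<std::vector<double>>(actions);
  c.mid.resize(c.L - 1);
  for (int i = 0; i < c.L - 1; ++i) c.mid[i] = (c.act[i] + c.act[i + 1]) / 2.0;
  c.E = E;
  c.p = p;
  c.thr = threshold;
  return c;
}

//' @noRd
// [[Rcpp::export]]
List crd_sim_games(IntegerMatrix profiles, IntegerVector modes,
                   NumericVector actions, double E, int r, double p,
                   double threshold, double eps, IntegerMatrix pool,
                   IntegerVector pool_index, int nsim, double seed,
                   bool track_errors) {
  Cfg c = make_cfg(profiles.nrow(), r, actions, E, p, threshold);
  const int N = c.N, W = 1 + c.L;
  std::vector<int> intended(N * W);
  for (int i = 0; i < N; ++i)
    for (int t = 0; t < W; ++t) intended[i * W + t] = profiles(i, t);
  std::vector<int> eff(N * W);
  std::vector<int> md = as<std::vector<int>>(modes);
  std::vector<int> pidx = as<std::vector<int>>(pool_index);
  std::mt19937_64 g(sm64((uint64_t)seed));
  NumericMatrix pay(nsim, N), con(nsim, N);
  NumericVector pub(nsim);
  LogicalVector suc(nsim);
  IntegerVector rds(nsim);
  std::vector<double> prev(N), cur(N), contrib(N);
  long long dev = 0, tot = 0;
  for (int s = 0; s < nsim; ++s) {
    realize_eff(c, intended.data(), md.data(), pool, pidx.data(), eps, g,
                eff.data());
    double pb;
    bool ok;
    int rp;
    play_one(c, intended.data(), eff.data(), md.data(), eps, g, prev, cur,
             contrib.data(), pb, ok, rp, dev, tot, track_errors);
    double fac = ok ? 1.0 : (1.0 - p);
    for (int i = 0; i < N; ++i) {
      con(s, i) = contrib[i];
      pay(s, i) = (E - contrib[i]) * fac;
    }
    pub[s] = pb;
    suc[s] = ok;
    rds[s] = rp;
  }
  double drate = (track_errors && tot > 0) ? (double)dev / (double)tot : NA_REAL;
  return List::create(_["payoffs"] = pay, _["contributions"] = con,
                      _["public_account"] = pub, _["success"] = suc,
                      _["rounds"] = rds, _["deviation_rate"] = drate);
}

//' @noRd
// [[Rcpp::export]]
List crd_pair_table(IntegerVector prof_a, int mode_a, IntegerVector prof_b,
                    int mode_b, NumericVector actions, int N, double E, int r,
                    double p, double threshold, double eps, IntegerMatrix pool,
                    int pool_ia, int pool_ib, int nsim, double seed) {
  Cfg c = make_cfg(N, r, actions, E, p, threshold);
  const int W = 1 + c.L;
  NumericVector pia(N, NA_REAL), pib(N, NA_REAL);
  std::vector<int> intended(N * W), md(N), pidx(N), eff(N * W);
  std::vector<double> prev(N), cur(N), contrib(N);
  long long dev = 0, tot = 0;
  for (int a = 0; a <= N; ++a) { // a = number of A-players in the group
    for (int i = 0; i < N; ++i) {
      bool isA = i < a;
      const IntegerVector &src = isA ? prof_a : prof_b;
      for (int t = 0; t < W; ++t) intended[i * W + t] = src[t];
      md[i] = isA ? mode_a : mode_b;
      pidx[i] = isA ? pool_ia : pool_ib;
    }
    // per-composition child stream: reproducible, order-insensitive
    std::mt19937_64 g(sm64(sm64((uint64_t)seed) ^ (uint64_t)(a + 1)));
    double sumA = 0.0, sumB = 0.0;
    for (int s = 0; s < nsim; ++s) {
      realize_eff(c, intended.data(), md.data(), pool, pidx.data(), eps, g,
                  eff.data());
      double pb;
      bool ok;
      int rp;
      play_one(c, intended.data(), eff.data(), md.data(), eps, g, prev, cur,
               contrib.data(), pb, ok, rp, dev, tot, false);
      double fac = ok ? 1.0 : (1.0 - p);
      for (int i = 0; i < N; ++i) {
        double pay = (c.E - contrib[i]) * fac;
        if (i < a)
          sumA += pay;
        else
          sumB += pay;
      }
    }
    if (a > 0) pia[a - 1] = sumA / ((double)nsim * a); // j = a-1 A co-players
    if (a < N) pib[a] = sumB / ((double)nsim * (N - a)); // j = a A-players
  }
  return List::create(_["pi_a"] = pia, _["pi_b"] = pib);
}
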
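#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Haplotype-copying cohort simulator.
//
// Each haplotype is a binary Markov chain along the variant order: the
// allele at SNP j is drawn from t1[j] / t0[j] (transition probabilities
// given the previous SNP's allele), restarting from the marginal p[j] at
// every chromosome start.  Transition probabilities are precomputed in R
// so that marginals are preserved exactly even where the requested
// adjacent correlation is infeasible for a frequency pair.
//
// Allele draws use an internal xoshiro256++ stream whose state is seeded
// from R's RNG at entry (and the liability noise uses R's norm_rand
// directly), so set.seed() in R fully determines the output.

namespace {

struct SplitMix64 {
  uint64_t x;
  explicit SplitMix64(uint64_t seed) : x(seed) {}
  uint64_t next() {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
};

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    SplitMix64 sm(seed);
    for (int i = 0; i < 4; ++i) s[i] = sm.next();
  }
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// seed the internal stream from R's RNG so set.seed() governs
inline uint64_t seed_from_r() {
  uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
  return (hi << 32) ^ lo ^ 0x8f1bbcdcULL;
}

inline int draw_allele(Xoshiro256pp &rng, int prev, double p, double t1,
                       double t0, bool start) {
  double pr = start ? p : (prev ? t1 : t0);
  return rng.unif() < pr ? 1 : 0;
}

}  // namespace

// Simulate n samples unconditionally (population mode).
// Returns the dosage matrix (copies of allele1) and the genetic value
// G = sum beta_j * (g_j - 2 p_j).
// [[Rcpp::export]]
List sim_population_cpp(int n, NumericVector p, NumericVector t1,
                        NumericVector t0, LogicalVector chrom_start,
                        NumericVector beta) {
  const int m = p.size();
  Xoshiro256pp rng(seed_from_r());
  IntegerMatrix geno(n, m);
  NumericVector G(n);
  for (int i = 0; i < n; ++i) {
    int h1 = 0, h2 = 0;
    double g_i = 0.0;
    for (int j = 0; j < m; ++j) {
      bool st = chrom_start[j];
      h1 = draw_allele(rng, h1, p[j], t1[j], t0[j], st);
      h2 = draw_allele(rng, h2, p[j], t1[j], t0[j], st);
      int g = h1 + h2;
      geno(i, j) = g;
      g_i += beta[j] * (g - 2.0 * p[j]);
    }
    G[i] = g_i;
  }
  return List::create(_["geno"] = geno, _["G"] = G);
}

// Simulate until case/control quotas are met (retrospective sampling).
// Liability L = G + e, e ~ N(0, err_sd^2); case iff L > thresh.
// Genotypes of discarded samples are still drawn, keeping the per-sample
// stream identical whatever the quotas.
// [[Rcpp::export]]
List sim_case_control_cpp(int n_cases, int n_controls, NumericVector p,
                          NumericVector t1, NumericVector t0,
                          LogicalVector chrom_start, NumericVector beta,
                          double err_sd, double thresh, double max_draws) {
  const int m = p.size();
  const int n_keep = n_cases + n_controls;
  Xoshiro256pp rng(seed_from_r());
  IntegerMatrix geno(n_keep, m);
  NumericVector G(n_keep), L(n_keep);
  IntegerVector is_case(n_keep);
  std::vector<int> hap(m);
  int kept_cases = 0, kept_controls = 0, row = 0;
  double drawn = 0.0;

  while (kept_cases < n_cases || kept_controls < n_controls) {
    if (++drawn > max_draws)
      stop("case/control quota unreachable within %.0f population draws "
           "(prevalence too low for the requested quota?)", max_draws);
    double g_i = 0.0;
    int h1 = 0, h2 = 0;
    for (int j = 0; j < m; ++j) {
      bool st = chrom_start[j];
      h1 = draw_allele(rng, h1, p[j], t1[j], t0[j], st);
      h2 = draw_allele(rng, h2, p[j], t1[j], t0[j], st);
      hap[j] = h1 + h2;
      g_i += beta[j] * (hap[j] - 2.0 * p[j]);
    }
    double l_i = g_i + err_sd * norm_rand();
    bool cs = l_i > thresh;
    bool keep = cs ? (kept_cases < n_cases) : (kept_controls < n_controls);
    if (!keep) continue;
    for (int j = 0; j < m; ++j) geno(row, j) = hap[j];
    G[row] = g_i;
    L[row] = l_i;
    is_case[row] = cs ? 1 : 0;
    if (cs) ++kept_cases; else ++kept_controls;
    ++row;
  }
  return List::create(_["geno"] = geno, _["G"] = G, _["L"] = L,
                      _["is_case"] = is_case, _["n_drawn"] = drawn);
}
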
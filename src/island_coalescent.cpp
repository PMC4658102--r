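// Structured-coalescent simulator for a symmetric island model with
// infinite-alleles mutation, used as the neutral null for F_ST outlier
// detection.  d of n_demes demes are sampled at `genes` genes each.  Time
// runs in units of 2N (deme) generations: a pair of lineages in the same
// deme coalesces at rate 1, a lineage migrates at rate M/2 (M = 4Nm) to a
// uniformly chosen other deme, and a lineage mutates at rate u/2.  Under
// infinite alleles the allele of a leaf is fixed by the first mutation on
// its path to the root, so a lineage can be dropped at its first mutation
// after assigning a fresh allele to the leaves it subtends; no genealogy
// needs to be stored.  The surviving alleles are collapsed to biallelic
// (most frequent vs rest), genes are randomly paired into diploids within
// each deme (Hardy-Weinberg), and the function returns, per retained
// locus, the d major-allele gene counts followed by the d heterozygote
// counts.  Loci that are monomorphic or below the He threshold are
// rejected and redrawn (ascertainment); per-locus mutation rates are drawn
// log-uniformly in [u_lo, u_hi] so heterozygosity spans a wide range.
//
// Low target F_ST means high migration rates, so the event loop is
// migration-dominated; a fast local xoshiro256+ generator (seeded from R's
// RNG so set.seed() still governs reproducibility) keeps the per-event
// cost down.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97f4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double runif() {  // uniform in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  inline int iunif(int n) {  // uniform integer in [0, n)
    int k;
    do { k = (int)(runif() * n); } while (k >= n);
    return k;
  }
};

struct Lineage {
  int deme;
  int pos_in_deme;
  int pos_alive;
  std::vector<int> leaves;
};

}  // namespace

// [[Rcpp::export]]
IntegerMatrix island_coalescent_cpp(int n_loci, int d, int genes,
                                    int n_demes, double M, double u_lo,
                                    double u_hi, double he_min) {
  const int n_dip = genes / 2;
  IntegerMatrix out(n_loci, 2 * d);
  const double log_lo = std::log(u_lo), log_hi = std::log(u_hi);
  const long max_attempts = 50L * (long)n_loci + 1000L;
  long attempts = 0;
  int filled = 0;
  Xoshiro rng((uint64_t)(unif_rand() * 9007199254740992.0) + 1ULL);

  std::vector<Lineage> pool((size_t)d * genes);
  std::vector<std::vector<int>> deme_members(n_demes);
  std::vector<int> alive;
  // demes holding >= 2 lineages, for coalescence selection
  std::vector<int> busy;                 // deme ids
  std::vector<int> busy_pos(n_demes, -1);
  std::vector<std::vector<int>> alleles;
  std::vector<int> gene_allele;

  auto busy_update = [&](int deme) {
    size_t k = deme_members[deme].size();
    if (k >= 2 && busy_pos[deme] < 0) {
      busy_pos[deme] = (int)busy.size();
      busy.push_back(deme);
    } else if (k < 2 && busy_pos[deme] >= 0) {
      int last = busy.back();
      busy[busy_pos[deme]] = last;
      busy_pos[last] = busy_pos[deme];
      busy.pop_back();
      busy_pos[deme] = -1;
    }
  };

  while (filled < n_loci) {
    if (++attempts > max_attempts)
      stop("island model could not produce enough polymorphic loci; "
           "widen the mutation range or lower he_min");
    double u = std::exp(log_lo + rng.runif() * (log_hi - log_lo));

    for (int k = 0; k < n_demes; ++k) deme_members[k].clear();
    busy.clear();
    std::fill(busy_pos.begin(), busy_pos.end(), -1);
    alive.clear();
    alleles.clear();
    int L = 0;
    double sumpairs = 0.0;
    for (int k = 0; k < d; ++k) {
      for (int j = 0; j < genes; ++j) {
        Lineage &ln = pool[L];
        ln.deme = k;
        ln.leaves.assign(d, 0);
        ln.leaves[k] = 1;
        ln.pos_in_deme = (int)deme_members[k].size();
        deme_members[k].push_back(L);
        ln.pos_alive = (int)alive.size();
        alive.push_back(L);
        ++L;
      }
      sumpairs += 0.5 * genes * (genes - 1);
      busy_update(k);
    }

    auto remove_from_deme = [&](int id) {
      Lineage &ln = pool[id];
      std::vector<int> &mem = deme_members[ln.deme];
      int last = mem.back();
      mem[ln.pos_in_deme] = last;
      pool[last].pos_in_deme = ln.pos_in_deme;
      mem.pop_back();
      sumpairs -= (double)mem.size();
      busy_update(ln.deme);
    };
    auto add_to_deme = [&](int id, int deme) {
      Lineage &ln = pool[id];
      ln.deme = deme;
      std::vector<int> &mem = deme_members[deme];
      sumpairs += (double)mem.size();
      ln.pos_in_deme = (int)mem.size();
      mem.push_back(id);
      busy_update(deme);
    };
    auto kill = [&](int id) {
      Lineage &ln = pool[id];
      int last = alive.back();
      alive[ln.pos_alive] = last;
      pool[last].pos_alive = ln.pos_alive;
      alive.pop_back();
      --L;
    };

    while (L > 1) {
      double rate_mig = L * M * 0.5;
      double rate_mut = L * u * 0.5;
      double total = rate_mig + rate_mut + sumpairs;
      double r = rng.runif() * total;
      if (r < rate_mig) {
        int id = alive[rng.iunif(L)];
        int nd = rng.iunif(n_demes - 1);
        if (nd >= pool[id].deme) ++nd;
        remove_from_deme(id);
        add_to_deme(id, nd);
      } else if (r < rate_mig + rate_mut) {
        int id = alive[rng.iunif(L)];
        alleles.push_back(pool[id].leaves);
        remove_from_deme(id);
        kill(id);
      } else {
        double s = r - rate_mig - rate_mut;
        int deme = -1;
        for (int bi = 0; bi < (int)busy.size(); ++bi) {
          size_t kk = deme_members[busy[bi]].size();
          s -= 0.5 * (double)kk * (double)(kk - 1);
          if (s <= 0) { deme = busy[bi]; break; }
        }
        if (deme < 0) continue;  // numerical slip; redraw event
        std::vector<int> &mem = deme_members[deme];
        int i1 = rng.iunif((int)mem.size());
        int i2 = rng.iunif((int)mem.size() - 1);
        if (i2 >= i1) ++i2;
        int a = mem[i1], b = mem[i2];
        for (int k = 0; k < d; ++k) pool[a].leaves[k] += pool[b].leaves[k];
        remove_from_deme(b);
        kill(b);
      }
    }
    if (L == 1) alleles.push_back(pool[alive[0]].leaves);

    if (alleles.size() < 2) continue;
    int best = 0, best_tot = -1;
    for (size_t a = 0; a < alleles.size(); ++a) {
      int tot = 0;
      for (int k = 0; k < d; ++k) tot += alleles[a][k];
      if (tot > best_tot) { best_tot = tot; best = (int)a; }
    }
    double pbar = (double)best_tot / (d * genes);
    double he = 2.0 * pbar * (1.0 - pbar);
    if (he < he_min) continue;

    for (int k = 0; k < d; ++k) {
      int c = alleles[best][k];
      out(filled, k) = c;
      gene_allele.assign(genes, 0);
      for (int j = 0; j < c; ++j) gene_allele[j] = 1;
      for (int j = genes - 1; j > 0; --j) {
        int t = rng.iunif(j + 1);
        std::swap(gene_allele[j], gene_allele[t]);
      }
      int het = 0;
      for (int j = 0; j < n_dip; ++j)
        if (gene_allele[2 * j] != gene_allele[2 * j + 1]) ++het;
      out(filled, d + k) = het;
    }
    ++filled;
  }
  return out;
}
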
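#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward-time agent-based simulator of genome-wide conflict between a cabal
// of trait-distorter loci and the commonwealth of dedicated-suppressor loci.
//
// Loci are held sparsely: only activated loci are materialised. Genotypes are
// stored individual-major (one contiguous row of allele strengths per
// individual per haplotype) so that the phenotype scan, meiosis and parental
// reads are all stride-1. Cabal locus i is targeted by commonwealth locus i.
// Discrete mode holds strengths in {0, k} (distorters) and {0, 1}
// (suppressors) with functional/neutral flips; continuous mode lets
// strengths evolve in [0, 1] under a truncated-normal mutation kernel.

static inline double clamp01(double v) {
  return v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
}

static int sample_parent(const std::vector<double> &cum, double tot) {
  double u = unif_rand() * tot;
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// pool of fair coins refilled 16 at a time from one uniform draw
struct CoinPool {
  unsigned int bits;
  int left;
  CoinPool() : bits(0), left(0) {}
  inline bool flip() {
    if (left == 0) {
      bits = (unsigned int)(unif_rand() * 65536.0);
      left = 16;
    }
    bool b = bits & 1u;
    bits >>= 1;
    --left;
    return b;
  }
};

struct HaploSet {  // one haplotype per individual, N rows of capacity cap
  std::vector<double> v;
  int cap;
  void init(int N, int cap_) { cap = cap_; v.assign((size_t)N * cap, 0.0); }
  inline double *row(int i) { return v.data() + (size_t)i * cap; }
  void grow(int N, int newcap) {
    std::vector<double> nv((size_t)N * newcap, 0.0);
    for (int i = 0; i < N; ++i)
      std::copy(v.begin() + (size_t)i * cap, v.begin() + (size_t)i * cap + cap,
                nv.begin() + (size_t)i * newcap);
    v.swap(nv);
    cap = newcap;
  }
};

static int capacity_guess(double expected) {
  double c = expected + 10.0 * std::sqrt(expected > 1 ? expected : 1) + 16.0;
  return (int)c;
}

// [[Rcpp::export]]
List cpp_run_multilocus(int N, int T_end,
                        double cabal_total, double comm_total,
                        double rho_D, double rho_S,
                        bool continuous, double k_fixed, double z,
                        double c_sup, double c_coef, double c_exp,
                        double r_rec,
                        double flip_prob, double mut_prob, double mut_sd) {
  if (N < 2) stop("N must be at least 2");
  int cap_cab = capacity_guess(cabal_total * rho_D * T_end);
  int cap_com = capacity_guess(comm_total * rho_S * T_end);
  HaploSet cab_a, cab_b, com_a, com_b, ocab_a, ocab_b, ocom_a, ocom_b;
  cab_a.init(N, cap_cab); cab_b.init(N, cap_cab);
  ocab_a.init(N, cap_cab); ocab_b.init(N, cap_cab);
  com_a.init(N, cap_com); com_b.init(N, cap_com);
  ocom_a.init(N, cap_com); ocom_b.init(N, cap_com);
  int n_cab = 0, n_comm = 0;
  NumericVector mean_dist(T_end);
  IntegerVector n_cab_trace(T_end), n_comm_trace(T_end);
  std::vector<double> fitness(N), drive_pull(N), cum(N);
  std::vector<int> dloci;
  std::vector<double> kmax_l, own_l;
  long long neg_fitness_events = 0;

  for (int t = 0; t < T_end; ++t) {
    // --- locus activation ---------------------------------------------
    double dormant_cab = cabal_total - (double)n_cab;
    if (dormant_cab > 0.0 && rho_D > 0.0) {
      int new_cab = (int)R::rbinom(dormant_cab, rho_D);
      while (n_cab + new_cab > cap_cab) {
        int nc = cap_cab * 2;
        cab_a.grow(N, nc); cab_b.grow(N, nc);
        ocab_a.grow(N, nc); ocab_b.grow(N, nc);
        cap_cab = nc;
      }
      for (int m = 0; m < new_cab; ++m) {
        int ind = (int)(unif_rand() * N); if (ind >= N) ind = N - 1;
        double v = continuous ? clamp01(std::fabs(norm_rand() * mut_sd)) : k_fixed;
        (unif_rand() < 0.5 ? cab_a : cab_b).row(ind)[n_cab] = v;
        ++n_cab;
      }
    }
    // dedicated suppressors only arise for distorters that lack one
    if (n_cab > n_comm && rho_S > 0.0) {
      double dormant_com = comm_total - (double)n_comm;
      if (dormant_com > 0.0) {
        int new_com = (int)R::rbinom(dormant_com, rho_S);
        if (new_com > n_cab - n_comm) new_com = n_cab - n_comm;
        while (n_comm + new_com > cap_com) {
          int nc = cap_com * 2;
          com_a.grow(N, nc); com_b.grow(N, nc);
          ocom_a.grow(N, nc); ocom_b.grow(N, nc);
          cap_com = nc;
        }
        for (int m = 0; m < new_com; ++m) {
          int ind = (int)(unif_rand() * N); if (ind >= N) ind = N - 1;
          double v = continuous ? clamp01(std::fabs(norm_rand() * mut_sd)) : 1.0;
          (unif_rand() < 0.5 ? com_a : com_b).row(ind)[n_comm] = v;
          ++n_comm;
        }
      }
    }

    // --- phenotypes: TotSup, Dist, fitness, drive pull ----------------
    double dsum = 0.0;
    for (int i = 0; i < N; ++i) {
      const double *ka = cab_a.row(i), *kb = cab_b.row(i);
      const double *ma = com_a.row(i), *mb = com_b.row(i);
      dloci.clear(); kmax_l.clear(); own_l.clear();
      for (int l = 0; l < n_cab; ++l) {
        double km = ka[l] > kb[l] ? ka[l] : kb[l];
        if (km > 0.0) { dloci.push_back(l); kmax_l.push_back(km); }
      }
      int nd = (int)dloci.size();
      int q = 0; double sum_expr = 0.0;
      for (int j = 0; j < nd; ++j) {
        int l = dloci[j];
        double sm = 0.0;
        if (l < n_comm) sm = ma[l] > mb[l] ? ma[l] : mb[l];
        own_l.push_back(sm);  // expressed iff its target distorter is present
        if (sm > 0.0) { ++q; sum_expr += sm; }
      }
      double tot_sum = 0.0, Dist = 0.0, sum_eff = 0.0, pull = 0.0;
      for (int j = 0; j < nd; ++j) {
        double ts;
        if (!continuous) {
          ts = own_l[j] > 0.0 ? 1.0 : std::fmin(z * (double)q, 1.0);
        } else {
          ts = std::fmin(own_l[j] + z * (sum_expr - own_l[j]), 1.0);
        }
        double eff = (1.0 - ts) * kmax_l[j];
        sum_eff += eff; tot_sum += ts;
        if (eff > Dist) Dist = eff;  // ties: earliest (lowest-index) locus
        int l = dloci[j];
        double diff = std::fabs(ka[l] - kb[l]);
        double pl = (1.0 - ts) * diff;
        if (pl > pull) pull = pl;
      }
      double Waste = sum_eff - Dist;
      double ct = Dist > 0.0 ? c_coef * std::pow(Dist, c_exp) : 0.0;
      // redundant-product cost: the trait-cost curve applied to Waste,
      // scaled so one unsuppressed inter-locus-recessive distorter costs
      // r_rec times the distortion cost itself
      double crec = Waste > 0.0 ? r_rec * c_coef * std::pow(Waste, c_exp) : 0.0;
      double fit = 1.0 - ct - crec - c_sup * tot_sum;
      if (fit < 0.0) { fit = 0.0; ++neg_fitness_events; }
      fitness[i] = fit; drive_pull[i] = pull;
      dsum += Dist;
    }
    mean_dist[t] = dsum / (double)N;
    n_cab_trace[t] = n_cab; n_comm_trace[t] = n_comm;

    // --- reproduction --------------------------------------------------
    double tot = 0.0;
    for (int i = 0; i < N; ++i) { tot += fitness[i]; cum[i] = tot; }
    if (tot <= 0.0)
      stop("population fitness collapsed to zero at generation %d", t + 1);
    CoinPool coins;
    for (int j = 0; j < N; ++j) {
      for (int rep = 0; rep < 2; ++rep) {
        int p = sample_parent(cum, tot);
        const double *pka = cab_a.row(p), *pkb = cab_b.row(p);
        const double *pma = com_a.row(p), *pmb = com_b.row(p);
        double *gk = (rep == 0 ? ocab_a : ocab_b).row(j);
        double *gm = (rep == 0 ? ocom_a : ocom_b).row(j);
        bool drv = unif_rand() < 0.5 * (1.0 + drive_pull[p]);
        if (drv) {
          for (int l = 0; l < n_cab; ++l)
            gk[l] = pka[l] > pkb[l] ? pka[l] : pkb[l];
        } else {
          for (int l = 0; l < n_cab; ++l)
            gk[l] = pka[l] < pkb[l] ? pka[l] : pkb[l];
        }
        for (int l = 0; l < n_comm; ++l)
          gm[l] = coins.flip() ? pma[l] : pmb[l];
      }
    }

    // --- mutation on offspring ----------------------------------------
    double pmut = continuous ? mut_prob : flip_prob;
    if (pmut > 0.0) {
      for (int set = 0; set < 2; ++set) {
        int nl = set == 0 ? n_cab : n_comm;
        if (nl == 0) continue;
        HaploSet *haps[2] = {set == 0 ? &ocab_a : &ocom_a,
                             set == 0 ? &ocab_b : &ocom_b};
        double slots = 2.0 * (double)N * (double)nl;
        int nmut = (int)R::rbinom(slots, pmut);
        double func_val = set == 0 ? k_fixed : 1.0;
        for (int m = 0; m < nmut; ++m) {
          int l = (int)(unif_rand() * nl); if (l >= nl) l = nl - 1;
          int ind = (int)(unif_rand() * N); if (ind >= N) ind = N - 1;
          double *row = haps[unif_rand() < 0.5 ? 0 : 1]->row(ind);
          if (continuous) row[l] = clamp01(row[l] + norm_rand() * mut_sd);
          else row[l] = row[l] > 0.0 ? 0.0 : func_val;
        }
      }
    }

    std::swap(cab_a.v, ocab_a.v); std::swap(cab_b.v, ocab_b.v);
    std::swap(com_a.v, ocom_a.v); std::swap(com_b.v, ocom_b.v);
    if ((t & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  double avg = 0.0;
  for (int t = 0; t < T_end; ++t) avg += mean_dist[t];
  avg /= (double)T_end;
  return List::create(
    _["mean_distortion"] = mean_dist,
    _["n_cabal"] = n_cab_trace,
    _["n_commonwealth"] = n_comm_trace,
    _["average_distortion"] = avg,
    _["negative_fitness_events"] = (double)neg_fitness_events);
}
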
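// Exclusion-constrained Gillespie engine for the RNAPII transcription cycle.
//
// The gene is a row of 120 bp compartments: [UAS] promoter bin1..binN terminator.
// Each compartment holds at most one polymerase; moves into an occupied
// compartment are disabled (propensity 0), so every enabled transition is a
// Poisson process and the whole gene is a continuous-time Markov jump process.
// This mirrors the pure-R reference implementation in R/gillespie.R; the C++
// version exists only because ensemble fitting needs ~10^6 gene simulations.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// splitmix64: small, fast, well-distributed 64-bit PRNG. One independent
// substream per gene, derived from the master seed and the gene index, so
// multi-gene runs are order-independent.
static inline uint64_t sm64_next(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double sm64_unif(uint64_t &state) {
  // in (0, 1): never returns 0 so -log(u) is finite
  return ((sm64_next(state) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline uint64_t gene_stream(uint64_t master, uint64_t gene_index) {
  uint64_t s = master ^ (0xD1B54A32D192ED03ULL * (gene_index + 1));
  // warm up once so nearby seeds decorrelate
  sm64_next(s);
  return s;
}

// rates vector layout (absent transitions carry rate 0):
// 0 k1, 1 k_minus1, 2 k2, 3 k_minus2, 4 k3, 5 k_minus3, 6 k4, 7 k5, 8 hop, 9 k7
// promoter substates: 0 empty, 1 awaiting TFIIH, 2 PIC complete

// [[Rcpp::export]]
List cpp_sim_occupancy(bool has_uas, int n_bins, NumericVector rates,
                       int n_genes, double total_time, double record_window,
                       double master_seed) {
  const double k1 = rates[0], km1 = rates[1], k2 = rates[2], km2 = rates[3],
               k3 = rates[4], km3 = rates[5], k4 = rates[6], k5 = rates[7],
               hop = rates[8], k7 = rates[9];
  const int n_comp = (has_uas ? 1 : 0) + 2 + n_bins;
  const int off = has_uas ? 1 : 0;   // compartment index of the promoter
  const double rec_start = total_time - record_window;
  const uint64_t master = (uint64_t)master_seed;

  std::vector<double> sum(n_comp, 0.0), sumsq(n_comp, 0.0);
  std::vector<double> occ(n_comp);
  std::vector<double> prop(3 + 1 + 2 + 1 + n_bins + 1);
  std::vector<int> bins(n_bins);

  double initiations = 0, completions = 0, recruitments = 0;
  double init_window = 0, compl_window = 0;

  for (int g = 0; g < n_genes; ++g) {
    uint64_t rng = gene_stream(master, (uint64_t)g);
    int uas = 0, prom = 0, term = 0;
    std::fill(bins.begin(), bins.end(), 0);
    std::fill(occ.begin(), occ.end(), 0.0);
    double t = 0.0;

    while (t < total_time) {
      // enabled transitions
      int n_en = 0;
      double total = 0.0;
      // ids: 0 recruit_uas, 1 uas_loss, 2 transfer, 3 reversal, 4 recruit_prom,
      // 5 prom_loss, 6 tfiih, 7 initiate, 8..8+n_bins-1 hops (last into term),
      // 8+n_bins release
      static thread_local std::vector<int> ids;
      ids.resize(prop.size());
      if (has_uas) {
        if (!uas && k1 > 0)            { ids[n_en] = 0; prop[n_en++] = k1; }
        if (uas && km1 > 0)            { ids[n_en] = 1; prop[n_en++] = km1; }
        if (uas && prom == 0 && k2 > 0){ ids[n_en] = 2; prop[n_en++] = k2; }
        if (prom == 1 && !uas && km2 > 0) { ids[n_en] = 3; prop[n_en++] = km2; }
      }
      if (prom == 0 && k3 > 0)         { ids[n_en] = 4; prop[n_en++] = k3; }
      if (prom == 1 && km3 > 0)        { ids[n_en] = 5; prop[n_en++] = km3; }
      if (prom == 1 && k4 > 0)         { ids[n_en] = 6; prop[n_en++] = k4; }
      if (prom == 2 && !bins[0] && k5 > 0) { ids[n_en] = 7; prop[n_en++] = k5; }
      if (hop > 0) {
        for (int i = 0; i < n_bins - 1; ++i)
          if (bins[i] && !bins[i + 1]) { ids[n_en] = 8 + i; prop[n_en++] = hop; }
        if (bins[n_bins - 1] && !term) { ids[n_en] = 8 + n_bins - 1; prop[n_en++] = hop; }
      }
      if (term && k7 > 0)              { ids[n_en] = 8 + n_bins; prop[n_en++] = k7; }

      for (int i = 0; i < n_en; ++i) total += prop[i];

      double t_next;
      if (total <= 0.0) {
        t_next = total_time;            // absorbed: frozen until end of run
      } else {
        t_next = t - std::log(sm64_unif(rng)) / total;
      }
      // accumulate occupancy over the overlap with the recording window
      double a = t > rec_start ? t : rec_start;
      double b = t_next < total_time ? t_next : total_time;
      if (b > a) {
        double dt = b - a;
        if (uas) occ[0] += dt;
        if (prom > 0) occ[off] += dt;
        for (int i = 0; i < n_bins; ++i) if (bins[i]) occ[off + 1 + i] += dt;
        if (term) occ[off + 1 + n_bins] += dt;
      }
      if (total <= 0.0 || t_next >= total_time) break;
      t = t_next;

      // choose transition proportional to propensity
      double u = sm64_unif(rng) * total;
      int chosen = n_en - 1;
      double cum = 0.0;
      for (int i = 0; i < n_en; ++i) {
        cum += prop[i];
        if (u <= cum) { chosen = i; break; }
      }
      bool in_window = t >= rec_start;
      switch (ids[chosen]) {
        case 0: uas = 1; recruitments += 1; break;
        case 1: uas = 0; break;
        case 2: uas = 0; prom = 1; break;
        case 3: prom = 0; uas = 1; break;
        case 4: prom = 1; recruitments += 1; break;
        case 5: prom = 0; break;
        case 6: prom = 2; break;
        case 7:
          prom = 0; bins[0] = 1; initiations += 1;
          if (in_window) init_window += 1;
          break;
        default: {
          int id = ids[chosen];
          if (id == 8 + n_bins) {       // terminator release
            term = 0; completions += 1;
            if (in_window) compl_window += 1;
          } else {
            int i = id - 8;
            if (i == n_bins - 1) { bins[i] = 0; term = 1; }
            else { bins[i] = 0; bins[i + 1] = 1; }
          }
        }
      }
    }

    for (int c = 0; c < n_comp; ++c) {
      double frac = occ[c] / record_window;
      sum[c] += frac;
      sumsq[c] += frac * frac;
    }
  }

  NumericVector mean(n_comp), se(n_comp);
  for (int c = 0; c < n_comp; ++c) {
    double m = sum[c] / n_genes;
    mean[c] = m;
    double var = n_genes > 1 ? (sumsq[c] - n_genes * m * m) / (n_genes - 1.0) : 0.0;
    if (var < 0) var = 0;
    se[c] = std::sqrt(var / n_genes);
  }
  return List::create(
    _["mean"] = mean, _["se"] = se, _["n_genes"] = n_genes,
    _["initiations"] = initiations, _["completions"] = completions,
    _["recruitments"] = recruitments,
    _["initiations_window"] = init_window,
    _["completions_window"] = compl_window);
}

// Minimal dwell-time model: one polymerase cycling promoter -> bins ->
// terminator -> (instantly back to) promoter, exponential dwell in each
// compartment, no exclusion. Starts at the promoter.

// [[Rcpp::export]]
List cpp_sim_minimal(int n_bins, double r_prom, double r_hop, double r_term,
                     int n_genes, double total_time, double record_window,
                     double master_seed) {
  const int n_comp = 2 + n_bins;
  const double rec_start = total_time - record_window;
  const uint64_t master = (uint64_t)master_seed;
  std::vector<double> sum(n_comp, 0.0), sumsq(n_comp, 0.0), occ(n_comp);

  for (int g = 0; g < n_genes; ++g) {
    uint64_t rng = gene_stream(master, (uint64_t)g);
    std::fill(occ.begin(), occ.end(), 0.0);
    int pos = 0;  // 0 promoter, 1..n_bins bins, n_bins+1 terminator
    double t = 0.0;
    while (t < total_time) {
      double rate = pos == 0 ? r_prom : (pos <= n_bins ? r_hop : r_term);
      double t_next = t - std::log(sm64_unif(rng)) / rate;
      double a = t > rec_start ? t : rec_start;
      double b = t_next < total_time ? t_next : total_time;
      if (b > a) occ[pos] += b - a;
      t = t_next;
      pos = pos == n_bins + 1 ? 0 : pos + 1;
    }
    for (int c = 0; c < n_comp; ++c) {
      double frac = occ[c] / record_window;
      sum[c] += frac;
      sumsq[c] += frac * frac;
    }
  }
  NumericVector mean(n_comp), se(n_comp);
  for (int c = 0; c < n_comp; ++c) {
    double m = sum[c] / n_genes;
    mean[c] = m;
    double var = n_genes > 1 ? (sumsq[c] - n_genes * m * m) / (n_genes - 1.0) : 0.0;
    if (var < 0) var = 0;
    se[c] = std::sqrt(var / n_genes);
  }
  return List::create(_["mean"] = mean, _["se"] = se, _["n_genes"] = n_genes);
}
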
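#include <Rcpp.h>
#include "rps_rng.h"
using namespace Rcpp;

// cell states: 0 vacant, 1 A, 2 B, 3 C; cyclic prey: A->B, B->C, C->A
static inline int prey_of(int s) { return s == 3 ? 1 : s + 1; }

// One elementary event, the paper's update rule: pick an occupied site
// uniformly (rejection over all sites), check death first with the
// pulse-adjusted probability, otherwise act on one uniformly chosen von
// Neumann neighbour (periodic wrap): reproduce into vacancy, or kill cyclic
// prey in place (the predator does not move).
static inline void one_update(int *g, int L, int N, int *counts, double p,
                              double r, const double *deff,
                              Xoshiro256pp &rng) {
  int idx;
  do {
    idx = rng.unif_int(N);
  } while (g[idx] == 0);
  const int s = g[idx];
  if (rng.unif() < deff[s]) {
    g[idx] = 0;
    --counts[s];
    ++counts[0];
    return;
  }
  const int row = idx % L, col = idx / L;
  int nrow = row, ncol = col;
  switch (rng.unif_int(4)) {
  case 0:
    nrow = row + 1 == L ? 0 : row + 1;
    break;
  case 1:
    nrow = row == 0 ? L - 1 : row - 1;
    break;
  case 2:
    ncol = col + 1 == L ? 0 : col + 1;
    break;
  default:
    ncol = col == 0 ? L - 1 : col - 1;
  }
  const int nidx = nrow + ncol * L;
  const int ns = g[nidx];
  if (ns == 0) {
    if (rng.unif() < r) {
      g[nidx] = s;
      ++counts[s];
      --counts[0];
    }
  } else if (ns == prey_of(s)) {
    if (rng.unif() < p) {
      g[nidx] = 0;
      --counts[ns];
      ++counts[0];
    }
  }
}

static void recount(const int *g, int N, int *counts) {
  for (int i = 0; i < 4; ++i) counts[i] = 0;
  for (int i = 0; i < N; ++i) ++counts[g[i]];
}

// n_updates elementary events at fixed per-species death probabilities;
// exposed for transition-probability oracle tests on tiny lattices.
// [[Rcpp::export(rng = false)]]
IntegerMatrix lattice_update_cpp(IntegerMatrix grid, double p, double r,
                                 NumericVector d_eff, int n_updates,
                                 double seed) {
  const int L = grid.nrow();
  if (grid.ncol() != L) stop("grid must be square");
  const int N = L * L;
  IntegerMatrix g = clone(grid);
  int counts[4];
  recount(INTEGER(g), N, counts);
  if (counts[0] == N) stop("fully vacant lattice: no update possible");
  double deff[4] = {0.0, d_eff[0], d_eff[1], d_eff[2]};
  Xoshiro256pp rng((uint64_t)seed);
  for (int k = 0; k < n_updates; ++k) {
    if (counts[0] == N) stop("lattice became fully vacant");
    one_update(INTEGER(g), L, N, counts, p, r, deff, rng);
  }
  return g;
}

// Full run: burn-in sweeps without pulse, then t_max sweeps with the pulse
// clock in sweep units; densities recorded once per time unit (= N elementary
// events). Early stop when <= 1 species remains and no reclassification is
// possible (lone species with r > d persists; with r <= d run on to t_max).
// [[Rcpp::export(rng = false)]]
List lattice_run_cpp(IntegerMatrix grid, double p, double r, double d,
                     double delta_d, double tau, double onset, int target,
                     int t_max, int burn_in, double seed, bool early_stop) {
  const int L = grid.nrow();
  if (grid.ncol() != L) stop("grid must be square");
  const int N = L * L;
  IntegerMatrix g = clone(grid);
  int *gp = INTEGER(g);
  int counts[4];
  recount(gp, N, counts);
  Xoshiro256pp rng((uint64_t)seed);
  double deff[4];

  for (int t = 0; t < burn_in; ++t) {
    deff[0] = 0.0;
    deff[1] = deff[2] = deff[3] = d;
    for (int k = 0; k < N; ++k) {
      if (counts[0] == N) break;
      one_update(gp, L, N, counts, p, r, deff, rng);
    }
    Rcpp::checkUserInterrupt();
  }

  std::vector<double> rec_t;
  std::vector<int> rec_counts; // a, b, c per record
  double ext[3] = {-1.0, -1.0, -1.0};
  for (int i = 0; i < 3; ++i)
    if (counts[i + 1] == 0) ext[i] = 0.0;
  rec_t.push_back(0.0);
  for (int i = 1; i <= 3; ++i) rec_counts.push_back(counts[i]);

  int t = 0;
  bool stopped_early = false;
  for (t = 0; t < t_max; ++t) {
    const bool in_pulse = (t >= onset && t <= onset + tau);
    deff[0] = 0.0;
    for (int s = 1; s <= 3; ++s)
      deff[s] = d + ((in_pulse && s == target) ? delta_d : 0.0);
    for (int k = 0; k < N; ++k) {
      if (counts[0] == N) break;
      one_update(gp, L, N, counts, p, r, deff, rng);
    }
    rec_t.push_back((double)(t + 1));
    int alive = 0;
    for (int i = 1; i <= 3; ++i) {
      rec_counts.push_back(counts[i]);
      if (counts[i] > 0)
        ++alive;
      else if (ext[i - 1] < 0.0)
        ext[i - 1] = (double)(t + 1);
    }
    if (alive == 0 || (early_stop && alive == 1 && r > d)) {
      stopped_early = true;
      ++t;
      break;
    }
    Rcpp::checkUserInterrupt();
  }
  if (!stopped_early) t = t_max;

  const int nrec = (int)rec_t.size();
  NumericVector tt(nrec), ra(nrec), rb(nrec), rc(nrec), rv(nrec);
  for (int i = 0; i < nrec; ++i) {
    tt[i] = rec_t[i];
    ra[i] = rec_counts[3 * i] / (double)N;
    rb[i] = rec_counts[3 * i + 1] / (double)N;
    rc[i] = rec_counts[3 * i + 2] / (double)N;
    rv[i] = 1.0 - ra[i] - rb[i] - rc[i];
  }
  NumericVector extv(3);
  for (int i = 0; i < 3; ++i) extv[i] = ext[i] < 0.0 ? NA_REAL : ext[i];
  IntegerVector cnt(4);
  for (int i = 0; i < 4; ++i) cnt[i] = counts[i];
  return List::create(_["grid"] = g, _["counts"] = cnt, _["t"] = tt,
                      _["rho_a"] = ra, _["rho_b"] = rb, _["rho_c"] = rc,
                      _["rho_v"] = rv, _["extinction_times"] = extv,
                      _["t_end"] = (double)t,
                      _["stopped_early"] = stopped_early);
}
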
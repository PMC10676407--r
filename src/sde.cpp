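#include <Rcpp.h>
#include <vector>
#include "rps_rng.h"
using namespace Rcpp;

// noise kinds: 0 none, 1 gaussian (additive sd=scale), 2 uniform (additive,
// full width = scale), 3 lognormal (multiplicative, median 1, shape = scale)
static inline double effective_r(double r, int kind, double scale,
                                 Xoshiro256pp &rng) {
  switch (kind) {
  case 1:
    return r + scale * rng.norm();
  case 2:
    return r + scale * (rng.unif() - 0.5);
  case 3:
    return r * std::exp(scale * rng.norm());
  default:
    return r;
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector noise_draw_cpp(int kind, double scale, double r, int n,
                             double seed) {
  Xoshiro256pp rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = effective_r(r, kind, scale, rng);
  return out;
}

// [[Rcpp::export(rng = false)]]
NumericVector unif_cpp(int n, double seed) {
  Xoshiro256pp rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.unif();
  return out;
}

// [[Rcpp::export(rng = false)]]
double mix_seed_cpp(double base, double a, double b, double c) {
  uint64_t h = mix_seed_u64((uint64_t)base, (uint64_t)a, (uint64_t)b,
                            (uint64_t)c);
  // keep in [1, 2^31 - 2] so the value survives as an R integer seed
  return (double)(h % 2147483645ULL) + 1.0;
}

struct SdeResult {
  double rho[3];
  double ext[3]; // extinction times, NA -> negative sentinel
  double t_end;
  bool resolved;
};

// explicit Euler map of the three coupled rate equations; per-step
// independent reproduction-rate draws; species falling below eps are set to
// exactly 0 (no resurrection). Stops when <= 1 species remains or at t_max.
static SdeResult sde_core(const double *init, double p, double r, double d,
                          double delta_d, double tau, double onset, int target,
                          double dt, double t_max, double eps, int noise_kind,
                          double noise_scale, uint64_t seed, int record_stride,
                          std::vector<double> *rec_t,
                          std::vector<double> *rec_rho) {
  Xoshiro256pp rng(seed);
  SdeResult res;
  double rho[3] = {init[0], init[1], init[2]};
  double ext[3] = {-1.0, -1.0, -1.0};
  const long n_steps = (long)std::ceil(t_max / dt - 1e-9);
  long step = 0;
  double t = 0.0;
  bool resolved = false;

  for (int i = 0; i < 3; ++i) {
    if (rho[i] < eps) {
      rho[i] = 0.0;
      ext[i] = 0.0;
    }
  }

  for (step = 0; step < n_steps; ++step) {
    t = step * dt;
    if (rec_t && step % record_stride == 0) {
      rec_t->push_back(t);
      rec_rho->push_back(rho[0]);
      rec_rho->push_back(rho[1]);
      rec_rho->push_back(rho[2]);
    }
    const double dprime =
        (t >= onset && t <= onset + tau) ? delta_d : 0.0;
    const double rv = 1.0 - rho[0] - rho[1] - rho[2];
    double re[3];
    for (int i = 0; i < 3; ++i)
      re[i] = effective_r(r, noise_kind, noise_scale, rng);
    const double da =
        rho[0] * (re[0] * rv - p * rho[2] - (d + (target == 1 ? dprime : 0.0)));
    const double db =
        rho[1] * (re[1] * rv - p * rho[0] - (d + (target == 2 ? dprime : 0.0)));
    const double dc =
        rho[2] * (re[2] * rv - p * rho[1] - (d + (target == 3 ? dprime : 0.0)));
    rho[0] += dt * da;
    rho[1] += dt * db;
    rho[2] += dt * dc;
    int alive = 0;
    for (int i = 0; i < 3; ++i) {
      if (rho[i] < eps) {
        if (rho[i] != 0.0 || ext[i] < 0.0) {
          rho[i] = 0.0;
          if (ext[i] < 0.0) ext[i] = t + dt;
        }
      } else {
        ++alive;
      }
    }
    if (alive <= 1) {
      resolved = true;
      t = (step + 1) * dt;
      break;
    }
  }
  if (!resolved) t = n_steps * dt;
  if (rec_t) {
    rec_t->push_back(t);
    rec_rho->push_back(rho[0]);
    rec_rho->push_back(rho[1]);
    rec_rho->push_back(rho[2]);
  }
  for (int i = 0; i < 3; ++i) {
    res.rho[i] = rho[i];
    res.ext[i] = ext[i];
  }
  res.t_end = t;
  res.resolved = resolved;
  return res;
}

// [[Rcpp::export(rng = false)]]
List sde_run_cpp(NumericVector init, double p, double r, double d,
                 double delta_d, double tau, double onset, int target,
                 double dt, double t_max, double eps, int noise_kind,
                 double noise_scale, double seed, int record_stride,
                 bool record) {
  std::vector<double> rec_t, rec_rho;
  SdeResult res = sde_core(
      REAL(init), p, r, d, delta_d, tau, onset, target, dt, t_max, eps,
      noise_kind, noise_scale, (uint64_t)seed, record_stride,
      record ? &rec_t : (std::vector<double> *)0, record ? &rec_rho : 0);
  NumericVector ext(3), rho(3);
  for (int i = 0; i < 3; ++i) {
    rho[i] = res.rho[i];
    ext[i] = res.ext[i] < 0.0 ? NA_REAL : res.ext[i];
  }
  List out = List::create(
      _["rho"] = rho, _["extinction_times"] = ext, _["t_end"] = res.t_end,
      _["resolved"] = res.resolved);
  if (record) {
    const int nrec = (int)rec_t.size();
    NumericVector tt(nrec), ra(nrec), rb(nrec), rc(nrec);
    for (int i = 0; i < nrec; ++i) {
      tt[i] = rec_t[i];
      ra[i] = rec_rho[3 * i];
      rb[i] = rec_rho[3 * i + 1];
      rc[i] = rec_rho[3 * i + 2];
    }
    out["t"] = tt;
    out["rho_a"] = ra;
    out["rho_b"] = rb;
    out["rho_c"] = rc;
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List sde_ensemble_cpp(NumericVector init, double p, double r, double d,
                      double delta_d, double tau, double onset, int target,
                      double dt, double t_max, double eps, int noise_kind,
                      double noise_scale, NumericVector seeds) {
  const int n = seeds.size();
  NumericMatrix rho(n, 3), ext(n, 3);
  NumericVector t_end(n);
  LogicalVector resolved(n);
  for (int k = 0; k < n; ++k) {
    SdeResult res =
        sde_core(REAL(init), p, r, d, delta_d, tau, onset, target, dt, t_max,
                 eps, noise_kind, noise_scale, (uint64_t)seeds[k], 1000000,
                 (std::vector<double> *)0, (std::vector<double> *)0);
    for (int i = 0; i < 3; ++i) {
      rho(k, i) = res.rho[i];
      ext(k, i) = res.ext[i] < 0.0 ? NA_REAL : res.ext[i];
    }
    t_end[k] = res.t_end;
    resolved[k] = res.resolved;
    if (k % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["rho"] = rho, _["extinction_times"] = ext,
                      _["t_end"] = t_end, _["resolved"] = resolved);
}
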
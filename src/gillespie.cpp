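#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation of the mating assay over five reactions:
//   D -> 2D        at psiD * D
//   R -> 2R        at psiR * R
//   T -> 2T        at psiT * T
//   D + R -> D + T at gammaD * D * R / V   (records t* on first firing)
//   T + R -> 2T    at gammaT * T * R / V
// Counts are integers in the simulated volume V (ml); conjugation
// propensities carry the 1/V mass-action volume scaling. The walk stops at
// t_max, at zero total propensity (absorbing state) or when the total count
// reaches population_cap; the state is frozen thereafter for any remaining
// sample times. The sampled path is cadlag: a sample time coinciding with an
// event reports the post-event state. Uses R's RNG so set.seed() makes runs
// reproducible.
// [[Rcpp::export(name = ".ssa_mating")]]
List ssa_mating(double D, double R, double T,
                double psiD, double psiR, double psiT,
                double gammaD, double gammaT,
                double volume, double t_max, double population_cap,
                NumericVector sample_times) {
  const int n_s = sample_times.size();
  NumericVector outD(n_s), outR(n_s), outT(n_s);
  int si = 0;
  double t = 0.0;
  double t_star = NA_REAL;
  std::string stop_reason;

  RNGScope scope;
  for (;;) {
    double a1 = psiD * D;
    double a2 = psiR * R;
    double a3 = psiT * T;
    double a4 = gammaD * D * R / volume;
    double a5 = gammaT * T * R / volume;
    double a0 = a1 + a2 + a3 + a4 + a5;
    if (!R_FINITE(a0)) {
      stop("propensity overflow at counts D=%g R=%g T=%g", D, R, T);
    }
    if (a0 <= 0.0) { stop_reason = "absorbed"; break; }
    double t_next = t + exp_rand() / a0;
    while (si < n_s && sample_times[si] < t_next) {  // state constant here
      outD[si] = D; outR[si] = R; outT[si] = T;
      ++si;
    }
    if (t_next > t_max) { stop_reason = "t_max"; t = t_max; break; }
    t = t_next;
    double u = unif_rand() * a0;
    if (u < a1) {
      D += 1;
    } else if (u < a1 + a2) {
      R += 1;
    } else if (u < a1 + a2 + a3) {
      T += 1;
    } else if (u < a1 + a2 + a3 + a4) {
      R -= 1; T += 1;
      if (!R_FINITE(t_star)) t_star = t;  // first donor->recipient event
    } else {
      R -= 1; T += 1;
    }
    if (D + R + T >= population_cap) { stop_reason = "population_cap"; break; }
  }
  while (si < n_s) { outD[si] = D; outR[si] = R; outT[si] = T; ++si; }
  return List::create(_["D"] = outD, _["R"] = outR, _["T"] = outT,
                      _["t_star"] = t_star, _["end_time"] = t,
                      _["final"] = NumericVector::create(D, R, T),
                      _["stop_reason"] = stop_reason);
}
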
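#include <Rcpp.h>
using namespace Rcpp;

// Monte Carlo run-length engine shared by every chart kind.
//
// stat_kind: 0 raw observation (Tukey's individual chart)
//            1 moving average of span w
//            2 MEWMA recursion  M_t = lam*x_t + (1-lam)*M_{t-1} + k*(x_t - x_{t-1})
//            3 MA of the MEWMA statistic (MMME)
//            4 MEWMA of the MA statistic (MMEM)
// dist:      1 normal(mean p1, sd p2)
//            2 Laplace(location p1, scale p2), sampled as the difference of
//              two standard exponentials scaled by p2
//            3 exponential(rate p1)
//            4 gamma(shape p1, scale p2)
// shift:     additive offset applied to every draw (delta * sigma for
//            location shifts; scale shifts are passed through p1/p2 instead)
// ucl/lcl:   limit profiles indexed by min(t, length) - limits of every chart
//            here are constant from t = w onward, so a length-w profile is
//            enough for any horizon.
//
// Returns the first index t with stat outside (lcl[t], ucl[t]) per replicate;
// exact boundary hits do not signal. Replicates with no signal by max_horizon
// are returned as max_horizon and flagged censored.
//
// Uses R's RNG: seeding via set.seed() on the R side makes runs reproducible.

static inline double draw_obs(int dist, double p1, double p2) {
  switch (dist) {
  case 1:  return p1 + p2 * norm_rand();
  case 2:  return p1 + p2 * (exp_rand() - exp_rand());
  case 3:  return exp_rand() / p1;
  default: return R::rgamma(p1, p2);
  }
}

// [[Rcpp::export(name = ".rl_sim_cpp")]]
List rl_sim_cpp(int n_reps, int max_horizon, int stat_kind,
                int w, double lam, double k, double m0,
                NumericVector ucl, NumericVector lcl,
                int dist, double p1, double p2, double shift) {
  IntegerVector rl(n_reps);
  LogicalVector censored(n_reps);
  const int L = ucl.size();
  std::vector<double> buf(w > 0 ? w : 1);
  RNGScope scope;

  for (int r = 0; r < n_reps; ++r) {
    double M = m0, xprev = m0, maprev = m0, sum = 0.0;
    int nb = 0, head = 0;
    bool hit = false;
    for (int t = 1; t <= max_horizon; ++t) {
      const double x = draw_obs(dist, p1, p2) + shift;
      double s;
      if (stat_kind == 0) {
        s = x;
      } else if (stat_kind == 2) {
        M = lam * x + (1.0 - lam) * M + k * (x - xprev);
        xprev = x;
        s = M;
      } else {
        double v = x;
        if (stat_kind == 3) {          // MEWMA stage feeds the MA stage
          M = lam * x + (1.0 - lam) * M + k * (x - xprev);
          xprev = x;
          v = M;
        }
        double a;                      // span-w moving average of v
        if (nb < w) {
          buf[nb++] = v; sum += v; a = sum / nb;
        } else {
          sum += v - buf[head]; buf[head] = v;
          head = (head + 1) % w; a = sum / w;
        }
        if (stat_kind == 4) {          // MA stage feeds the MEWMA stage
          M = lam * a + (1.0 - lam) * M + k * (a - maprev);
          maprev = a;
          s = M;
        } else {
          s = a;
        }
      }
      const int idx = (t <= L) ? (t - 1) : (L - 1);
      if (s > ucl[idx] || s < lcl[idx]) { rl[r] = t; hit = true; break; }
    }
    if (!hit) { rl[r] = max_horizon; censored[r] = true; }
  }
  return List::create(_["rl"] = rl, _["censored"] = censored);
}
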
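#include <Rcpp.h>
using namespace Rcpp;

// Exact event-driven simulation of the two-state (telegraph) promoter for a
// set of independent alleles in one cell. State per allele: promoter ON/OFF,
// mRNA copy number. Events: OFF->ON (k_on), ON->OFF (k_off), transcription
// while ON (k_tx), first-order decay (m * k_deg). Uses R's RNG stream so the
// caller's set.seed() fully determines the trajectory.
//
// Returns an integer matrix n_alleles x 2: column 1 = mRNA count at t_end,
// column 2 = promoter state at t_end (1 = ON).
// [[Rcpp::export]]
IntegerMatrix telegraph_alleles(int n_alleles, double k_on, double k_off,
                                double k_tx, double k_deg, double t_end,
                                double p_init_on) {
  if (t_end <= 0.0) stop("t_end must be positive");
  IntegerMatrix out(n_alleles, 2);
  for (int a = 0; a < n_alleles; ++a) {
    bool on = unif_rand() < p_init_on;
    long m = 0;
    double t = 0.0;
    for (;;) {
      double a_switch = on ? k_off : k_on;
      double a_birth = on ? k_tx : 0.0;
      double a_death = m * k_deg;
      double a_tot = a_switch + a_birth + a_death;
      if (a_tot <= 0.0) break;
      t += exp_rand() / a_tot;
      if (t > t_end) break;
      double u = unif_rand() * a_tot;
      if (u < a_switch) {
        on = !on;
      } else if (u < a_switch + a_birth) {
        ++m;
      } else {
        --m;
      }
    }
    out(a, 0) = (int)m;
    out(a, 1) = on ? 1 : 0;
  }
  return out;
}
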
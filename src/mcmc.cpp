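#include <Rcpp.h>
using namespace Rcpp;

// Polynomial roll/twist energy in kBT, angles in degrees.
// coef order: a2 c2 g a3 c3 b d a4 c4 h (natural scale); global 1/2 on all.
static inline double poly_energy(const double *cf, double r, double w) {
  return 0.5 * (cf[0] * r * r + cf[1] * w * w + 2.0 * cf[2] * w * r +
                cf[3] * r * r * r + cf[4] * w * w * w +
                cf[5] * r * r * w + cf[6] * r * w * w +
                cf[7] * r * r * r * r + cf[8] * w * w * w * w +
                cf[9] * r * r * w * w);
}

// Metropolis chain over (roll, excess twist) under model energy plus a
// harmonic bias centred at (rho_bar, omega_bar) with stiffness k_deg in
// kBT/deg^2, and a hard square wall at |rho|,|omega| <= bound (bound <= 0
// means unbounded). Uses R's RNG: deterministic under set.seed().
// Returns kept samples after burn-in and thinning, plus acceptance rate.
// [[Rcpp::export(name = ".mcmc_kernel")]]
List mcmc_kernel(NumericVector coef, double rho_bar, double omega_bar,
                 double k_deg, double bound, double halfwidth,
                 int n_keep, int burn_in, int thin,
                 double rho0, double omega0) {
  if (coef.size() != 10) stop("coef must have length 10");
  if (n_keep <= 0) stop("n_keep must be positive");
  if (thin < 1) stop("thin must be >= 1");
  const double *cf = coef.begin();
  RNGScope scope;

  double r = rho0, w = omega0;
  double e = poly_energy(cf, r, w) +
             0.5 * k_deg * ((r - rho_bar) * (r - rho_bar) +
                            (w - omega_bar) * (w - omega_bar));
  NumericVector out_r(n_keep), out_w(n_keep);
  long n_prop = 0, n_acc = 0;
  long total = (long)burn_in + (long)n_keep * thin;
  int kept = 0;
  for (long i = 0; i < total; ++i) {
    double rp = r + R::runif(-halfwidth, halfwidth);
    double wp = w + R::runif(-halfwidth, halfwidth);
    ++n_prop;
    bool inside = (bound <= 0.0) ||
                  (std::fabs(rp) <= bound && std::fabs(wp) <= bound);
    if (inside) {
      double ep = poly_energy(cf, rp, wp) +
                  0.5 * k_deg * ((rp - rho_bar) * (rp - rho_bar) +
                                 (wp - omega_bar) * (wp - omega_bar));
      if (ep <= e || R::unif_rand() < std::exp(e - ep)) {
        r = rp; w = wp; e = ep; ++n_acc;
      }
    }
    if (i >= burn_in && ((i - burn_in) % thin) == (thin - 1L)) {
      if (kept < n_keep) { out_r[kept] = r; out_w[kept] = w; ++kept; }
    }
  }
  return List::create(_["roll"] = out_r, _["twist_excess"] = out_w,
                      _["acceptance_rate"] = (double)n_acc / (double)n_prop);
}
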
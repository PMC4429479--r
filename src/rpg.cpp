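// Polya-Gamma PG(1, z) sampling by the alternating-series rejection method
// (Devroye-type sampler for the Jacobi J*(1, z) density, draws scaled by 1/4).
// Uses R's RNG so draws are reproducible under set.seed().
#include <Rcpp.h>

static const double TRUNC = 0.64;

// n-th coefficient of the alternating series bounding the J*(1,z) density
static double a_coef(int n, double x) {
  double k = n + 0.5;
  if (x > TRUNC)
    return M_PI * k * std::exp(-k * k * M_PI * M_PI * x / 2.0);
  double y = std::pow(2.0 / (M_PI * x), 1.5);
  return M_PI * k * y * std::exp(-2.0 * k * k / x);
}

// P(left-of-TRUNC mass) helper: probability of drawing from the exponential
// tail proposal rather than the truncated inverse-Gaussian body.
static double mass_texpon(double z) {
  double t = TRUNC;
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double b = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// inverse-Gaussian IG(1/z, 1) truncated to (0, TRUNC]
static double rtigauss(double z) {
  double t = TRUNC;
  double mu = (z > 0.0) ? 1.0 / z : R_PosInf;
  double x = t + 1.0;
  if (!(mu < t)) {
    // one-sided rejection from the z = 0 kernel, thinned by exp(-z^2 x / 2)
    while (true) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (R::unif_rand() <= std::exp(-0.5 * z * z * x)) return x;
    }
  }
  while (x > t) {
    double yy = R::norm_rand();
    yy *= yy;
    double muy = mu * yy;
    x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
    if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
  }
  return x;
}

// one PG(1, z) draw
double rpg1(double z) {
  z = std::fabs(z) * 0.5;
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double p_tail = mass_texpon(z);
  while (true) {
    double x;
    if (R::unif_rand() < p_tail)
      x = TRUNC + R::exp_rand() / fz;
    else
      x = rtigauss(z);
    double s = a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    while (true) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x * 0.25;
      } else {
        s += a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

// [[Rcpp::export(name = ".rpg_vec")]]
Rcpp::NumericVector rpg_vec(Rcpp::NumericVector z) {
  int n = z.size();
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}
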
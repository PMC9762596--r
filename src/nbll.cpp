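#include <Rcpp.h>
using namespace Rcpp;

// Negative binomial log-pmf with mean mu and dispersion theta
// (variance mu + mu^2/theta).
static inline double nb_logpmf(double y, double mu, double theta) {
  return R::lgammafn(y + theta) - R::lgammafn(theta) - R::lgammafn(y + 1.0) +
         theta * std::log(theta / (theta + mu)) +
         y * std::log(mu / (theta + mu));
}

static inline double clamp(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Negative log-likelihood of a NB GLM with log link.
// par = (beta[0..p-1], log_theta)
// [[Rcpp::export]]
double nb_nll_cpp(NumericVector par, NumericVector y, NumericMatrix X) {
  int n = X.nrow(), p = X.ncol();
  double theta = std::exp(clamp(par[p], -25.0, 30.0));
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int j = 0; j < p; ++j) eta += X(i, j) * par[j];
    double mu = std::exp(clamp(eta, -40.0, 40.0));
    nll -= nb_logpmf(y[i], mu, theta);
  }
  return nll;
}

// Marginal negative log-likelihood of a NB GLMM with one normal random
// intercept per group, integrated by adaptive Gauss-Hermite quadrature at
// the per-group Laplace mode (nagq = 1 gives the Laplace approximation).
//
// par = (beta[0..p-1], log_theta, sigma); sigma enters through sigma^2, so
// the likelihood is even in sigma and sigma = 0 (no random effect: the NB
// GLM likelihood, evaluated exactly) is an interior stationary point rather
// than a boundary the optimizer must crawl to in log scale.
// Observations must be sorted by group; gstart/gsize give each group's
// offset (0-based) and length. z, w are standard Gauss-Hermite nodes and
// weights for weight function exp(-x^2).
//
// The terms lgamma(y+theta) - lgamma(theta) depend only on theta and are
// hoisted out of the mode search and quadrature. `bcache` (length = number
// of groups) carries each group's mode between calls and is updated in
// place: successive optimizer steps move the modes little, so warm-started
// Newton converges in 1-2 iterations.
// [[Rcpp::export]]
double nb_glmm_nll_cpp(NumericVector par, NumericVector y, NumericMatrix X,
                       IntegerVector gstart, IntegerVector gsize,
                       NumericVector z, NumericVector w,
                       NumericVector bcache) {
  int n = X.nrow(), p = X.ncol(), G = gstart.size(), K = z.size();
  double theta = std::exp(clamp(par[p], -25.0, 30.0));
  double sig2 = par[p + 1] * par[p + 1];
  double tlogt = theta * std::log(theta);

  std::vector<double> eta(n), cons(n);
  double lgam_theta = R::lgammafn(theta);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * par[j];
    eta[i] = e;
    cons[i] = R::lgammafn(y[i] + theta) - lgam_theta - R::lgammafn(y[i] + 1.0);
  }

  if (sig2 < 1e-12) {            // exact sigma = 0 limit: plain NB GLM
    double nll0 = 0.0;
    for (int i = 0; i < n; ++i) {
      double ei = clamp(eta[i], -40.0, 40.0);
      double mu = std::exp(ei);
      nll0 -= cons[i] + tlogt + y[i] * ei -
              (y[i] + theta) * std::log(theta + mu);
    }
    return nll0;
  }

  std::vector<double> terms(K);
  double log_norm = -0.5 * std::log(2.0 * M_PI * sig2);
  double nll = 0.0;
  for (int g = 0; g < G; ++g) {
    int a = gstart[g], m = gsize[g];

    // Newton search for the mode of
    // f(b) = sum_i log NB(y_i | exp(eta_i + b), theta) + log N(b | 0, sig2)
    double b = bcache[g];
    for (int it = 0; it < 50; ++it) {
      double g1 = -b / sig2, g2 = -1.0 / sig2;
      for (int i = a; i < a + m; ++i) {
        double mu = std::exp(clamp(eta[i] + b, -40.0, 40.0));
        double r = (y[i] + theta) / (theta + mu);
        g1 += y[i] - r * mu;
        g2 -= r * theta * mu / (theta + mu);
      }
      double step = -g1 / g2;
      if (step > 5.0) step = 5.0;
      if (step < -5.0) step = -5.0;
      b += step;
      if (std::fabs(step) < 1e-9) break;
    }
    bcache[g] = b;

    // curvature at the mode
    double g2 = -1.0 / sig2;
    for (int i = a; i < a + m; ++i) {
      double mu = std::exp(clamp(eta[i] + b, -40.0, 40.0));
      g2 -= (y[i] + theta) * theta * mu / ((theta + mu) * (theta + mu));
    }
    double s = 1.0 / std::sqrt(-g2);

    // adaptive quadrature: log integral = 0.5 log 2 + log s +
    //   logsumexp_k( log w_k + z_k^2 + f(b + sqrt(2) s z_k) )
    double lse_max = -INFINITY;
    for (int k = 0; k < K; ++k) {
      double bk = b + M_SQRT2 * s * z[k];
      double fk = log_norm - bk * bk / (2.0 * sig2);
      for (int i = a; i < a + m; ++i) {
        double ei = clamp(eta[i] + bk, -40.0, 40.0);
        double mu = std::exp(ei);
        fk += cons[i] + tlogt + y[i] * ei -
              (y[i] + theta) * std::log(theta + mu);
      }
      terms[k] = std::log(w[k]) + z[k] * z[k] + fk;
      if (terms[k] > lse_max) lse_max = terms[k];
    }
    double acc = 0.0;
    for (int k = 0; k < K; ++k) acc += std::exp(terms[k] - lse_max);
    nll -= 0.5 * std::log(2.0) + std::log(s) + lse_max + std::log(acc);
  }
  return nll;
}
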
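// Gibbs samplers for the Bayesian-alphabet marker-effect models
// (BRR, Bayes A, Bayes B, Bayes C, Bayesian LASSO) on standardized
// marker matrices. Uses R's RNG so runs are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// scaled inverse chi-square draw: nu * S / chisq_nu
static inline double rscinv(double nu, double S) {
  return nu * S / R::rchisq(nu);
}

// inverse-Gaussian draw (Michael, Schucany & Haas)
static inline double rinvgauss(double mu, double lambda) {
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mu + mu * mu * y / (2.0 * lambda) -
    (mu / (2.0 * lambda)) * std::sqrt(4.0 * mu * lambda * y +
                                      mu * mu * y * y);
  if (x <= 0) x = 1e-12;
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export(name = ".gibbsAlphabet")]]
List gibbsAlphabet(NumericVector y, NumericMatrix W, std::string model,
                   int niter, int burnin, int thin,
                   double nu_e, double S_e, double nu_a, double S_a,
                   double pi_in, bool estimate_pi,
                   double beta_a, double beta_b,
                   double bl_shape, double bl_rate,
                   bool fix_var, double fixed_sa2, double fixed_s2e) {
  const int n = y.size(), m = W.ncol();
  enum Model { BRR, BAYESA, BAYESB, BAYESC, BL };
  Model mod;
  if (model == "BRR") mod = BRR;
  else if (model == "BayesA") mod = BAYESA;
  else if (model == "BayesB") mod = BAYESB;
  else if (model == "BayesC") mod = BAYESC;
  else if (model == "BL") mod = BL;
  else stop("unknown Gibbs model: " + model);

  std::vector<double> xtx(m), a(m, 0.0), sj2(m, S_a), tau2(m, 1.0);
  std::vector<int> delta(m, 1);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += W(i, j) * W(i, j);
    xtx[j] = s;
  }
  double mu = mean(y);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double s2e = fix_var ? fixed_s2e : S_e;
  double sa2 = fix_var ? fixed_sa2 : S_a;
  double lambda2 = 10.0;
  double pi_cur = pi_in;
  bool spike = (mod == BAYESB || mod == BAYESC);

  std::vector<double> a_sum(m, 0.0);
  double mu_sum = 0.0, pi_sum = 0.0, lambda2_sum = 0.0;
  std::vector<double> s2e_chain;
  int nsamp = 0;

  for (int it = 0; it < niter; ++it) {
    // intercept
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = mu + ebar + R::norm_rand() * std::sqrt(s2e / n);
    double d = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= d;
    mu = mu_new;

    int m_in = 0;
    double ss_a = 0.0, ss_a_tau = 0.0, ss_tau2 = 0.0;
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0) continue;
      double aj = a[j];
      double u = aj * xtx[j];
      for (int i = 0; i < n; ++i) u += W(i, j) * e[i];
      double v;  // slab prior variance of the effect
      switch (mod) {
      case BRR: case BAYESC: v = sa2; break;
      case BAYESA: case BAYESB: v = sj2[j]; break;
      case BL: v = tau2[j] * s2e; break;
      }
      double anew;
      bool inc = true;
      if (spike && pi_cur < 1.0 - 1e-12) {
        double var0 = s2e * xtx[j];
        double var1 = v * xtx[j] * xtx[j] + var0;
        double logbf = 0.5 * std::log(var0 / var1) +
          0.5 * u * u * (1.0 / var0 - 1.0 / var1);
        double logodds = logbf + std::log(pi_cur) - std::log1p(-pi_cur);
        double p1 = 1.0 / (1.0 + std::exp(-logodds));
        inc = (R::unif_rand() < p1);
      }
      if (inc) {
        double C = xtx[j] + s2e / v;
        anew = u / C + R::norm_rand() * std::sqrt(s2e / C);
        ++m_in;
      } else {
        anew = 0.0;
      }
      if (anew != aj) {
        double diff = aj - anew;
        for (int i = 0; i < n; ++i) e[i] += W(i, j) * diff;
        a[j] = anew;
      }
      delta[j] = inc ? 1 : 0;
      if (inc) ss_a += anew * anew;
      // per-marker variance updates
      if (mod == BAYESA) {
        sj2[j] = rscinv(nu_a + 1.0, (nu_a * S_a + anew * anew) /
                        (nu_a + 1.0));
      } else if (mod == BAYESB) {
        if (inc)
          sj2[j] = rscinv(nu_a + 1.0, (nu_a * S_a + anew * anew) /
                          (nu_a + 1.0));
        else
          sj2[j] = rscinv(nu_a, S_a);
      } else if (mod == BL) {
        double aj2 = anew * anew;
        if (aj2 < 1e-12) aj2 = 1e-12;
        double itau = rinvgauss(std::sqrt(lambda2 * s2e / aj2), lambda2);
        tau2[j] = 1.0 / itau;
        ss_tau2 += tau2[j];
        ss_a_tau += aj2 / tau2[j];
      }
    }
    if (mod == BL)
      lambda2 = R::rgamma(bl_shape + m, 1.0 / (bl_rate + ss_tau2 / 2.0));
    if ((mod == BRR || mod == BAYESC) && !fix_var)
      sa2 = rscinv(nu_a + m_in, (nu_a * S_a + ss_a) /
                   (nu_a + std::max(m_in, 1)));
    if (mod == BAYESC && estimate_pi)
      pi_cur = R::rbeta(beta_a + m_in, beta_b + (m - m_in));
    if (!fix_var) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      if (mod == BL)
        s2e = rscinv(nu_e + n + m, (nu_e * S_e + sse + ss_a_tau) /
                     (nu_e + n + m));
      else
        s2e = rscinv(nu_e + n, (nu_e * S_e + sse) / (nu_e + n));
      if (!std::isfinite(s2e) || s2e <= 0)
        stop("MCMC divergence: non-finite residual variance at iteration %d",
             it + 1);
    }
    if (it >= burnin && ((it - burnin) % thin == 0)) {
      for (int j = 0; j < m; ++j) a_sum[j] += a[j];
      mu_sum += mu;
      pi_sum += pi_cur;
      lambda2_sum += lambda2;
      s2e_chain.push_back(s2e);
      ++nsamp;
    }
  }
  NumericVector amean(m);
  for (int j = 0; j < m; ++j) amean[j] = a_sum[j] / nsamp;
  return List::create(_["effects"] = amean,
                      _["intercept"] = mu_sum / nsamp,
                      _["s2e_chain"] = wrap(s2e_chain),
                      _["pi_mean"] = pi_sum / nsamp,
                      _["lambda2_mean"] = lambda2_sum / nsamp,
                      _["n_samples"] = nsamp);
}
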
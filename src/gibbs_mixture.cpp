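#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for a three-component Gaussian mixture of test statistics.
// Component 0 is the empirical null (bias = mu0, inflation = sigma0);
// components 1 and 2 absorb left/right signal. Conjugate updates:
// Dirichlet on proportions, normal on means, inverse-gamma on variances.
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export(name = ".gibbs_mixture")]]
List gibbs_mixture(NumericVector z, int niter, int burnin,
                   NumericVector prior_mu, NumericVector prior_mu_tau2,
                   NumericVector prior_a, NumericVector prior_b,
                   NumericVector dirichlet_alpha) {
  const int n = z.size();
  const int K = 3;
  RNGScope scope;

  double med = Rcpp::median(z);
  double s = Rcpp::sd(z);
  if (!(s > 0)) s = 1.0;

  std::vector<double> p(K), mu(K), sig2(K);
  p[0] = 0.9; p[1] = 0.05; p[2] = 0.05;
  mu[0] = med; mu[1] = med - 3.0 * s; mu[2] = med + 3.0 * s;
  sig2[0] = s * s; sig2[1] = s * s; sig2[2] = s * s;

  std::vector<double> sum_k(K), ssq_k(K);
  std::vector<int> n_k(K);
  std::vector<int> comp(n);

  int keep = niter - burnin;
  double acc_mu0 = 0, acc_sig0 = 0, acc_p0 = 0;
  double acc_mu0_sq = 0, acc_sig0_sq = 0;
  NumericVector mean_p(K), mean_mu(K), mean_sig(K);

  for (int it = 0; it < niter; ++it) {
    // assignments
    for (int k = 0; k < K; ++k) { n_k[k] = 0; sum_k[k] = 0; ssq_k[k] = 0; }
    for (int i = 0; i < n; ++i) {
      double w[3];
      double tot = 0;
      for (int k = 0; k < K; ++k) {
        w[k] = p[k] * R::dnorm(z[i], mu[k], std::sqrt(sig2[k]), 0);
        tot += w[k];
      }
      int k = 0;
      if (tot > 0) {
        double u = unif_rand() * tot;
        if (u > w[0]) { k = (u > w[0] + w[1]) ? 2 : 1; }
      }
      comp[i] = k;
      n_k[k] += 1;
      sum_k[k] += z[i];
    }
    // proportions ~ Dirichlet(n_k + alpha)
    double g[3], gs = 0;
    for (int k = 0; k < K; ++k) {
      g[k] = R::rgamma(n_k[k] + dirichlet_alpha[k], 1.0);
      gs += g[k];
    }
    for (int k = 0; k < K; ++k) p[k] = g[k] / gs;
    // means: normal conjugate update; signal components are constrained to
    // lie at least `sep` null-SDs away from the null mean, which is what
    // identifies the central component as the empirical null (otherwise a
    // "signal" component can camp inside the null bulk and shrink it)
    const double sep = 3.0;
    for (int k = 0; k < K; ++k) {
      double prec = n_k[k] / sig2[k] + 1.0 / prior_mu_tau2[k];
      double m = (sum_k[k] / sig2[k] + prior_mu[k] / prior_mu_tau2[k]) / prec;
      double sd = std::sqrt(1.0 / prec);
      if (k == 0) {
        mu[0] = R::rnorm(m, sd);
      } else {
        // truncated normal draw via inverse CDF
        double bound = (k == 1) ? mu[0] - sep * std::sqrt(sig2[0])
                                : mu[0] + sep * std::sqrt(sig2[0]);
        double pb = R::pnorm(bound, m, sd, 1, 0);
        double u = (k == 1) ? unif_rand() * pb
                            : pb + unif_rand() * (1.0 - pb);
        u = std::min(std::max(u, 1e-12), 1.0 - 1e-12);
        mu[k] = R::qnorm(u, m, sd, 1, 0);
      }
    }
    // variances: inverse-gamma conjugate update
    for (int k = 0; k < K; ++k) ssq_k[k] = 0;
    for (int i = 0; i < n; ++i) {
      double d = z[i] - mu[comp[i]];
      ssq_k[comp[i]] += d * d;
    }
    for (int k = 0; k < K; ++k) {
      double shape = prior_a[k] + 0.5 * n_k[k];
      double rate = prior_b[k] + 0.5 * ssq_k[k];
      sig2[k] = 1.0 / R::rgamma(shape, 1.0 / rate);
    }

    if (it >= burnin) {
      double s0 = std::sqrt(sig2[0]);
      acc_mu0 += mu[0]; acc_mu0_sq += mu[0] * mu[0];
      acc_sig0 += s0; acc_sig0_sq += s0 * s0;
      acc_p0 += p[0];
      for (int k = 0; k < K; ++k) {
        mean_p[k] += p[k]; mean_mu[k] += mu[k]; mean_sig[k] += std::sqrt(sig2[k]);
      }
    }
  }

  for (int k = 0; k < K; ++k) {
    mean_p[k] /= keep; mean_mu[k] /= keep; mean_sig[k] /= keep;
  }
  double bias = acc_mu0 / keep;
  double inflation = acc_sig0 / keep;
  double sd_mu0 = std::sqrt(std::max(0.0, acc_mu0_sq / keep - bias * bias));
  double sd_sig0 = std::sqrt(std::max(0.0, acc_sig0_sq / keep - inflation * inflation));

  return List::create(
    _["bias"] = bias, _["inflation"] = inflation,
    _["p0"] = acc_p0 / keep,
    _["proportions"] = mean_p, _["means"] = mean_mu, _["sds"] = mean_sig,
    _["posterior_sd_bias"] = sd_mu0, _["posterior_sd_inflation"] = sd_sig0);
}
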
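#include <Rcpp.h>
using namespace Rcpp;

// Single-trait Bayes-B Gibbs sampler with weighted residuals.
// Model: y = 1*mu + sum_j Z_j g_j + e, e ~ N(0, diag(1/w) * s2e).
// Prior: g_j = 0 with prob pi, else g_j ~ N(0, s2_j),
//        s2_j ~ nu_g * S_g * inv-chisq(nu_g);  s2e ~ nu_e * S_e * inv-chisq(nu_e).
// Per-locus scan: (1) locus variance from its full conditional,
// (2) indicator with g_j integrated out given that variance,
// (3) effect draw. Uses R's RNG, so set.seed() gives identical chains.
// [[Rcpp::export(name = ".bayesb_gibbs")]]
List bayesb_gibbs(NumericVector y, NumericMatrix Z, NumericVector w,
                  double pi, int chain_length, int burn_in,
                  double nu_g, double S_g, double nu_e, double S_e,
                  bool common_variance) {
  const int n = y.size(), m = Z.ncol();
  if (Z.nrow() != n || w.size() != n) stop("dimension mismatch");

  std::vector<double> g(m, 0.0), s2j(m, S_g), zwz(m), e(n);
  double mu = 0.0, sw = 0.0, swy = 0.0;
  for (int i = 0; i < n; ++i) { sw += w[i]; swy += w[i] * y[i]; }
  mu = swy / sw;
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  for (int j = 0; j < m; ++j) {
    double a = 0.0;
    for (int i = 0; i < n; ++i) a += w[i] * Z(i, j) * Z(i, j);
    zwz[j] = a;
  }
  double s2e = S_e > 0 ? S_e : 1.0;
  double var0 = 0.0;
  for (int i = 0; i < n; ++i) var0 += w[i] * e[i] * e[i];
  if (var0 > 0) s2e = var0 / n;

  const int kept = chain_length - burn_in;
  if (kept <= 0) stop("burn_in must be smaller than chain_length");
  std::vector<double> gsum(m, 0.0), gsum_in(m, 0.0);
  std::vector<int> nin(m, 0);
  double mu_sum = 0.0, s2e_sum = 0.0, fit_frac_sum = 0.0;
  double common_s2 = S_g;

  RNGScope scope;
  for (int it = 0; it < chain_length; ++it) {
    // intercept
    double r = 0.0;
    for (int i = 0; i < n; ++i) r += w[i] * (e[i] + mu);
    double mu_new = R::rnorm(r / sw, std::sqrt(s2e / sw));
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    int in_count = 0;
    double ss_g = 0.0; int n_nz = 0;
    for (int j = 0; j < m; ++j) {
      const double gj = g[j];
      // locus variance
      if (!common_variance) {
        if (gj != 0.0)
          s2j[j] = (nu_g * S_g + gj * gj) / R::rchisq(nu_g + 1.0);
        else
          s2j[j] = nu_g * S_g / R::rchisq(nu_g);
      } else {
        s2j[j] = common_s2;
      }
      // restore residual without marker j
      double rhs = 0.0;
      if (gj != 0.0) {
        for (int i = 0; i < n; ++i) {
          e[i] += Z(i, j) * gj;
          rhs += w[i] * Z(i, j) * e[i];
        }
      } else {
        for (int i = 0; i < n; ++i) rhs += w[i] * Z(i, j) * e[i];
      }
      rhs /= s2e;
      const double cj = zwz[j] / s2e;
      const double P = cj + 1.0 / s2j[j];
      const double logBF = -0.5 * std::log(s2j[j] * P) + 0.5 * rhs * rhs / P;
      double p_in;
      if (pi <= 0.0) p_in = 1.0;
      else {
        const double lodds = std::log((1.0 - pi) / pi) + logBF;
        p_in = 1.0 / (1.0 + std::exp(-lodds));
      }
      if (R::unif_rand() < p_in) {
        const double gnew = R::rnorm(rhs / P, std::sqrt(1.0 / P));
        for (int i = 0; i < n; ++i) e[i] -= Z(i, j) * gnew;
        g[j] = gnew;
        ++in_count;
        ss_g += gnew * gnew / 1.0; ++n_nz;
        if (it >= burn_in) { gsum_in[j] += gnew; ++nin[j]; }
      } else {
        g[j] = 0.0;
      }
    }
    if (common_variance) {
      common_s2 = (nu_g * S_g + ss_g) / R::rchisq(nu_g + n_nz);
    }
    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += w[i] * e[i] * e[i];
    s2e = (nu_e * S_e + sse) / R::rchisq(nu_e + n);

    if (it >= burn_in) {
      for (int j = 0; j < m; ++j) gsum[j] += g[j];
      mu_sum += mu;
      s2e_sum += s2e;
      fit_frac_sum += (double)in_count / m;
    }
  }

  NumericVector abar(m), incl(m), cond(m);
  for (int j = 0; j < m; ++j) {
    abar[j] = gsum[j] / kept;
    incl[j] = (double)nin[j] / kept;
    cond[j] = nin[j] > 0 ? gsum_in[j] / nin[j] : 0.0;
  }
  return List::create(_["abar"] = abar, _["inclusion_freq"] = incl,
                      _["abar_conditional"] = cond,
                      _["mu"] = mu_sum / kept, _["sigma2e"] = s2e_sum / kept,
                      _["mean_model_fraction"] = fit_frac_sum / kept);
}
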
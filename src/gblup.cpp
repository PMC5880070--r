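#include <Rcpp.h>
using namespace Rcpp;

// GBLUP Gibbs sampler with one or more genomic kernels and weighted
// residuals, reparameterized through the eigendecomposition of each
// kernel: g_k = U_k b_k with b_ki ~ N(0, lambda_ki * s2_k). Individuals
// with weight 0 contribute no likelihood (masked validation bulls) but
// receive genetic-value predictions. Variance components get scaled
// inverse chi-square priors unless fixed.
// [[Rcpp::export(name = ".gblup_gibbs")]]
List gblup_gibbs(NumericVector y, NumericVector w, List U_list,
                 List lam_list, int chain_length, int burn_in,
                 double nu_g, NumericVector S_g, double nu_e, double S_e,
                 bool fix_var, NumericVector s2k_fixed, double s2e_fixed) {
  const int n = y.size(), K = U_list.size();
  const int kept = chain_length - burn_in;
  if (kept <= 0) stop("burn_in must be smaller than chain_length");

  std::vector<NumericMatrix> U(K);
  std::vector<NumericVector> lam(K);
  std::vector<std::vector<double> > b(K), cw(K), bsum(K);
  std::vector<int> mk(K);
  for (int k = 0; k < K; ++k) {
    U[k] = as<NumericMatrix>(U_list[k]);
    lam[k] = as<NumericVector>(lam_list[k]);
    if (U[k].nrow() != n) stop("kernel eigenvector rows must match y");
    mk[k] = U[k].ncol();
    b[k].assign(mk[k], 0.0);
    bsum[k].assign(mk[k], 0.0);
    cw[k].assign(mk[k], 0.0);
    for (int i = 0; i < mk[k]; ++i) {
      double a = 0.0;
      for (int r = 0; r < n; ++r) a += w[r] * U[k](r, i) * U[k](r, i);
      cw[k][i] = a;
    }
  }

  double sw = 0.0; int n_obs = 0;
  for (int i = 0; i < n; ++i) { sw += w[i]; if (w[i] > 0) ++n_obs; }
  if (sw <= 0) stop("all weights are zero");

  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += w[i] * y[i];
  mu /= sw;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  std::vector<double> s2k(K);
  for (int k = 0; k < K; ++k)
    s2k[k] = fix_var ? s2k_fixed[k] : std::max(S_g[k], 1e-8);
  double s2e = fix_var ? s2e_fixed : std::max(S_e, 1e-8);

  double mu_sum = 0.0, s2e_sum = 0.0;
  NumericVector s2k_sum(K);

  RNGScope scope;
  for (int it = 0; it < chain_length; ++it) {
    // intercept (flat prior)
    double r = 0.0;
    for (int i = 0; i < n; ++i) r += w[i] * (e[i] + mu);
    double mu_new = R::rnorm(r / sw, std::sqrt(s2e / sw));
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    for (int k = 0; k < K; ++k) {
      double ssb = 0.0; int nb = 0;
      for (int i = 0; i < mk[k]; ++i) {
        if (lam[k][i] < 1e-10) continue;
        double rhs = 0.0;
        for (int rr = 0; rr < n; ++rr) rhs += w[rr] * U[k](rr, i) * e[rr];
        rhs = rhs / s2e + cw[k][i] * b[k][i] / s2e;
        const double P = cw[k][i] / s2e + 1.0 / (lam[k][i] * s2k[k]);
        const double bnew = R::rnorm(rhs / P, std::sqrt(1.0 / P));
        const double d = bnew - b[k][i];
        if (d != 0.0) for (int rr = 0; rr < n; ++rr) e[rr] -= U[k](rr, i) * d;
        b[k][i] = bnew;
        ssb += bnew * bnew / lam[k][i];
        ++nb;
      }
      if (!fix_var)
        s2k[k] = (nu_g * S_g[k] + ssb) / R::rchisq(nu_g + nb);
    }
    if (!fix_var) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += w[i] * e[i] * e[i];
      s2e = (nu_e * S_e + sse) / R::rchisq(nu_e + n_obs);
    }

    if (it >= burn_in) {
      mu_sum += mu; s2e_sum += s2e;
      for (int k = 0; k < K; ++k) {
        s2k_sum[k] += s2k[k];
        for (int i = 0; i < mk[k]; ++i) bsum[k][i] += b[k][i];
      }
    }
  }

  // posterior-mean genetic values per kernel: g_k = U_k * mean(b_k)
  NumericMatrix ghat(n, K);
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < mk[k]; ++i) {
      const double bb = bsum[k][i] / kept;
      if (bb == 0.0) continue;
      for (int rr = 0; rr < n; ++rr) ghat(rr, k) += U[k](rr, i) * bb;
    }
    s2k_sum[k] /= kept;
  }
  return List::create(_["mu"] = mu_sum / kept, _["ghat"] = ghat,
                      _["s2k"] = s2k_sum, _["s2e"] = s2e_sum / kept);
}
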
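#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Single-site Gibbs sampler for the Bayesian alphabet mixture model
//   y_i = mu + sum_j z_ij beta_j delta_j + e_i
// method codes: 0 BayesA, 1 BayesB, 2 BayesC (C0 when pi = 0), 3 BayesCpi.
// Z must arrive column-centered. Uses R's RNG so set.seed() in R gives full
// determinism. Inclusion indicators are sampled with beta_j integrated out;
// for per-marker-variance methods an excluded locus redraws its variance
// from the prior. The update order over markers is fixed ascending.
// [[Rcpp::export]]
List gibbs_chain(const arma::mat& Z, const arma::vec& y, int method,
                 double pi0, double nu_beta, double scale_beta,
                 double nu_e, double scale_e,
                 bool fix_beta_var, double sigma2_beta_fixed,
                 bool fix_e_var, double sigma2_e_fixed,
                 int n_iter, int burn_in, int thin, bool store_samples) {
  const int n = Z.n_rows;
  const int p = Z.n_cols;
  const double var_floor = 1e-8;

  arma::vec czz(p);
  for (int j = 0; j < p; ++j) czz[j] = arma::dot(Z.col(j), Z.col(j));

  arma::vec beta(p, arma::fill::zeros);
  arma::ivec delta(p, arma::fill::ones);
  const bool per_marker = (method <= 1);
  double prior_mean_var = nu_beta > 2.0
    ? nu_beta * scale_beta / (nu_beta - 2.0) : scale_beta;
  if (prior_mean_var < var_floor) prior_mean_var = var_floor;
  arma::vec sigma2_j(p);
  sigma2_j.fill(prior_mean_var);
  double sigma2_b = fix_beta_var ? sigma2_beta_fixed : prior_mean_var;
  if (per_marker && fix_beta_var) sigma2_j.fill(sigma2_beta_fixed);
  double vy = arma::var(y);
  double sigma2_e = fix_e_var ? sigma2_e_fixed : std::max(0.5 * vy, var_floor);
  double mu = arma::mean(y);
  arma::vec e = y - mu;
  double pi = pi0;

  const int n_kept_max = (n_iter - burn_in) / thin + 1;
  arma::vec eff_sum(p, arma::fill::zeros);
  arma::vec delta_sum(p, arma::fill::zeros);
  double mu_sum = 0.0, s2e_sum = 0.0, s2b_sum = 0.0, pi_sum = 0.0;
  std::vector<double> pi_samples;
  arma::mat samples;
  if (store_samples) samples.set_size(n_kept_max, p);
  int kept = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // intercept
    e += mu;
    mu = R::rnorm(arma::mean(e), std::sqrt(sigma2_e / n));
    e -= mu;

    // marker effects and inclusion indicators, fixed ascending order
    int m_incl = 0;
    double* ep = e.memptr();
    for (int j = 0; j < p; ++j) {
      if (czz[j] <= 0.0) { beta[j] = 0.0; delta[j] = 0; continue; }
      const double* zj = Z.colptr(j);
      const double b_old = (delta[j] == 1) ? beta[j] : 0.0;
      // r = z_j' e_adj where e_adj excludes marker j's current contribution
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += zj[i] * ep[i];
      r += czz[j] * b_old;
      const double s2j = per_marker ? sigma2_j[j] : sigma2_b;
      bool include = true;
      if (pi > 0.0) {
        // r | delta=0 ~ N(0, czz s2e); r | delta=1 ~ N(0, czz s2e + czz^2 s2j)
        const double v0 = czz[j] * sigma2_e;
        const double v1 = v0 + czz[j] * czz[j] * s2j;
        const double log_odds = std::log((1.0 - pi) / pi)
          - 0.5 * (std::log(v1) - std::log(v0))
          - 0.5 * r * r * (1.0 / v1 - 1.0 / v0);
        double prob;
        if (log_odds > 35.0) prob = 1.0;
        else if (log_odds < -35.0) prob = 0.0;
        else prob = 1.0 / (1.0 + std::exp(-log_odds));
        include = (R::runif(0.0, 1.0) < prob);
      }
      double b_new = 0.0;
      if (include) {
        const double lhs = czz[j] + sigma2_e / s2j;
        b_new = R::rnorm(r / lhs, std::sqrt(sigma2_e / lhs));
        beta[j] = b_new;
        delta[j] = 1;
        ++m_incl;
      } else {
        beta[j] = 0.0;
        delta[j] = 0;
      }
      const double diff = b_old - b_new;
      if (diff != 0.0) {
        for (int i = 0; i < n; ++i) ep[i] += zj[i] * diff;
      }
    }

    // effect variances
    if (!fix_beta_var) {
      if (per_marker) {
        for (int j = 0; j < p; ++j) {
          if (czz[j] <= 0.0) continue;
          double s2;
          if (delta[j] == 1) {
            s2 = (nu_beta * scale_beta + beta[j] * beta[j])
              / R::rchisq(nu_beta + 1.0);
          } else {
            // excluded locus: draw from the prior
            s2 = nu_beta * scale_beta / R::rchisq(nu_beta);
          }
          sigma2_j[j] = std::max(s2, var_floor);
        }
      } else {
        double ssb = 0.0;
        for (int j = 0; j < p; ++j) {
          if (delta[j] == 1) ssb += beta[j] * beta[j];
        }
        sigma2_b = (nu_beta * scale_beta + ssb) / R::rchisq(nu_beta + m_incl);
        if (sigma2_b < var_floor) sigma2_b = var_floor;
      }
    }

    // residual variance (floored: at h^2 = 1 it converges towards zero)
    if (!fix_e_var) {
      sigma2_e = (nu_e * scale_e + arma::dot(e, e)) / R::rchisq(nu_e + n);
      if (sigma2_e < var_floor) sigma2_e = var_floor;
    }

    // mixture proportion, uniform prior
    if (method == 3) {
      pi = R::rbeta(p - m_incl + 1.0, m_incl + 1.0);
      if (pi < 1e-8) pi = 1e-8;
      if (pi > 1.0 - 1e-8) pi = 1.0 - 1e-8;
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      for (int j = 0; j < p; ++j) {
        const double eff = delta[j] == 1 ? beta[j] : 0.0;
        eff_sum[j] += eff;
        delta_sum[j] += delta[j];
        if (store_samples) samples(kept, j) = eff;
      }
      mu_sum += mu;
      s2e_sum += sigma2_e;
      s2b_sum += per_marker ? arma::mean(sigma2_j) : sigma2_b;
      if (method == 3) { pi_sum += pi; pi_samples.push_back(pi); }
      ++kept;
    }
  }

  if (kept == 0) stop("no post-burn-in samples were retained");
  List out = List::create(
    Named("effect") = eff_sum / kept,
    Named("inclusion") = delta_sum / kept,
    Named("mu") = mu_sum / kept,
    Named("sigma2_e") = s2e_sum / kept,
    Named("sigma2_beta") = s2b_sum / kept,
    Named("pi") = method == 3 ? pi_sum / kept : pi0,
    Named("n_kept") = kept);
  if (method == 3) out["pi_samples"] = NumericVector(pi_samples.begin(),
                                                     pi_samples.end());
  if (store_samples) out["samples"] = samples.rows(0, kept - 1);
  return out;
}
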
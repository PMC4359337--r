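// Stochastic EM sweep for the joint spike-and-slab trans-eQTL model.
//
// Model, per transcript j (columns of Y, standardized) and SNP k (columns of
// Zc, mean-centered dosages):
//
//   y_ij = beta_j + sum_k Zc_ik * gamma_jk + eps_ij,  eps ~ N(0, sigma2_j)
//   gamma_jk = 0                      with prob 1 - pi_k   (spike)
//   gamma_jk ~ N(0, slab_var_k)       with prob pi_k       (slab)
//
// S-step: eta_jk ~ Bernoulli of its conditional posterior, integrating the
// candidate effect over the slab (closed-form Bayes factor against the
// spike).  SNPs are scanned in fixed index order within a sweep, residuals
// updated after each SNP.  M-step (MAP): per-transcript slab-penalized
// least squares on the active columns (ridge with per-effect penalty
// sigma2_j / slab_var_k, the conditional posterior mode given eta), pi_k as
// the bounded fraction of active transcripts, and posterior-mode updates of
// slab_var_k and sigma2_j under weak inverse-gamma priors.  Unpenalized ML
// updates are degenerate here: in a small sample subset a handful of active
// effects can interpolate a transcript, collapse sigma2_j, inflate every
// Bayes factor and saturate the model.  Uses R's RNG so set.seed() governs.

#include <RcppArmadillo.h>
using namespace Rcpp;

static const double RESID_VAR_MIN = 1e-8;

// Ridge solve of r on X's columns with per-column penalties; on a singular
// system (only possible with zero penalties) drop the last (later-indexed)
// column and retry.  Returns number dropped.
static int ls_active(const arma::mat& X, const arma::vec& r,
                     const arma::vec& penalty, arma::vec& coef,
                     arma::uvec& kept) {
  arma::uword p = X.n_cols;
  kept = arma::regspace<arma::uvec>(0, p - 1);
  int dropped = 0;
  while (kept.n_elem > 0) {
    arma::mat Xk = X.cols(kept);
    arma::mat XtX = Xk.t() * Xk;
    XtX.diag() += penalty.elem(kept);
    arma::vec Xtr = Xk.t() * r;
    arma::vec g;
    bool ok = arma::solve(g, XtX, Xtr, arma::solve_opts::no_approx);
    if (ok && g.is_finite()) { coef = g; return dropped; }
    kept.shed_row(kept.n_elem - 1);
    ++dropped;
  }
  coef.reset();
  return dropped;
}

// [[Rcpp::export(name = ".sem_run_cpp")]]
List sem_run_cpp(const arma::mat& Y, const arma::mat& Zc,
                 arma::vec beta, arma::mat gamma, arma::imat eta,
                 arma::vec pi, arma::vec slab_var, arma::vec resid_var,
                 int n_iter, int burn_in,
                 double pi_lo, double pi_hi, double slab_floor,
                 bool update_pi, bool update_slab_var, bool update_resid_var,
                 double resid_prior_shape, double resid_prior_scale,
                 double slab_prior_shape, double slab_prior_scale,
                 double pi_pseudo) {
  const arma::uword n = Y.n_rows, J = Y.n_cols, K = Zc.n_cols;
  arma::mat support(J, K, arma::fill::zeros);
  arma::mat incl_prob(J, K, arma::fill::zeros);
  arma::vec szz(K);
  for (arma::uword k = 0; k < K; ++k) szz(k) = arma::dot(Zc.col(k), Zc.col(k));
  long n_collinear = 0;
  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    // residual matrix under current state
    arma::mat R = Y - Zc * gamma.t();
    R.each_row() -= beta.t();

    // ---- S-step: scan SNPs in index order, residuals updated in place
    for (arma::uword k = 0; k < K; ++k) {
      if (szz(k) <= 0) continue;  // degenerate column: never included
      arma::rowvec b = Zc.col(k).t() * R;      // partial, excludes SNP k ...
      b += szz(k) * gamma.col(k).t();          // ... after adding k back
      const double v = slab_var(k);
      const double lodds_prior = std::log(pi(k)) - std::log1p(-pi(k));
      for (arma::uword j = 0; j < J; ++j) {
        const double s2 = resid_var(j);
        const double denom = szz(k) + s2 / v;
        const double lbf = 0.5 * b(j) * b(j) / (s2 * denom)
                         - 0.5 * std::log1p(v * szz(k) / s2);
        const double p = 1.0 / (1.0 + std::exp(-(lodds_prior + lbf)));
        incl_prob(j, k) = p;
        const int e_new = (unif_rand() < p) ? 1 : 0;
        const double g_new = e_new ? b(j) / denom : 0.0;  // posterior mean
        const double diff = gamma(j, k) - g_new;
        if (diff != 0.0) R.col(j) += Zc.col(k) * diff;
        eta(j, k) = e_new;
        gamma(j, k) = g_new;
      }
    }

    // ---- M-step
    for (arma::uword j = 0; j < J; ++j) {
      arma::uvec act = arma::find(eta.row(j).t() == 1);
      beta(j) = arma::mean(Y.col(j));  // Zc centered: intercept = column mean
      arma::vec resid;
      gamma.row(j).zeros();
      if (act.n_elem == 0) {
        resid = Y.col(j) - beta(j);
      } else {
        arma::mat X = Zc.cols(act);
        arma::vec penalty(act.n_elem);
        for (arma::uword m = 0; m < act.n_elem; ++m)
          penalty(m) = resid_var(j) / slab_var(act(m));
        arma::vec coef;
        arma::uvec kept;
        int drp = ls_active(X, Y.col(j) - beta(j), penalty, coef, kept);
        n_collinear += drp;
        if (drp > 0) {  // dropped effects leave the active set this iteration
          arma::ivec e(act.n_elem, arma::fill::zeros);
          for (arma::uword m = 0; m < kept.n_elem; ++m) e(kept(m)) = 1;
          for (arma::uword m = 0; m < act.n_elem; ++m) eta(j, act(m)) = e(m);
        }
        resid = Y.col(j) - beta(j);
        for (arma::uword m = 0; m < kept.n_elem; ++m) {
          gamma(j, act(kept(m))) = coef(m);
          resid -= Zc.col(act(kept(m))) * coef(m);
        }
      }
      if (update_resid_var) {
        // posterior mode of IG(a0 + n/2, b0 + RSS/2)
        const double rss = arma::dot(resid, resid);
        resid_var(j) = std::max(
            (2.0 * resid_prior_scale + rss) / (2.0 * resid_prior_shape + n + 2.0),
            RESID_VAR_MIN);
      }
    }
    for (arma::uword k = 0; k < K; ++k) {
      if (update_pi) {
        // MAP under a Beta(1, 1 + pi_pseudo) prior: the raw active fraction
        // is a near-neutral random walk under the null (the expected Bayes
        // factor is 1), so without the pseudo-count anchor pi drifts
        double m = 0.0;
        for (arma::uword j = 0; j < J; ++j) m += eta(j, k);
        pi(k) = std::min(std::max(m / (J + pi_pseudo), pi_lo), pi_hi);
      }
      if (update_slab_var) {
        // posterior mode of IG(a0 + m/2, b0 + sum(gamma^2)/2); with an empty
        // active set this relaxes to the prior mode instead of collapsing
        arma::uvec act = arma::find(eta.col(k) == 1);
        double ss = 0.0;
        for (arma::uword m = 0; m < act.n_elem; ++m)
          ss += gamma(act(m), k) * gamma(act(m), k);
        slab_var(k) = std::max(
            (2.0 * slab_prior_scale + ss) /
                (2.0 * slab_prior_shape + act.n_elem + 2.0),
            slab_floor);
      }
    }

    if (it >= burn_in)
      for (arma::uword k = 0; k < K; ++k)
        for (arma::uword j = 0; j < J; ++j)
          support(j, k) += eta(j, k);
  }

  const int n_post = n_iter - burn_in;
  if (n_post > 0) support /= n_post;

  return List::create(
      _["support"] = support, _["beta"] = beta, _["gamma"] = gamma,
      _["eta"] = eta, _["pi"] = pi, _["slab_var"] = slab_var,
      _["resid_var"] = resid_var, _["incl_prob"] = incl_prob,
      _["n_collinear_drops"] = (double)n_collinear,
      _["n_post_burnin"] = n_post);
}
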
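// Gibbs sampler for the Bayesian penalised linear-regression EWAS:
// y = X beta + e with a spike at the origin plus a four-component Gaussian
// mixture prior on each coefficient (slab variances are fixed fractions of
// a common sampled scale sigma2_beta). Uses R's RNG so set.seed() in R
// fully determines the chain.
//
// For moderate p the sampler caches C = X'X and maintains the sufficient
// statistics u = X'r and w = C beta with rank-one updates (only active
// coefficients touch them), turning each sweep from O(n p) into
// O(p + k p) with k = number of moving coefficients. Beyond the cache
// threshold it streams over X columns instead.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double rinvchisq(double df, double scale) {
  // scaled inverse chi-square draw: df * scale / chisq(df)
  return df * scale / R::rchisq(df);
}

static double popvar(const arma::vec& x) {
  double m = arma::mean(x);
  return arma::mean(arma::square(x - m));
}

// [[Rcpp::export(name = ".gibbs_cpp")]]
List gibbs_cpp(const arma::mat& X, const arma::vec& y,
               const arma::vec& slab_fracs,      // active slab variance fractions
               const arma::ivec& slab_index,     // 1-based index into the 4 slots
               bool spike,
               int burn_in, int iters, int thin,
               double nu_beta, double s2_beta_scale,
               double nu_e, double s2_e_scale,
               Nullable<NumericVector> fixed_pi_,
               double fixed_sigma2_beta,         // <0 means sample
               double fixed_sigma2_e,
               bool random_scan,
               bool check_residual,
               int cache_max_p) {
  const int n = X.n_rows, p = X.n_cols;
  const int n_slab = slab_fracs.n_elem;
  const int n_comp = n_slab + (spike ? 1 : 0); // categorical dimension
  const int n_keep = iters / thin;
  const bool cache = p <= cache_max_p;

  arma::vec xtx(p);
  for (int j = 0; j < p; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));
  const arma::vec xty = X.t() * y;
  const double yty = arma::dot(y, y);
  const double vy = popvar(y);

  arma::mat C;
  if (cache) C = X.t() * X;

  bool fix_pi = fixed_pi_.isNotNull();
  arma::vec pi_fix;
  if (fix_pi) {
    NumericVector fp(fixed_pi_);
    pi_fix = arma::vec(fp.begin(), fp.size());
  }

  // state
  arma::vec beta(p, arma::fill::zeros);
  arma::ivec comp(p, arma::fill::zeros); // 0 = spike/null; 1..4 = slab slot
  arma::vec u = xty;                     // X'r with r = y - X beta
  arma::vec w(p, arma::fill::zeros);     // C beta (cache mode)
  arma::vec r;                           // explicit residual (stream mode)
  if (!cache || check_residual) r = y;
  double sigma2_e = fixed_sigma2_e > 0 ? fixed_sigma2_e : vy;
  double sigma2_b = fixed_sigma2_beta > 0 ? fixed_sigma2_beta : 0.01;
  arma::vec pi(n_comp);
  pi.fill(1.0 / n_comp);
  if (fix_pi) pi = pi_fix;

  // accumulators over retained samples
  arma::vec pip_count(p, arma::fill::zeros);
  arma::vec beta_sum(p, arma::fill::zeros);
  arma::mat comp_count(p, 5, arma::fill::zeros); // spike + 4 slab slots
  arma::mat pi_samples(n_keep, 5, arma::fill::zeros);
  arma::vec s2b_samples(n_keep), s2e_samples(n_keep), vexp_samples(n_keep);
  double max_drift = 0.0;

  arma::vec logw(n_comp);
  arma::uvec order(p);
  for (int j = 0; j < p; ++j) order(j) = j;
  // slot label (1..4) -> active slab position, for count/scale lookups
  int slot2act[5] = {-1, -1, -1, -1, -1};
  for (int k = 0; k < n_slab; ++k) slot2act[slab_index(k)] = k;

  int keep_i = 0;
  const int total = burn_in + iters;
  for (int it = 1; it <= total; ++it) {
    if (random_scan) {
      // Fisher-Yates with R's RNG for reproducibility
      for (int j = p - 1; j > 0; --j) {
        int k = (int)std::floor(unif_rand() * (j + 1));
        std::swap(order(j), order(k));
      }
    }
    for (int jj = 0; jj < p; ++jj) {
      const int j = order(jj);
      const double bj = beta(j);
      const double rhs = cache ? (u(j) + xtx(j) * bj)
                               : (arma::dot(X.col(j), r) + xtx(j) * bj);
      // component log-weights (effect marginalized analytically)
      int base = 0;
      if (spike) { logw(0) = std::log(pi(0)); base = 1; }
      for (int k = 0; k < n_slab; ++k) {
        double s2k = slab_fracs(k) * sigma2_b;
        double denom = xtx(j) * s2k + sigma2_e;
        logw(base + k) = std::log(pi(base + k))
          - 0.5 * std::log(denom / sigma2_e)
          + 0.5 * rhs * rhs * s2k / (sigma2_e * denom);
      }
      double mx = logw.max();
      arma::vec wgt = arma::exp(logw - mx);
      wgt /= arma::accu(wgt);
      double uu = unif_rand(), acc = 0.0;
      int pick = n_comp - 1;
      for (int k = 0; k < n_comp; ++k) {
        acc += wgt(k);
        if (uu <= acc) { pick = k; break; }
      }
      double bnew = 0.0;
      int cnew = 0;
      if (!(spike && pick == 0)) {
        int k = spike ? pick - 1 : pick;
        double s2k = slab_fracs(k) * sigma2_b;
        double post_var = sigma2_e / (xtx(j) + sigma2_e / s2k);
        double post_mean = rhs / (xtx(j) + sigma2_e / s2k);
        bnew = post_mean + std::sqrt(post_var) * norm_rand();
        cnew = slab_index(k); // 1..4 slot label
      }
      const double delta = bj - bnew; // r gains x_j * delta
      if (delta != 0.0) {
        if (cache) {
          u += C.col(j) * delta;
          w -= C.col(j) * delta; // w = C beta
        } else {
          r += X.col(j) * delta;
        }
        if (cache && check_residual) r += X.col(j) * delta;
      }
      beta(j) = bnew;
      comp(j) = cnew;
      if (!std::isfinite(bnew)) stop("non-finite coefficient draw at CpG %d", j + 1);
    }

    // quadratic forms over the active set
    double btxty = 0.0, btCb = 0.0, ssq_scaled = 0.0;
    int m_active = 0;
    arma::vec counts(n_comp, arma::fill::zeros);
    if (spike) counts(0) = 0.0;
    for (int j = 0; j < p; ++j) {
      if (comp(j) > 0) {
        ++m_active;
        btxty += beta(j) * xty(j);
        if (cache) btCb += beta(j) * w(j);
        ssq_scaled += beta(j) * beta(j) / slab_fracs(slot2act[comp(j)]);
        counts((spike ? 1 : 0) + slot2act[comp(j)]) += 1.0;
      } else if (spike) {
        counts(0) += 1.0;
      }
    }
    double rss = cache ? (yty - 2.0 * btxty + btCb) : arma::dot(r, r);
    if (rss < 0) rss = 0;

    // mixture proportions (Dirichlet(1,...,1) prior)
    if (!fix_pi) {
      double tot = 0.0;
      for (int k = 0; k < n_comp; ++k) {
        double g = R::rgamma(counts(k) + 1.0, 1.0);
        pi(k) = g; tot += g;
      }
      pi /= tot;
    }

    // effect-scale variance
    if (fixed_sigma2_beta <= 0) {
      sigma2_b = rinvchisq(nu_beta + m_active,
                           (nu_beta * s2_beta_scale + ssq_scaled) /
                             (nu_beta + m_active));
    }

    // residual variance
    if (fixed_sigma2_e <= 0) {
      sigma2_e = rinvchisq(nu_e + n, (nu_e * s2_e_scale + rss) / (nu_e + n));
    }
    if (!std::isfinite(sigma2_e) || !std::isfinite(sigma2_b))
      stop("non-finite variance draw");

    if (check_residual) {
      // drift of the maintained statistic against a from-scratch recompute
      if (cache) {
        arma::vec u_exact = xty - C * beta;
        double d = arma::abs(u - u_exact).max();
        if (d > max_drift) max_drift = d;
      } else {
        arma::vec r_exact = y - X * beta;
        double d = arma::abs(r - r_exact).max();
        if (d > max_drift) max_drift = d;
      }
    }

    if (it > burn_in && (it - burn_in) % thin == 0) {
      // g = X beta is centered (X columns centered), so var(g) = b'Cb / n
      double var_g = cache ? (btCb / n)
                           : popvar(y - r);
      vexp_samples(keep_i) = var_g / vy;
      s2b_samples(keep_i) = sigma2_b;
      s2e_samples(keep_i) = sigma2_e;
      if (spike) pi_samples(keep_i, 0) = pi(0);
      for (int k = 0; k < n_slab; ++k)
        pi_samples(keep_i, slab_index(k)) = pi((spike ? 1 : 0) + k);
      for (int j = 0; j < p; ++j) {
        beta_sum(j) += beta(j);
        if (comp(j) > 0) pip_count(j) += 1.0;
        comp_count(j, comp(j)) += 1.0;
      }
      ++keep_i;
    }
  }

  arma::vec r_final = y - X * beta;
  return List::create(
    _["pip"] = pip_count / std::max(n_keep, 1),
    _["post_mean"] = beta_sum / std::max(n_keep, 1),
    _["comp_prob"] = comp_count / std::max(n_keep, 1),
    _["pi_samples"] = pi_samples,
    _["sigma2_beta"] = s2b_samples,
    _["sigma2_e"] = s2e_samples,
    _["vexp"] = vexp_samples,
    _["n_retained"] = n_keep,
    _["beta_last"] = beta,
    _["residual_last"] = r_final,
    _["max_residual_drift"] = max_drift);
}
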
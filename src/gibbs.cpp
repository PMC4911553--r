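#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Multi-kernel Gibbs sampler in the factor basis.
//
// Each random term t has covariance sigma2_t * Phi_t Phi_t' and is
// represented by coordinates b_t with prior N(0, sigma2_t I).  Training rows
// of Phi act as regressors; single-site conjugate updates per coordinate,
// scaled-inverse-chi-square updates for the variances, flat prior on mu.
// Uses R's RNG, so set.seed() in R gives bit-for-bit determinism.
//
// fixed_var / fixed_var_e: negative => sample the variance, otherwise the
// variance is held at the given value (used for closed-form checks).

// Generalized-Gibbs scale move for one term: propose (b, sigma2_t) ->
// (alpha b, alpha^2 sigma2_t).  With the scaled-inverse-chi-square prior
// (nu, S) on sigma2_t and Gaussian likelihood, the invariant density of
// t = log(alpha) is
//   f(t) = -nu t - (a^2 u'u - 2 a u'r) / (2 sigma2_e) - S / (2 a^2 sigma2_t)
// (a = exp(t)); sampled by slice sampling with stepping out.  The move
// travels along the scale direction that single-site updates mix slowly on.
static double draw_log_scale(double uu, double ur, double s2e,
                             double S, double nu, double s2t) {
  auto logf = [&](double t) {
    const double a = std::exp(t);
    return -nu * t - (a * a * uu - 2.0 * a * ur) / (2.0 * s2e)
           - S / (2.0 * a * a * s2t);
  };
  const double f0 = logf(0.0);
  const double level = f0 - R::exp_rand();
  double lo = -1.0, hi = 1.0;
  for (int i = 0; i < 50 && logf(lo) > level; ++i) lo -= 1.0;
  for (int i = 0; i < 50 && logf(hi) > level; ++i) hi += 1.0;
  for (int i = 0; i < 100; ++i) {
    const double t = lo + R::unif_rand() * (hi - lo);
    if (logf(t) >= level) return t;
    if (t < 0.0) lo = t; else hi = t;
  }
  return 0.0;
}

// [[Rcpp::export(name = ".gibbs_multikernel")]]
List gibbs_multikernel(const arma::vec& y_train,
                       const List& Phi_full,
                       const arma::uvec& train,
                       const arma::vec& prior_S,
                       const arma::vec& prior_nu,
                       double prior_S_e, double prior_nu_e,
                       const arma::vec& fixed_var,
                       double fixed_var_e,
                       int n_iter, int burn_in, int thin) {
  const int T = Phi_full.size();
  const int n = y_train.n_elem;
  if (n < 1) stop("no training observations");

  std::vector<arma::mat> Phi(T), Ptr(T);
  std::vector<arma::vec> xtx(T), b(T);
  // contiguous nonzero support of each training column (site-blocked
  // interaction factors are sparse; dense columns get the full range)
  std::vector<arma::uvec> c_lo(T), c_hi(T), f_lo(T), f_hi(T);
  int n_obs = 0;
  auto support = [](const arma::mat& M, arma::uvec& lo, arma::uvec& hi) {
    lo.set_size(M.n_cols); hi.set_size(M.n_cols);
    for (arma::uword j = 0; j < M.n_cols; ++j) {
      arma::uword a = 0, z = M.n_rows;
      while (a < z && M(a, j) == 0.0) ++a;
      while (z > a && M(z - 1, j) == 0.0) --z;
      lo(j) = a; hi(j) = z;   // half-open [a, z)
    }
  };
  for (int t = 0; t < T; ++t) {
    Phi[t] = as<arma::mat>(Phi_full[t]);
    n_obs = Phi[t].n_rows;
    Ptr[t] = Phi[t].rows(train);
    xtx[t] = arma::sum(arma::square(Ptr[t]), 0).t();
    b[t] = arma::zeros(Phi[t].n_cols);
    support(Ptr[t], c_lo[t], c_hi[t]);
    support(Phi[t], f_lo[t], f_hi[t]);
  }

  double mu = arma::mean(y_train);
  arma::vec sigma2(T);
  for (int t = 0; t < T; ++t)
    sigma2(t) = (fixed_var(t) >= 0.0) ? fixed_var(t)
                                      : prior_S(t) / (prior_nu(t) + 2.0);
  double sig2e = (fixed_var_e >= 0.0) ? fixed_var_e
                                      : prior_S_e / (prior_nu_e + 2.0);
  arma::vec e = y_train - mu;

  const int n_saved = (thin > 0) ? (n_iter - burn_in) / thin : 0;
  if (n_saved < 1) stop("no post-burn-in draws would be saved");
  arma::vec mu_chain(n_saved);
  arma::mat var_chain(n_saved, T + 1);
  std::vector<arma::vec> u_sum(T), u_ss(T), b_sum(T);
  for (int t = 0; t < T; ++t) {
    u_sum[t] = arma::zeros(n_obs);
    u_ss[t] = arma::zeros(n_obs);
    b_sum[t] = arma::zeros(b[t].n_elem);
  }
  arma::vec yhat_sum = arma::zeros(n_obs), yhat_ss = arma::zeros(n_obs);
  int saved = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // grand mean, flat prior
    double mnew = mu + arma::mean(e) + R::rnorm(0.0, std::sqrt(sig2e / n));
    e -= (mnew - mu);
    mu = mnew;

    for (int t = 0; t < T; ++t) {
      arma::mat& P = Ptr[t];
      arma::vec& bt = b[t];
      const double lambda = sig2e / sigma2(t);
      for (arma::uword i = 0; i < bt.n_elem; ++i) {
        const arma::uword a = c_lo[t](i), z = c_hi[t](i);
        if (a >= z) continue;
        const double xi = xtx[t](i);
        const double* pc = P.colptr(i);
        double dot = 0.0;
        for (arma::uword r = a; r < z; ++r) dot += pc[r] * e(r);
        const double xe = dot + xi * bt(i);
        const double c = xi + lambda;
        const double bn = xe / c + R::norm_rand() * std::sqrt(sig2e / c);
        const double d = bn - bt(i);
        if (d != 0.0) {
          for (arma::uword r = a; r < z; ++r) e(r) -= pc[r] * d;
          bt(i) = bn;
        }
      }
      if (fixed_var(t) < 0.0) {
        // scale move: improves mixing of sigma2_t when many coordinates
        // are weakly informed (low-eigenvalue directions)
        arma::vec u(n, arma::fill::zeros);
        for (arma::uword i = 0; i < bt.n_elem; ++i) {
          const double bi = bt(i);
          if (bi == 0.0) continue;
          const double* pc = P.colptr(i);
          for (arma::uword r = c_lo[t](i); r < c_hi[t](i); ++r)
            u(r) += pc[r] * bi;
        }
        const double uu = arma::dot(u, u);
        if (uu > 0.0) {
          const double ur = arma::dot(u, e) + uu;
          const double alpha = std::exp(
            draw_log_scale(uu, ur, sig2e, prior_S(t), prior_nu(t),
                           sigma2(t)));
          bt *= alpha;
          sigma2(t) *= alpha * alpha;
          e += (1.0 - alpha) * u;
        }
        const double ss = arma::dot(bt, bt) + prior_S(t);
        sigma2(t) = ss / R::rchisq(prior_nu(t) + bt.n_elem);
      }
    }
    if (fixed_var_e < 0.0) {
      const double ss = arma::dot(e, e) + prior_S_e;
      sig2e = ss / R::rchisq(prior_nu_e + n);
    }

    if (it > burn_in && ((it - burn_in) % thin == 0) && saved < n_saved) {
      mu_chain(saved) = mu;
      for (int t = 0; t < T; ++t) var_chain(saved, t) = sigma2(t);
      var_chain(saved, T) = sig2e;
      arma::vec yhat(n_obs, arma::fill::value(mu));
      for (int t = 0; t < T; ++t) {
        arma::vec u(n_obs, arma::fill::zeros);
        for (arma::uword i = 0; i < b[t].n_elem; ++i) {
          const double bi = b[t](i);
          if (bi == 0.0) continue;
          const double* pc = Phi[t].colptr(i);
          for (arma::uword r = f_lo[t](i); r < f_hi[t](i); ++r)
            u(r) += pc[r] * bi;
        }
        u_sum[t] += u;
        u_ss[t] += arma::square(u);
        b_sum[t] += b[t];
        yhat += u;
      }
      yhat_sum += yhat;
      yhat_ss += arma::square(yhat);
      ++saved;
    }
    if (it % 500 == 0) Rcpp::checkUserInterrupt();
  }

  auto post_sd = [&](const arma::vec& s, const arma::vec& ss) {
    arma::vec v = ss / saved - arma::square(s / saved);
    v.transform([](double x) { return x > 0.0 ? std::sqrt(x) : 0.0; });
    return v;
  };
  List u_mean(T), u_sd(T), b_mean(T);
  for (int t = 0; t < T; ++t) {
    u_mean[t] = u_sum[t] / saved;
    u_sd[t] = post_sd(u_sum[t], u_ss[t]);
    b_mean[t] = b_sum[t] / saved;
  }
  return List::create(
    _["mu_chain"] = mu_chain,
    _["var_chain"] = var_chain,
    _["u_mean"] = u_mean,
    _["u_sd"] = u_sd,
    _["b_mean"] = b_mean,
    _["yhat_mean"] = yhat_sum / saved,
    _["yhat_sd"] = post_sd(yhat_sum, yhat_ss),
    _["n_saved"] = saved);
}
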
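#include <Rcpp.h>
using namespace Rcpp;

// NB2 log-pmf summed over stations, parameterised by the linear predictor
// eta = log(mu) and the size (overdispersion) parameter r:
//   ll_i = lgamma(y_i + r) - lgamma(r) - lgamma(y_i + 1)
//          + r*log(r) + y_i*eta_i - (y_i + r)*log(r + exp(eta_i))
// A lookup table over the unique counts keeps the lgamma cost independent
// of the number of stations, which matters inside the sampler loop.
static double nb_loglik_eta(const std::vector<int>& y,
                            const std::vector<double>& eta,
                            double r,
                            const std::vector<double>& lgyfact,
                            const std::vector<int>& uidx,
                            const std::vector<int>& uy) {
  const int nu = (int) uy.size();
  std::vector<double> tab(nu);
  const double lgr = lgamma(r);
  for (int k = 0; k < nu; ++k) tab[k] = lgamma((double) uy[k] + r) - lgr;
  const double rlogr = r * std::log(r);
  double ll = 0.0;
  const int n = (int) y.size();
  for (int i = 0; i < n; ++i) {
    const double mu = std::exp(eta[i]);
    ll += tab[uidx[i]] - lgyfact[i] + rlogr + y[i] * eta[i]
          - (y[i] + r) * std::log(r + mu);
  }
  return ll;
}

// Same sum restricted to one array's stations (used for eps_j updates).
static double nb_loglik_subset(const std::vector<int>& y,
                               const std::vector<double>& eta,
                               double r,
                               const std::vector<double>& lgyfact,
                               const std::vector<int>& uidx,
                               const std::vector<int>& uy,
                               const std::vector<int>& rows) {
  const int nu = (int) uy.size();
  std::vector<double> tab(nu);
  const double lgr = lgamma(r);
  for (int k = 0; k < nu; ++k) tab[k] = lgamma((double) uy[k] + r) - lgr;
  const double rlogr = r * std::log(r);
  double ll = 0.0;
  for (size_t s = 0; s < rows.size(); ++s) {
    const int i = rows[s];
    const double mu = std::exp(eta[i]);
    ll += tab[uidx[i]] - lgyfact[i] + rlogr + y[i] * eta[i]
          - (y[i] + r) * std::log(r + mu);
  }
  return ll;
}

static inline double dnorm_log(double x, double m, double s) {
  const double z = (x - m) / s;
  return -0.91893853320467274178 - std::log(s) - 0.5 * z * z;
}

// [[Rcpp::export]]
double nb_loglik_eta_cpp(IntegerVector y, NumericVector eta, double r) {
  const int n = y.size();
  std::vector<int> yy(n);
  std::vector<double> ee(n), lgyfact(n);
  for (int i = 0; i < n; ++i) {
    yy[i] = y[i];
    ee[i] = eta[i];
    lgyfact[i] = lgamma((double) y[i] + 1.0);
  }
  // unique counts
  std::vector<int> uy(yy);
  std::sort(uy.begin(), uy.end());
  uy.erase(std::unique(uy.begin(), uy.end()), uy.end());
  std::vector<int> uidx(n);
  for (int i = 0; i < n; ++i)
    uidx[i] = (int) (std::lower_bound(uy.begin(), uy.end(), yy[i]) - uy.begin());
  return nb_loglik_eta(yy, ee, r, lgyfact, uidx, uy);
}

struct AdaptStep {
  double step;
  int n_try, n_acc;
  AdaptStep(double s) : step(s), n_try(0), n_acc(0) {}
  void tally(bool acc) { ++n_try; if (acc) ++n_acc; }
  // Robbins-Monro-flavoured tuning toward ~0.44 acceptance, used only
  // during burn-in so the retained chain is a fixed-kernel Markov chain.
  void maybe_adapt() {
    if (n_try >= 50) {
      const double rate = (double) n_acc / (double) n_try;
      step *= std::exp(rate - 0.44);
      if (step < 1e-4) step = 1e-4;
      if (step > 10.0) step = 10.0;
      n_try = 0; n_acc = 0;
    }
  }
};

// Adaptive Metropolis-within-Gibbs for the two-level NB site-use model:
//   y_i ~ NB2(mu_i = exp(eta_i), r)
//   eta_i = sum_k beta_k X_ik + eps_{array(i)}        (k = 1..7, no intercept)
//   eps_j ~ Normal(beta8 * rec_land_j, sigma_array^2)
// Priors: beta_k ~ U(-beta_bound, beta_bound), sigma_array ~ U(0, sigma_upper),
//         r ~ U(r_lower, r_upper).
// init packs c(beta[1..8], eps[1..J], sigma_array, r).
// [[Rcpp::export]]
List mwg_nb_sampler(IntegerVector y, NumericMatrix X, IntegerVector array_index,
                    NumericVector rec_land, int n_iter, int burn_in, int thin,
                    NumericVector init, double beta_bound, double sigma_upper,
                    double r_lower, double r_upper) {
  const int n = y.size();
  const int p = X.ncol();          // local fixed effects (7 in the full model)
  const int J = rec_land.size();

  std::vector<int> yy(n);
  std::vector<double> lgyfact(n);
  for (int i = 0; i < n; ++i) {
    yy[i] = y[i];
    lgyfact[i] = lgamma((double) y[i] + 1.0);
  }
  std::vector<int> uy(yy);
  std::sort(uy.begin(), uy.end());
  uy.erase(std::unique(uy.begin(), uy.end()), uy.end());
  std::vector<int> uidx(n);
  for (int i = 0; i < n; ++i)
    uidx[i] = (int) (std::lower_bound(uy.begin(), uy.end(), yy[i]) - uy.begin());

  std::vector< std::vector<int> > arr_rows(J);
  for (int i = 0; i < n; ++i) arr_rows[array_index[i] - 1].push_back(i);

  // state
  std::vector<double> beta(p + 1);           // beta[0..p-1] local, beta[p] = landscape slope
  for (int k = 0; k <= p; ++k) beta[k] = init[k];
  std::vector<double> eps(J);
  for (int j = 0; j < J; ++j) eps[j] = init[p + 1 + j];
  double sigma = init[p + 1 + J];
  double r     = init[p + 2 + J];

  std::vector<double> eta(n);
  for (int i = 0; i < n; ++i) {
    double e = eps[array_index[i] - 1];
    for (int k = 0; k < p; ++k) e += beta[k] * X(i, k);
    eta[i] = e;
  }
  double ll = nb_loglik_eta(yy, eta, r, lgyfact, uidx, uy);
  double lp_eps = 0.0;
  for (int j = 0; j < J; ++j) lp_eps += dnorm_log(eps[j], beta[p] * rec_land[j], sigma);

  const int npar = p + 1 + J + 2;
  std::vector<AdaptStep> steps;
  for (int k = 0; k < p + 1; ++k) steps.push_back(AdaptStep(0.1));
  for (int j = 0; j < J; ++j)     steps.push_back(AdaptStep(0.2));
  steps.push_back(AdaptStep(0.1));   // sigma
  steps.push_back(AdaptStep(0.3));   // r

  const int n_keep = (n_iter > burn_in) ? (n_iter - burn_in + thin - 1) / thin : 0;
  NumericMatrix out(n_keep, npar);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // local fixed effects
    for (int k = 0; k < p; ++k) {
      AdaptStep& st = steps[k];
      const double cur = beta[k];
      const double prop = cur + st.step * R::norm_rand();
      bool acc = false;
      if (std::fabs(prop) <= beta_bound) {
        const double d = prop - cur;
        std::vector<double> eta_new(eta);
        for (int i = 0; i < n; ++i) eta_new[i] += d * X(i, k);
        const double ll_new = nb_loglik_eta(yy, eta_new, r, lgyfact, uidx, uy);
        if (std::log(R::unif_rand()) < ll_new - ll) {
          beta[k] = prop; eta.swap(eta_new); ll = ll_new; acc = true;
        }
      }
      st.tally(acc);
      if (it <= burn_in) st.maybe_adapt();
    }

    // array random effects
    for (int j = 0; j < J; ++j) {
      AdaptStep& st = steps[p + 1 + j];
      const double cur = eps[j];
      const double prop = cur + st.step * R::norm_rand();
      const double m_j = beta[p] * rec_land[j];
      const double ll_cur_j = nb_loglik_subset(yy, eta, r, lgyfact, uidx, uy, arr_rows[j]);
      std::vector<double> eta_new(eta);
      const double d = prop - cur;
      for (size_t s = 0; s < arr_rows[j].size(); ++s) eta_new[arr_rows[j][s]] += d;
      const double ll_new_j = nb_loglik_subset(yy, eta_new, r, lgyfact, uidx, uy, arr_rows[j]);
      const double lr = (ll_new_j + dnorm_log(prop, m_j, sigma))
                      - (ll_cur_j + dnorm_log(cur, m_j, sigma));
      bool acc = false;
      if (std::log(R::unif_rand()) < lr) {
        eps[j] = prop;
        eta.swap(eta_new);
        ll += ll_new_j - ll_cur_j;
        lp_eps += dnorm_log(prop, m_j, sigma) - dnorm_log(cur, m_j, sigma);
        acc = true;
      }
      st.tally(acc);
      if (it <= burn_in) st.maybe_adapt();
    }

    // landscape slope (enters only through the eps prior mean)
    {
      AdaptStep& st = steps[p];
      const double cur = beta[p];
      const double prop = cur + st.step * R::norm_rand();
      bool acc = false;
      if (std::fabs(prop) <= beta_bound) {
        double lp_new = 0.0;
        for (int j = 0; j < J; ++j) lp_new += dnorm_log(eps[j], prop * rec_land[j], sigma);
        if (std::log(R::unif_rand()) < lp_new - lp_eps) {
          beta[p] = prop; lp_eps = lp_new; acc = true;
        }
      }
      st.tally(acc);
      if (it <= burn_in) st.maybe_adapt();
    }

    // array-effect SD
    {
      AdaptStep& st = steps[npar - 2];
      const double cur = sigma;
      const double prop = cur + st.step * R::norm_rand();
      bool acc = false;
      if (prop > 0.0 && prop < sigma_upper) {
        double lp_new = 0.0;
        for (int j = 0; j < J; ++j) lp_new += dnorm_log(eps[j], beta[p] * rec_land[j], prop);
        if (std::log(R::unif_rand()) < lp_new - lp_eps) {
          sigma = prop; lp_eps = lp_new; acc = true;
        }
      }
      st.tally(acc);
      if (it <= burn_in) st.maybe_adapt();
    }

    // NB size parameter
    {
      AdaptStep& st = steps[npar - 1];
      const double cur = r;
      const double prop = cur + st.step * R::norm_rand();
      bool acc = false;
      if (prop > r_lower && prop < r_upper) {
        const double ll_new = nb_loglik_eta(yy, eta, prop, lgyfact, uidx, uy);
        if (std::log(R::unif_rand()) < ll_new - ll) {
          r = prop; ll = ll_new; acc = true;
        }
      }
      st.tally(acc);
      if (it <= burn_in) st.maybe_adapt();
    }

    if (it > burn_in && ((it - burn_in - 1) % thin) == 0) {
      for (int k = 0; k <= p; ++k) out(kept, k) = beta[k];
      for (int j = 0; j < J; ++j) out(kept, p + 1 + j) = eps[j];
      out(kept, npar - 2) = sigma;
      out(kept, npar - 1) = r;
      ++kept;
    }
  }

  return List::create(_["draws"] = out, _["loglik"] = ll);
}

// Adaptive Metropolis-within-Gibbs for the Gaussian LMM on overlap
// coefficients:
//   y_i ~ Normal(eta_i, sigma_resid^2), eta_i = sum_k beta_k X_ik + eps_{array(i)}
//   eps_j ~ Normal(0, sigma_array^2)
// Priors: beta ~ U(-beta_bound, beta_bound); both SDs ~ U(0, sigma_upper).
// init packs c(beta[1..p], eps[1..J], sigma_array, sigma_resid).
// [[Rcpp::export]]
List mwg_lmm_sampler(NumericVector yresp, NumericMatrix X, IntegerVector array_index,
                     int n_iter, int burn_in, int thin, NumericVector init,
                     double beta_bound, double sigma_upper) {
  const int n = yresp.size();
  const int p = X.ncol();
  int J = 0;
  for (int i = 0; i < n; ++i) if (array_index[i] > J) J = array_index[i];

  std::vector< std::vector<int> > arr_rows(J);
  for (int i = 0; i < n; ++i) arr_rows[array_index[i] - 1].push_back(i);

  std::vector<double> beta(p);
  for (int k = 0; k < p; ++k) beta[k] = init[k];
  std::vector<double> eps(J);
  for (int j = 0; j < J; ++j) eps[j] = init[p + j];
  double sig_a = init[p + J];
  double sig_e = init[p + J + 1];

  std::vector<double> eta(n);
  for (int i = 0; i < n; ++i) {
    double e = eps[array_index[i] - 1];
    for (int k = 0; k < p; ++k) e += beta[k] * X(i, k);
    eta[i] = e;
  }
  double ss = 0.0;
  for (int i = 0; i < n; ++i) { const double d = yresp[i] - eta[i]; ss += d * d; }
  const double LN2PI_HALF = 0.91893853320467274178;
  double ll = -n * (LN2PI_HALF + std::log(sig_e)) - ss / (2.0 * sig_e * sig_e);
  double lp_eps = 0.0;
  for (int j = 0; j < J; ++j) lp_eps += dnorm_log(eps[j], 0.0, sig_a);

  const int npar = p + J + 2;
  std::vector<AdaptStep> steps;
  for (int k = 0; k < p; ++k) steps.push_back(AdaptStep(0.05));
  for (int j = 0; j < J; ++j) steps.push_back(AdaptStep(0.05));
  steps.push_back(AdaptStep(0.05));
  steps.push_back(AdaptStep(0.05));

  const int n_keep = (n_iter > burn_in) ? (n_iter - burn_in + thin - 1) / thin : 0;
  NumericMatrix out(n_keep, npar);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    for (int k = 0; k < p; ++k) {
      AdaptStep& st = steps[k];
      const double cur = beta[k];
      const double prop = cur + st.step * R::norm_rand();
      bool acc = false;
      if (std::fabs(prop) <= beta_bound) {
        const double d = prop - cur;
        double ss_new = 0.0;
        std::vector<double> eta_new(eta);
        for (int i = 0; i < n; ++i) {
          eta_new[i] += d * X(i, k);
          const double rr = yresp[i] - eta_new[i];
          ss_new += rr * rr;
        }
        const double ll_new = -n * (LN2PI_HALF + std::log(sig_e)) - ss_new / (2.0 * sig_e * sig_e);
        if (std::log(R::unif_rand()) < ll_new - ll) {
          beta[k] = prop; eta.swap(eta_new); ss = ss_new; ll = ll_new; acc = true;
        }
      }
      st.tally(acc);
      if (it <= burn_in) st.maybe_adapt();
    }

    for (int j = 0; j < J; ++j) {
      AdaptStep& st = steps[p + j];
      const double cur = eps[j];
      const double prop = cur + st.step * R::norm_rand();
      const double d = prop - cur;
      double ss_delta = 0.0;
      for (size_t s = 0; s < arr_rows[j].size(); ++s) {
        const int i = arr_rows[j][s];
        const double r_old = yresp[i] - eta[i];
        const double r_new = r_old - d;
        ss_delta += r_new * r_new - r_old * r_old;
      }
      const double ll_new = -n * (LN2PI_HALF + std::log(sig_e)) - (ss + ss_delta) / (2.0 * sig_e * sig_e);
      const double lr = (ll_new + dnorm_log(prop, 0.0, sig_a))
                      - (ll + dnorm_log(cur, 0.0, sig_a));
      bool acc = false;
      if (std::log(R::unif_rand()) < lr) {
        eps[j] = prop;
        for (size_t s = 0; s < arr_rows[j].size(); ++s) eta[arr_rows[j][s]] += d;
        ss += ss_delta;
        lp_eps += dnorm_log(prop, 0.0, sig_a) - dnorm_log(cur, 0.0, sig_a);
        ll = ll_new;
        acc = true;
      }
      st.tally(acc);
      if (it <= burn_in) st.maybe_adapt();
    }

    {
      AdaptStep& st = steps[npar - 2];
      const double cur = sig_a;
      const double prop = cur + st.step * R::norm_rand();
      bool acc = false;
      if (prop > 0.0 && prop < sigma_upper) {
        double lp_new = 0.0;
        for (int j = 0; j < J; ++j) lp_new += dnorm_log(eps[j], 0.0, prop);
        if (std::log(R::unif_rand()) < lp_new - lp_eps) {
          sig_a = prop; lp_eps = lp_new; acc = true;
        }
      }
      st.tally(acc);
      if (it <= burn_in) st.maybe_adapt();
    }

    {
      AdaptStep& st = steps[npar - 1];
      const double cur = sig_e;
      const double prop = cur + st.step * R::norm_rand();
      bool acc = false;
      if (prop > 0.0 && prop < sigma_upper) {
        const double ll_new = -n * (LN2PI_HALF + std::log(prop)) - ss / (2.0 * prop * prop);
        if (std::log(R::unif_rand()) < ll_new - ll) {
          sig_e = prop; ll = ll_new; acc = true;
        }
      }
      st.tally(acc);
      if (it <= burn_in) st.maybe_adapt();
    }

    if (it > burn_in && ((it - burn_in - 1) % thin) == 0) {
      for (int k = 0; k < p; ++k) out(kept, k) = beta[k];
      for (int j = 0; j < J; ++j) out(kept, p + j) = eps[j];
      out(kept, npar - 2) = sig_a;
      out(kept, npar - 1) = sig_e;
      ++kept;
    }
  }

  return List::create(_["draws"] = out, _["loglik"] = ll);
}
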
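#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }
static inline double logitf(double p) { return std::log(p / (1.0 - p)); }

// Forward recursion over the latent alive/dead chain for one encounter row,
// conditional on first capture. `phi_t[t]` is survival over the interval
// (t, t+1), 0-based; `p` is the occasion-constant detection probability.
static double forward_one(const int* y, int first, int T,
                          const double* phi_t, double p) {
  double a = 1.0, d = 0.0; // P(alive, obs so far), P(dead, obs so far)
  for (int t = first + 1; t < T; ++t) {
    double phi = phi_t[t - 1];
    double pa = a * phi;
    double pd = a * (1.0 - phi) + d;
    if (y[t] == 1) { a = pa * p; d = 0.0; }
    else           { a = pa * (1.0 - p); d = pd; }
  }
  return std::log(a + d);
}

// [[Rcpp::export]]
double cjs_forward_cpp(IntegerVector y, int first, NumericVector phi, double p) {
  int T = y.size();
  std::vector<int> yy(T);
  for (int t = 0; t < T; ++t) {
    if (y[t] != 0 && y[t] != 1) stop("encounter history must be binary");
    yy[t] = y[t];
  }
  if (first < 1 || first > T) stop("first out of range");
  for (int t = 0; t < first - 1; ++t)
    if (yy[t] == 1) stop("detection before first capture");
  if (yy[first - 1] != 1) stop("history must be 1 at the first-capture occasion");
  if ((int)phi.size() != T - 1) stop("phi must have length T - 1");
  return forward_one(yy.data(), first - 1, T, REAL(phi), p);
}

// Per-individual likelihood with survival taken from a cell-value vector via
// an index matrix, and an optional logit-additive covariate on survival.
static double forward_cells(const IntegerMatrix& y, int i, int first0,
                            const IntegerMatrix& phi_idx,
                            const std::vector<double>& phiv,
                            double beta, const NumericMatrix& phi_cov,
                            bool use_cov, double p) {
  int T = y.ncol();
  double a = 1.0, d = 0.0;
  for (int t = first0 + 1; t < T; ++t) {
    double phi = phiv[phi_idx(i, t - 1)];
    if (use_cov) {
      double x = phi_cov(i, t - 1);
      if (x != 0.0) phi = invlogit(logitf(phi) + beta * x);
    }
    double pa = a * phi;
    double pd = a * (1.0 - phi) + d;
    if (y(i, t) == 1) { a = pa * p; d = 0.0; }
    else              { a = pa * (1.0 - p); d = pd; }
  }
  double tot = a + d;
  return tot > 0.0 ? std::log(tot) : R_NegInf;
}

// [[Rcpp::export]]
NumericVector cjs_loglik_gh_cpp(IntegerMatrix y, IntegerVector first,
                                IntegerMatrix phi_idx, NumericVector phiv,
                                double mu, double sigma,
                                NumericVector gh_x, NumericVector gh_w) {
  int n = y.nrow(), K = gh_x.size();
  std::vector<double> pv(phiv.begin(), phiv.end());
  NumericMatrix dummy(1, 1);
  NumericVector out(n);
  double lsp = 0.5 * std::log(M_PI);
  for (int i = 0; i < n; ++i) {
    int f0 = first[i] - 1;
    double m = R_NegInf;
    std::vector<double> terms(K);
    for (int k = 0; k < K; ++k) {
      double p = invlogit(mu + M_SQRT2 * sigma * gh_x[k]);
      double ll = forward_cells(y, i, f0, phi_idx, pv, 0.0, dummy, false, p);
      terms[k] = std::log(gh_w[k]) - lsp + ll;
      if (terms[k] > m) m = terms[k];
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(terms[k] - m);
    out[i] = m + std::log(s);
  }
  return out;
}

struct StepSizes {
  std::vector<double> phi_step, mu_step;
  double sig_step, eps_step, beta_step;
};

// Metropolis-within-Gibbs sampler for the CJS model.
//
// Survival: phiv[k] ~ Uniform(0,1), one cell per (age class x sex) level,
//   addressed per individual/interval through phi_idx; optional logit-scale
//   covariate coefficient beta ~ Normal(0, beta_prior_sd^2) (collaring check).
// Detection: p_i = invlogit(mu[p_grp_i] + eps_i). Priors: invlogit(mu) ~
//   Uniform(0,1); with use_re, eps_i ~ Normal(0, sigma^2), sigma ~
//   Uniform(0, sigma_max); without, eps = 0.
// [[Rcpp::export]]
List cjs_mcmc_cpp(IntegerMatrix y, IntegerVector first, IntegerMatrix phi_idx,
                  int n_phi, IntegerVector p_grp, int n_p, bool use_re,
                  NumericMatrix phi_cov, bool use_cov,
                  int n_iter, int n_burn,
                  NumericVector phi_init, NumericVector mu_init,
                  double sigma_init, double sigma_max, double beta_prior_sd) {
  int n = y.nrow(), T = y.ncol();
  std::vector<double> phiv(phi_init.begin(), phi_init.end());
  std::vector<double> mu(mu_init.begin(), mu_init.end());
  double sigma = use_re ? sigma_init : 0.0;
  double beta = 0.0;
  std::vector<double> eps(n, 0.0), p_i(n), ll(n);

  // membership lists: which individuals' likelihoods touch each phi cell
  std::vector<std::vector<int>> cell_members(n_phi);
  std::vector<std::vector<bool>> seen(n_phi, std::vector<bool>(n, false));
  std::vector<int> cov_members;
  for (int i = 0; i < n; ++i) {
    int f0 = first[i] - 1;
    bool touches_cov = false;
    for (int t = f0 + 1; t < T; ++t) {
      int k = phi_idx(i, t - 1);
      if (!seen[k][i]) { seen[k][i] = true; cell_members[k].push_back(i); }
      if (use_cov && phi_cov(i, t - 1) != 0.0) touches_cov = true;
    }
    if (touches_cov) cov_members.push_back(i);
  }

  if (use_re) for (int i = 0; i < n; ++i) eps[i] = R::rnorm(0.0, sigma);
  for (int i = 0; i < n; ++i) p_i[i] = invlogit(mu[p_grp[i]] + eps[i]);
  NumericMatrix covm = use_cov ? phi_cov : NumericMatrix(1, 1);
  for (int i = 0; i < n; ++i)
    ll[i] = forward_cells(y, i, first[i] - 1, phi_idx, phiv, beta, covm, use_cov, p_i[i]);

  StepSizes st;
  st.phi_step.assign(n_phi, 0.3);
  st.mu_step.assign(n_p, 0.2);
  st.sig_step = 0.3; st.eps_step = 0.8; st.beta_step = 0.3;
  std::vector<int> phi_acc(n_phi, 0), mu_acc(n_p, 0);
  int sig_acc = 0, beta_acc = 0, eps_acc = 0, eps_try = 0;
  int batch = 50;

  int total = n_burn + n_iter;
  NumericMatrix phi_draws(n_iter, n_phi), mu_draws(n_iter, n_p);
  NumericVector sigma_draws(n_iter), beta_draws(n_iter),
      pmean_draws(n_iter), dev_draws(n_iter);
  std::vector<double> eps_sum(n, 0.0);

  for (int it = 0; it < total; ++it) {
    // survival cells
    for (int k = 0; k < n_phi; ++k) {
      if (cell_members[k].empty()) { phiv[k] = R::runif(0.0, 1.0); continue; }
      double cur = phiv[k];
      double prop = invlogit(logitf(cur) + st.phi_step[k] * R::rnorm(0.0, 1.0));
      double lr = std::log(prop * (1.0 - prop)) - std::log(cur * (1.0 - cur));
      phiv[k] = prop;
      std::vector<double> newll(cell_members[k].size());
      for (size_t j = 0; j < cell_members[k].size(); ++j) {
        int i = cell_members[k][j];
        newll[j] = forward_cells(y, i, first[i] - 1, phi_idx, phiv, beta, covm,
                                 use_cov, p_i[i]);
        lr += newll[j] - ll[i];
      }
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        for (size_t j = 0; j < cell_members[k].size(); ++j)
          ll[cell_members[k][j]] = newll[j];
        phi_acc[k]++;
      } else phiv[k] = cur;
    }

    // collaring-type coefficient
    if (use_cov) {
      double cur = beta;
      double prop = cur + st.beta_step * R::rnorm(0.0, 1.0);
      double lr = R::dnorm(prop, 0.0, beta_prior_sd, 1) -
                  R::dnorm(cur, 0.0, beta_prior_sd, 1);
      beta = prop;
      std::vector<double> newll(cov_members.size());
      for (size_t j = 0; j < cov_members.size(); ++j) {
        int i = cov_members[j];
        newll[j] = forward_cells(y, i, first[i] - 1, phi_idx, phiv, beta, covm,
                                 true, p_i[i]);
        lr += newll[j] - ll[i];
      }
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        for (size_t j = 0; j < cov_members.size(); ++j) ll[cov_members[j]] = newll[j];
        beta_acc++;
      } else beta = cur;
    }

    // detection means (logistic prior = uniform on the probability scale)
    for (int g = 0; g < n_p; ++g) {
      double cur = mu[g];
      double prop = cur + st.mu_step[g] * R::rnorm(0.0, 1.0);
      double lr = (std::log(invlogit(prop)) + std::log(1.0 - invlogit(prop))) -
                  (std::log(invlogit(cur)) + std::log(1.0 - invlogit(cur)));
      std::vector<double> newll(n), newp(n);
      bool any = false;
      for (int i = 0; i < n; ++i) {
        if (p_grp[i] != g) continue;
        any = true;
        newp[i] = invlogit(prop + eps[i]);
        newll[i] = forward_cells(y, i, first[i] - 1, phi_idx, phiv, beta, covm,
                                 use_cov, newp[i]);
        lr += newll[i] - ll[i];
      }
      if (!any) { mu[g] = R::rlogis(0.0, 1.0); continue; } // prior refresh
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        for (int i = 0; i < n; ++i)
          if (p_grp[i] == g) { ll[i] = newll[i]; p_i[i] = newp[i]; }
        mu[g] = prop; mu_acc[g]++;
      } else mu[g] = cur;
    }

    if (use_re) {
      // individual detection deviations
      for (int i = 0; i < n; ++i) {
        eps_try++;
        double cur = eps[i];
        double prop = cur + st.eps_step * R::rnorm(0.0, 1.0);
        double newp = invlogit(mu[p_grp[i]] + prop);
        double nll = forward_cells(y, i, first[i] - 1, phi_idx, phiv, beta, covm,
                                   use_cov, newp);
        double lr = nll - ll[i] +
                    R::dnorm(prop, 0.0, sigma, 1) - R::dnorm(cur, 0.0, sigma, 1);
        if (std::log(R::runif(0.0, 1.0)) < lr) {
          eps[i] = prop; p_i[i] = newp; ll[i] = nll; eps_acc++;
        }
      }
      // heterogeneity sd (likelihood does not involve sigma given eps)
      {
        double cur = sigma;
        double prop = cur * std::exp(st.sig_step * R::rnorm(0.0, 1.0));
        if (prop < sigma_max) {
          double lr = std::log(prop / cur); // log-scale proposal Jacobian
          for (int i = 0; i < n; ++i)
            lr += R::dnorm(eps[i], 0.0, prop, 1) - R::dnorm(eps[i], 0.0, cur, 1);
          if (std::log(R::runif(0.0, 1.0)) < lr) { sigma = prop; sig_acc++; }
        }
      }
    }

    // step-size adaptation (burn-in only, diminishing)
    if (it < n_burn && (it + 1) % batch == 0) {
      double delta = std::min(0.1, 1.0 / std::sqrt((double)(it + 1) / batch));
      for (int k = 0; k < n_phi; ++k) {
        double r = (double)phi_acc[k] / batch;
        st.phi_step[k] *= std::exp(r > 0.44 ? delta : -delta);
        phi_acc[k] = 0;
      }
      for (int g = 0; g < n_p; ++g) {
        double r = (double)mu_acc[g] / batch;
        st.mu_step[g] *= std::exp(r > 0.44 ? delta : -delta);
        mu_acc[g] = 0;
      }
      if (use_re) {
        double r = (double)sig_acc / batch;
        st.sig_step *= std::exp(r > 0.44 ? delta : -delta);
        sig_acc = 0;
        double re = eps_try ? (double)eps_acc / eps_try : 0.0;
        st.eps_step *= std::exp(re > 0.44 ? delta : -delta);
        eps_acc = 0; eps_try = 0;
      }
      if (use_cov) {
        double r = (double)beta_acc / batch;
        st.beta_step *= std::exp(r > 0.44 ? delta : -delta);
        beta_acc = 0;
      }
    }

    if (it >= n_burn) {
      int s = it - n_burn;
      for (int k = 0; k < n_phi; ++k) phi_draws(s, k) = phiv[k];
      for (int g = 0; g < n_p; ++g) mu_draws(s, g) = mu[g];
      sigma_draws[s] = sigma;
      beta_draws[s] = beta;
      double pm = 0.0, dev = 0.0;
      for (int i = 0; i < n; ++i) { pm += p_i[i]; dev += ll[i]; eps_sum[i] += eps[i]; }
      pmean_draws[s] = pm / n;
      dev_draws[s] = -2.0 * dev;
    }
  }

  NumericVector eps_mean(n);
  for (int i = 0; i < n; ++i) eps_mean[i] = eps_sum[i] / n_iter;
  return List::create(_["phi"] = phi_draws, _["mu_p"] = mu_draws,
                      _["sigma_p"] = sigma_draws, _["beta"] = beta_draws,
                      _["p_mean"] = pmean_draws, _["deviance"] = dev_draws,
                      _["eps_mean"] = eps_mean);
}
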
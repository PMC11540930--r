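#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Numerically stable log(1 + exp(x)).
static inline double log_one_plus_exp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Bernoulli-logistic log-likelihood for the full dataset given the linear
// predictor. y must be 0/1.
static double bern_loglik(const std::vector<double> &eta,
                          const NumericVector &y) {
  double ll = 0.0;
  int n = eta.size();
  for (int i = 0; i < n; ++i)
    ll += y[i] * eta[i] - log_one_plus_exp(eta[i]);
  return ll;
}

struct AdaptScale {
  double ls;        // log proposal scale
  int acc, att;     // window counters
  long acc_all, att_all; // post burn-in counters
  AdaptScale(double s) : ls(std::log(s)), acc(0), att(0),
                         acc_all(0), att_all(0) {}
  double scale() const { return std::exp(ls); }
  void count(bool accepted, bool record) {
    ++att;
    if (accepted) ++acc;
    if (record) { ++att_all; if (accepted) ++acc_all; }
  }
  void adapt(double target, double step) {
    if (att == 0) return;
    double rate = (double)acc / (double)att;
    ls += (rate > target ? step : -step);
    if (ls > 8.0) ls = 8.0;
    if (ls < -8.0) ls = -8.0;
    acc = 0; att = 0;
  }
  double rate_all() const {
    return att_all > 0 ? (double)acc_all / (double)att_all : NA_REAL;
  }
};

// Metropolis-within-Gibbs sampler for the logistic / spatial logistic /
// random-parameters spatial logistic model ladder.
//
// family: 0 = logistic, 1 = spatial logistic, 2 = random-parameters spatial.
// sec: 0-based section index per crash (ignored for family 0).
// sec_obs: per-section integer vectors of 0-based crash indices.
// nbrs: per-section integer vectors of 0-based neighbor section indices.
// eig: eigenvalues of D - W (for the Leroux joint determinant in the rho
//      and delta updates).
// random_idx: 0-based columns of X given crash-level random coefficients.
// fix_rho / fix_delta: NA to sample, otherwise held fixed at the value.
// [[Rcpp::export]]
List run_sampler(NumericVector y, NumericMatrix X, IntegerVector sec,
                 List sec_obs, List nbrs, NumericVector dcount,
                 NumericVector eig,
                 int family, IntegerVector random_idx,
                 double beta_var, double scale_lo, double scale_hi,
                 int n_iter, int n_burnin, int thin,
                 int adapt_interval, double target_accept,
                 bool prior_only, List init,
                 double fix_rho, double fix_delta,
                 int phi_keep_max, bool verbose) {
  const int N = X.nrow(), J = X.ncol();
  const int M = (family >= 1) ? dcount.size() : 0;
  const int K = (family == 2) ? random_idx.size() : 0;
  const bool spatial = family >= 1;
  const bool rho_free = ISNA(fix_rho);
  const bool delta_free = ISNA(fix_delta);

  // --- state ---------------------------------------------------------------
  std::vector<double> beta(J, 0.0);
  {
    NumericVector b0 = init["beta"];
    for (int j = 0; j < J; ++j) beta[j] = b0[j];
  }
  std::vector<double> phi(M, 0.0);
  if (spatial) {
    NumericVector p0 = init["phi"];
    for (int m = 0; m < M; ++m) phi[m] = p0[m];
  }
  double rho = spatial ? (rho_free ? as<double>(init["rho"]) : fix_rho) : 0.0;
  double delta = spatial ? (delta_free ? as<double>(init["delta"]) : fix_delta) : 1.0;
  std::vector<double> sigma(K, 1.0);
  if (K > 0) {
    NumericVector s0 = init["sigma"];
    for (int k = 0; k < K; ++k) sigma[k] = s0[k];
  }
  std::vector< std::vector<double> > mu(K, std::vector<double>(N, 0.0));
  std::vector<double> mu_ss(K, 0.0); // sum of squares per random covariate

  // nonzero row indices per column of X (skips null likelihood terms)
  std::vector< std::vector<int> > xnz(J);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < N; ++i)
      if (X(i, j) != 0.0) xnz[j].push_back(i);

  // per-section crash lists and neighbor lists as plain vectors
  std::vector< std::vector<int> > sobs(M), nbr(M);
  for (int m = 0; m < M; ++m) {
    IntegerVector a = sec_obs[m]; sobs[m].assign(a.begin(), a.end());
    IntegerVector b = nbrs[m];    nbr[m].assign(b.begin(), b.end());
  }

  // linear predictor cache
  std::vector<double> eta(N, 0.0);
  auto recompute_eta = [&]() {
    for (int i = 0; i < N; ++i) {
      double e = 0.0;
      for (int j = 0; j < J; ++j) e += beta[j] * X(i, j);
      for (int k = 0; k < K; ++k) e += mu[k][i] * X(i, random_idx[k]);
      if (spatial) e += phi[sec[i]];
      eta[i] = e;
    }
  };
  recompute_eta();
  if (!prior_only) {
    double ll0 = bern_loglik(eta, y);
    if (!std::isfinite(ll0))
      stop("non-finite log-likelihood at initialization");
  }

  // --- proposal scales -----------------------------------------------------
  std::vector<AdaptScale> s_beta(J, AdaptScale(0.1));
  std::vector<AdaptScale> s_mu(K, AdaptScale(1.0));
  std::vector<AdaptScale> s_sig(K, AdaptScale(0.3));
  std::vector<AdaptScale> s_res(K, AdaptScale(0.3));
  AdaptScale s_phi(0.5), s_rho(0.7), s_del(0.3), s_dres(0.3);

  // --- storage -------------------------------------------------------------
  int n_kept = 0;
  for (int it = n_burnin; it < n_iter; ++it)
    if ((it - n_burnin) % thin == 0) ++n_kept;
  int npar = J + K + (spatial ? 2 : 0);
  NumericMatrix draws(n_kept, npar);
  NumericVector dev_draws(n_kept);
  int phi_thin = 1, phi_rows = 0;
  if (spatial && n_kept > 0) {
    phi_thin = std::max(1, n_kept / std::max(1, phi_keep_max));
    phi_rows = (n_kept + phi_thin - 1) / phi_thin;
  }
  NumericMatrix phi_draws(spatial ? phi_rows : 0, spatial ? M : 0);
  std::vector<double> eta_mean(N, 0.0), phi_mean(M, 0.0), phi_m2(M, 0.0);
  NumericMatrix mu_mean(K > 0 ? N : 0, K);

  const double log_lo = std::log(scale_lo), log_hi = std::log(scale_hi);

  // Leroux joint terms S0 = phi'phi, S1 = phi'(D-W)phi (pairwise differences)
  auto leroux_quads = [&](double &S0, double &S1) {
    S0 = 0.0; S1 = 0.0;
    for (int m = 0; m < M; ++m) {
      S0 += phi[m] * phi[m];
      for (size_t u = 0; u < nbr[m].size(); ++u) {
        int n2 = nbr[m][u];
        if (n2 > m) { double d = phi[m] - phi[n2]; S1 += d * d; }
      }
    }
  };
  auto leroux_logdet_core = [&](double r) {
    // log det(r (D - W) + (1 - r) I), delta factored out
    double s = 0.0;
    for (int m = 0; m < M; ++m) s += std::log(r * eig[m] + 1.0 - r);
    return s;
  };

  int kept = 0, phi_row = 0;
  for (int it = 0; it < n_iter; ++it) {
    const bool record = it >= n_burnin;
    const bool adapting = it < n_burnin;

    // ---- fixed coefficients / random-coefficient means --------------------
    for (int j = 0; j < J; ++j) {
      double cur = beta[j];
      double prop = cur + s_beta[j].scale() * norm_rand();
      double d = prop - cur, dll = 0.0;
      if (!prior_only) {
        const std::vector<int> &rows = xnz[j];
        for (size_t u = 0; u < rows.size(); ++u) {
          int i = rows[u];
          double de = d * X(i, j);
          dll += y[i] * de - log_one_plus_exp(eta[i] + de) + log_one_plus_exp(eta[i]);
        }
      }
      double dlp = (cur * cur - prop * prop) / (2.0 * beta_var);
      bool acc = std::log(unif_rand()) < dll + dlp;
      if (acc) {
        const std::vector<int> &rows = xnz[j];
        for (size_t u = 0; u < rows.size(); ++u)
          eta[rows[u]] += d * X(rows[u], j);
        beta[j] = prop;
      }
      s_beta[j].count(acc, record);
    }

    // ---- crash-level random deviations and their scales --------------------
    for (int k = 0; k < K; ++k) {
      int col = random_idx[k];
      double sg = sigma[k], sg2 = sg * sg;
      // deviations
      for (int i = 0; i < N; ++i) {
        double x = X(i, col);
        if (x == 0.0 || prior_only) {
          // prior-only full conditional: Gibbs draw
          double old = mu[k][i];
          double nw = sg * norm_rand();
          mu_ss[k] += nw * nw - old * old;
          if (x != 0.0) eta[i] += (nw - old) * x;
          mu[k][i] = nw;
          continue;
        }
        double cur = mu[k][i];
        // alternate a random walk with an independence proposal from the
        // mixing prior (whose acceptance is the bare likelihood ratio);
        // the latter keeps the deviations' feedback on sigma sharp even
        // where the likelihood is nearly flat
        bool indep = unif_rand() < 0.5;
        double prop = indep ? sg * norm_rand()
                            : cur + s_mu[k].scale() * norm_rand();
        double de = (prop - cur) * x;
        double dll = y[i] * de - log_one_plus_exp(eta[i] + de) + log_one_plus_exp(eta[i]);
        double dlp = indep ? 0.0
                           : (cur * cur - prop * prop) / (2.0 * sg2);
        bool acc = std::log(unif_rand()) < dll + dlp;
        if (acc) {
          eta[i] += de;
          mu_ss[k] += prop * prop - cur * cur;
          mu[k][i] = prop;
        }
        if (!indep) s_mu[k].count(acc, record); // adapt on the RW kernel only
      }
      // scale: plain random-walk on log sigma (repeated; the scale chain is
      // the slow direction of the hierarchy)
      for (int rep = 0; rep < 3; ++rep) {
        double lcur = std::log(sigma[k]);
        double lprop = lcur + s_sig[k].scale() * norm_rand();
        bool acc = false;
        if (lprop >= log_lo && lprop <= log_hi) {
          double sp = std::exp(lprop);
          double dl = -(double)N * (lprop - lcur)
            - 0.5 * mu_ss[k] * (1.0 / (sp * sp) - 1.0 / (sigma[k] * sigma[k]))
            + (lprop - lcur); // Jacobian of the log transform
          acc = std::log(unif_rand()) < dl;
          if (acc) sigma[k] = sp;
        }
        s_sig[k].count(acc, record);
      }
      // scale: joint rescale move (sigma, mu) -> (sigma e^eps, mu e^eps);
      // the normal mixing density and the Jacobian cancel up to e^eps, so
      // the acceptance ratio is the likelihood ratio times e^eps.
      for (int rep = 0; rep < 3; ++rep) {
        double eps = s_res[k].scale() * norm_rand();
        double lprop = std::log(sigma[k]) + eps;
        bool acc = false;
        if (lprop >= log_lo && lprop <= log_hi) {
          double f = std::exp(eps);
          double dll = 0.0;
          if (!prior_only) {
            const std::vector<int> &rows = xnz[col];
            for (size_t u = 0; u < rows.size(); ++u) {
              int i = rows[u];
              double de = mu[k][i] * (f - 1.0) * X(i, col);
              dll += y[i] * de - log_one_plus_exp(eta[i] + de) + log_one_plus_exp(eta[i]);
            }
          }
          acc = std::log(unif_rand()) < dll + eps;
          if (acc) {
            const std::vector<int> &rows = xnz[col];
            for (size_t u = 0; u < rows.size(); ++u) {
              int i = rows[u];
              eta[i] += mu[k][i] * (f - 1.0) * X(i, col);
            }
            for (int i = 0; i < N; ++i) mu[k][i] *= f;
            mu_ss[k] *= f * f;
            sigma[k] = std::exp(lprop);
          }
        }
        s_res[k].count(acc, record);
      }
    }

    // ---- spatial effects and hyper-parameters ------------------------------
    if (spatial) {
      double d2 = delta * delta;
      for (int m = 0; m < M; ++m) {
        double cm = 1.0 - rho + rho * dcount[m];
        double nsum = 0.0;
        for (size_t u = 0; u < nbr[m].size(); ++u) nsum += phi[nbr[m][u]];
        double pm = rho * nsum / cm;      // conditional prior mean
        double pv = d2 / cm;              // conditional prior variance
        double cur = phi[m];
        double prop = cur + s_phi.scale() * norm_rand();
        double dll = 0.0;
        if (!prior_only) {
          double d = prop - cur;
          const std::vector<int> &rows = sobs[m];
          for (size_t u = 0; u < rows.size(); ++u) {
            int i = rows[u];
            dll += y[i] * d - log_one_plus_exp(eta[i] + d) + log_one_plus_exp(eta[i]);
          }
        }
        double dlp = ((cur - pm) * (cur - pm) - (prop - pm) * (prop - pm)) /
          (2.0 * pv);
        bool acc = std::log(unif_rand()) < dll + dlp;
        if (acc) {
          if (!prior_only) {
            double d = prop - cur;
            const std::vector<int> &rows = sobs[m];
            for (size_t u = 0; u < rows.size(); ++u) eta[rows[u]] += d;
          }
          phi[m] = prop;
        }
        s_phi.count(acc, record);
      }

      double S0, S1;
      leroux_quads(S0, S1);
      if (rho_free) {
        // random walk on logit(rho); U(0,1) prior
        double lcur = std::log(rho) - std::log1p(-rho);
        double lprop = lcur + s_rho.scale() * norm_rand();
        double rp = 1.0 / (1.0 + std::exp(-lprop));
        double lp_cur = 0.5 * leroux_logdet_core(rho)
          - (rho * S1 + (1.0 - rho) * S0) / (2.0 * d2)
          + std::log(rho) + std::log1p(-rho);
        double lp_prop = 0.5 * leroux_logdet_core(rp)
          - (rp * S1 + (1.0 - rp) * S0) / (2.0 * d2)
          + std::log(rp) + std::log1p(-rp);
        bool acc = std::log(unif_rand()) < lp_prop - lp_cur;
        if (acc) rho = rp;
        s_rho.count(acc, record);
      }
      if (delta_free) {
        for (int rep = 0; rep < 3; ++rep) {
          double lcur = std::log(delta);
          double lprop = lcur + s_del.scale() * norm_rand();
          bool acc = false;
          if (lprop >= log_lo && lprop <= log_hi) {
            double dp = std::exp(lprop);
            double q = rho * S1 + (1.0 - rho) * S0;
            double dl = -(double)M * (lprop - lcur)
              - 0.5 * q * (1.0 / (dp * dp) - 1.0 / (delta * delta))
              + (lprop - lcur);
            acc = std::log(unif_rand()) < dl;
            if (acc) delta = dp;
          }
          s_del.count(acc, record);
        }
        // joint rescale (delta, phi) -> (delta e^eps, phi e^eps): the CAR
        // prior density and the Jacobian cancel up to e^eps, leaving the
        // likelihood ratio -- the efficient scale kernel for the field
        for (int rep = 0; rep < 3; ++rep) {
          double eps = s_dres.scale() * norm_rand();
          double lprop = std::log(delta) + eps;
          bool acc = false;
          if (lprop >= log_lo && lprop <= log_hi) {
            double f = std::exp(eps);
            double dll = 0.0;
            if (!prior_only) {
              for (int i = 0; i < N; ++i) {
                double de = phi[sec[i]] * (f - 1.0);
                dll += y[i] * de - log_one_plus_exp(eta[i] + de)
                  + log_one_plus_exp(eta[i]);
              }
            }
            acc = std::log(unif_rand()) < dll + eps;
            if (acc) {
              if (!prior_only)
                for (int i = 0; i < N; ++i)
                  eta[i] += phi[sec[i]] * (f - 1.0);
              for (int m = 0; m < M; ++m) phi[m] *= f;
              S0 *= f * f; S1 *= f * f;
              delta = std::exp(lprop);
            }
          }
          s_dres.count(acc, record);
        }
      }
    }

    // ---- adaptation (burn-in only) -----------------------------------------
    if (adapting && (it + 1) % adapt_interval == 0) {
      double step = std::min(0.1, 5.0 / std::sqrt((double)(it + 1)));
      for (int j = 0; j < J; ++j) s_beta[j].adapt(target_accept, step);
      for (int k = 0; k < K; ++k) {
        s_mu[k].adapt(target_accept, step);
        s_sig[k].adapt(target_accept, step);
        s_res[k].adapt(target_accept, step);
      }
      if (spatial) {
        s_phi.adapt(target_accept, step);
        if (rho_free) s_rho.adapt(target_accept, step);
        if (delta_free) { s_del.adapt(target_accept, step);
                          s_dres.adapt(target_accept, step); }
      }
    }

    // periodic refresh against incremental drift
    if ((it + 1) % 2000 == 0) recompute_eta();

    // ---- record ------------------------------------------------------------
    if (record && (it - n_burnin) % thin == 0) {
      int c = 0;
      for (int j = 0; j < J; ++j) draws(kept, c++) = beta[j];
      for (int k = 0; k < K; ++k) draws(kept, c++) = sigma[k];
      if (spatial) { draws(kept, c++) = rho; draws(kept, c++) = delta; }
      dev_draws[kept] = -2.0 * bern_loglik(eta, y);
      double w = 1.0 / (double)(kept + 1);
      for (int i = 0; i < N; ++i) eta_mean[i] += (eta[i] - eta_mean[i]) * w;
      for (int m = 0; m < M; ++m) {
        double dlt = phi[m] - phi_mean[m];
        phi_mean[m] += dlt * w;
        phi_m2[m] += dlt * (phi[m] - phi_mean[m]);
      }
      for (int k = 0; k < K; ++k)
        for (int i = 0; i < N; ++i)
          mu_mean(i, k) += (mu[k][i] - mu_mean(i, k)) * w;
      if (spatial && kept % phi_thin == 0 && phi_row < phi_draws.nrow()) {
        for (int m = 0; m < M; ++m) phi_draws(phi_row, m) = phi[m];
        ++phi_row;
      }
      ++kept;
    }

    if (verbose && (it + 1) % 10000 == 0)
      Rcpp::Rcout << "iteration " << (it + 1) << " / " << n_iter << "\n";
    if ((it + 1) % 5000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector phi_sd(M);
  for (int m = 0; m < M; ++m)
    phi_sd[m] = kept > 1 ? std::sqrt(phi_m2[m] / (kept - 1)) : NA_REAL;

  NumericVector acc_beta(J), acc_mu(K), acc_sig(K), acc_res(K);
  NumericVector sc_beta(J);
  for (int j = 0; j < J; ++j) {
    acc_beta[j] = s_beta[j].rate_all();
    sc_beta[j] = s_beta[j].scale();
  }
  for (int k = 0; k < K; ++k) {
    acc_mu[k] = s_mu[k].rate_all();
    acc_sig[k] = s_sig[k].rate_all();
    acc_res[k] = s_res[k].rate_all();
  }

  return List::create(
    _["draws"] = draws,
    _["deviance"] = dev_draws,
    _["eta_mean"] = NumericVector(eta_mean.begin(), eta_mean.end()),
    _["phi_mean"] = NumericVector(phi_mean.begin(), phi_mean.end()),
    _["phi_sd"] = phi_sd,
    _["phi_draws"] = phi_draws,
    _["mu_mean"] = mu_mean,
    _["accept"] = List::create(
      _["beta"] = acc_beta, _["mu"] = acc_mu, _["sigma"] = acc_sig,
      _["sigma_rescale"] = acc_res,
      _["phi"] = spatial ? s_phi.rate_all() : NA_REAL,
      _["rho"] = (spatial && rho_free) ? s_rho.rate_all() : NA_REAL,
      _["delta"] = (spatial && delta_free) ? s_del.rate_all() : NA_REAL),
    _["scales"] = List::create(_["beta"] = sc_beta,
                               _["phi"] = s_phi.scale()));
}
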
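#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Gibbs samplers for the measurement-error DPGMM.
//
// Model: y_i ~ N(theta_i, sigma_k^2), theta_i ~ N(mu_k, tau_i^2),
// (mu_k, sigma_k^2) ~ N(mu0, sigma0_sq) x IG(r1, r2), CRP(alpha) on the
// partition.
//
// method "augmented" (blocked = false): the printed algorithm — update
// all theta (Step 2), reassign all c_i sequentially conditioning on
// theta_i, with immediate cluster birth/death bookkeeping (Step 3),
// resample all cluster parameters from the theta-based conditionals
// (Step 4). All stochastic draws go through R's RNG in a fixed order,
// and every reduction the pure-R reference sweep performs with
// sum()/cumsum() is accumulated in long double here, so a run with a
// given seed is bitwise reproducible in the interpreted reference.
//
// method "blocked" (blocked = true): exact blocked variant with better
// mixing — c_i is updated with theta_i integrated out (weights
// n_k N(y_i; mu_k, sigma_k^2 + tau_i^2); new clusters via m_aux
// auxiliary parameter draws from the base measure, Neal's Algorithm 8),
// after which theta_i is redrawn under the landing cluster; mu_k is
// updated with the member thetas integrated out (conjugate on y with
// variance sigma_k^2 + tau_i^2), after which member thetas are redrawn.
// Both methods have the same stationary distribution.

static double nll_current(const std::vector<double> &mu,
                          const std::vector<double> &sigsq,
                          const std::vector<int> &nk,
                          const NumericVector &y,
                          const NumericVector &tau_sq) {
  const int n = y.size();
  const int K = (int)mu.size();
  long double acc = 0.0L;
  for (int i = 0; i < n; ++i) {
    long double dens = 0.0L;
    for (int k = 0; k < K; ++k) {
      double sd = std::sqrt(sigsq[k] + tau_sq[i]);
      dens += (nk[k] / (double)n) * R::dnorm(y[i], mu[k], sd, 0);
    }
    acc += std::log((double)dens);
  }
  return -(double)acc;
}

// [[Rcpp::export]]
List cpp_run_gibbs(NumericVector y, NumericVector tau_sq,
                   int iterations, int burn_in, int thin,
                   double alpha, double mu0, double sigma0_sq,
                   double r1, double r2,
                   IntegerVector init_c, NumericVector init_theta,
                   NumericVector init_mu, NumericVector init_sigsq,
                   bool blocked, int m_aux, bool verbose) {
  const int n = y.size();
  const double l2p = std::log(2.0 * M_PI);

  std::vector<int> cvec(init_c.begin(), init_c.end());
  std::vector<double> theta(init_theta.begin(), init_theta.end());
  std::vector<double> mu(init_mu.begin(), init_mu.end());
  std::vector<double> sigsq(init_sigsq.begin(), init_sigsq.end());
  std::vector<int> nk(mu.size(), 0);
  for (int i = 0; i < n; ++i) nk[cvec[i] - 1] += 1;

  const int n_keep = (iterations - burn_in) / thin;
  IntegerVector keep_K(n_keep);
  NumericVector keep_nll(n_keep);
  IntegerMatrix keep_c(n_keep, n);
  List keep_params(n_keep);

  std::vector<double> lw, w, cum, mu_aux, s2_aux;

  for (int iter = 1; iter <= iterations; ++iter) {
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();

    // Step 2: latent true effects
    for (int i = 0; i < n; ++i) {
      int k = cvec[i] - 1;
      double prec = 1.0 / sigsq[k] + 1.0 / tau_sq[i];
      double m = (y[i] / sigsq[k] + mu[k] / tau_sq[i]) / prec;
      double v = 1.0 / prec;
      theta[i] = R::rnorm(m, std::sqrt(v));
    }

    // Step 3: cluster indicators, sequential
    for (int i = 0; i < n; ++i) {
      int k_old = cvec[i] - 1;
      nk[k_old] -= 1;
      if (nk[k_old] == 0) {
        mu.erase(mu.begin() + k_old);
        sigsq.erase(sigsq.begin() + k_old);
        nk.erase(nk.begin() + k_old);
        for (int j = 0; j < n; ++j)
          if (cvec[j] > k_old + 1) cvec[j] -= 1;
      }
      const int K = (int)mu.size();
      const double t2 = tau_sq[i];
      const double th = theta[i];
      const double dy2 = (y[i] - th) * (y[i] - th);

      int n_cand;
      if (!blocked) {
        // printed kernels, conditional on theta_i
        n_cand = K + 1;
        lw.assign(n_cand, 0.0);
        for (int k = 0; k < K; ++k) {
          lw[k] = ((((std::log((double)nk[k]) - l2p)
                     - 0.5 * std::log(sigsq[k] * t2))
                    - dy2 / (2.0 * sigsq[k]))
                   - ((th - mu[k]) * (th - mu[k])) / (2.0 * t2));
        }
        lw[K] = ((((((std::log(alpha) - l2p)
                     + r1 * std::log(r2))
                    - R::lgammafn(r1))
                   + R::lgammafn(r1 + 0.5))
                  - (r1 + 0.5) * std::log(0.5 * dy2 + r2))
                 - 0.5 * std::log(t2 + sigma0_sq))
                - ((th - mu0) * (th - mu0)) / (2.0 * (t2 + sigma0_sq));
      } else {
        // theta_i integrated out: marginal N(y; mu_k, sigma_k^2 + tau^2);
        // auxiliary fresh parameters stand in for the new cluster
        n_cand = K + m_aux;
        lw.assign(n_cand, 0.0);
        mu_aux.assign(m_aux, 0.0);
        s2_aux.assign(m_aux, 0.0);
        for (int k = 0; k < K; ++k)
          lw[k] = std::log((double)nk[k]) +
            R::dnorm(y[i], mu[k], std::sqrt(sigsq[k] + t2), 1);
        for (int j = 0; j < m_aux; ++j) {
          mu_aux[j] = R::rnorm(mu0, std::sqrt(sigma0_sq));
          s2_aux[j] = 1.0 / R::rgamma(r1, 1.0 / r2);
          lw[K + j] = std::log(alpha / m_aux) +
            R::dnorm(y[i], mu_aux[j], std::sqrt(s2_aux[j] + t2), 1);
        }
      }

      double mx = lw[0];
      for (int k = 1; k < n_cand; ++k) if (lw[k] > mx) mx = lw[k];
      w.assign(n_cand, 0.0);
      cum.assign(n_cand, 0.0);
      long double acc = 0.0L;
      for (int k = 0; k < n_cand; ++k) {
        w[k] = std::exp(lw[k] - mx);
        acc += w[k];
        cum[k] = (double)acc;
      }
      double tot = cum[n_cand - 1];
      double u = unif_rand() * tot;
      int pick = n_cand - 1;  // falls through to the last slot if u == tot
      for (int k = 0; k < n_cand; ++k) {
        if (u < cum[k]) { pick = k; break; }
      }

      if (pick >= K) {
        double s2_new, mu_new;
        if (!blocked) {
          // open a new cluster: draw its parameters from the conditionals
          // given this single observation
          double shape = r1 + 1 / 2.0;
          double rate = dy2 / 2.0 + r2;
          s2_new = 1.0 / R::rgamma(shape, 1.0 / rate);
          double prec = 1.0 / t2 + 1.0 / sigma0_sq;
          double mmean = (th / t2 + mu0 / sigma0_sq) / prec;
          mu_new = R::rnorm(mmean, std::sqrt(1.0 / prec));
        } else {
          mu_new = mu_aux[pick - K];
          s2_new = s2_aux[pick - K];
        }
        mu.push_back(mu_new);
        sigsq.push_back(s2_new);
        nk.push_back(1);
        cvec[i] = K + 1;
      } else {
        cvec[i] = pick + 1;
        nk[pick] += 1;
      }
      if (blocked) {
        // complete the blocked move: theta_i under its landing cluster
        int k = cvec[i] - 1;
        double prec = 1.0 / sigsq[k] + 1.0 / t2;
        double m = (y[i] / sigsq[k] + mu[k] / t2) / prec;
        theta[i] = R::rnorm(m, std::sqrt(1.0 / prec));
      }
    }

    // Step 4: cluster parameters
    {
      const int K = (int)mu.size();
      for (int k = 0; k < K; ++k) {
        if (!blocked) {
          long double s_inv = 0.0L, s_th = 0.0L;
          int count = 0;
          for (int i = 0; i < n; ++i) {
            if (cvec[i] == k + 1) {
              s_inv += 1.0 / tau_sq[i];
              s_th += theta[i] / tau_sq[i];
              ++count;
            }
          }
          double prec = (double)s_inv + 1.0 / sigma0_sq;
          double mmean = ((double)s_th + mu0 / sigma0_sq) / prec;
          mu[k] = R::rnorm(mmean, std::sqrt(1.0 / prec));
          (void)count;
        } else {
          long double s_inv = 0.0L, s_y = 0.0L;
          for (int i = 0; i < n; ++i) {
            if (cvec[i] == k + 1) {
              double v = sigsq[k] + tau_sq[i];
              s_inv += 1.0 / v;
              s_y += y[i] / v;
            }
          }
          double prec = (double)s_inv + 1.0 / sigma0_sq;
          double mmean = ((double)s_y + mu0 / sigma0_sq) / prec;
          mu[k] = R::rnorm(mmean, std::sqrt(1.0 / prec));
          // refresh member thetas under the new mean
          for (int i = 0; i < n; ++i) {
            if (cvec[i] == k + 1) {
              double prt = 1.0 / sigsq[k] + 1.0 / tau_sq[i];
              double mt = (y[i] / sigsq[k] + mu[k] / tau_sq[i]) / prt;
              theta[i] = R::rnorm(mt, std::sqrt(1.0 / prt));
            }
          }
        }
        long double s_rss = 0.0L;
        int count = 0;
        for (int i = 0; i < n; ++i) {
          if (cvec[i] == k + 1) {
            s_rss += (y[i] - theta[i]) * (y[i] - theta[i]);
            ++count;
          }
        }
        double shape = r1 + count / 2.0;
        double rate = (double)s_rss / 2.0 + r2;
        sigsq[k] = 1.0 / R::rgamma(shape, 1.0 / rate);
      }
    }

    if (verbose && iter % 1000 == 0) {
      Rprintf("iter %d: K = %d, NLL = %.4f\n", iter, (int)mu.size(),
              nll_current(mu, sigsq, nk, y, tau_sq));
    }

    // record post-burn-in thinned samples
    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      int r = (iter - burn_in) / thin - 1;
      if (r < n_keep) {
        keep_K[r] = (int)mu.size();
        keep_nll[r] = nll_current(mu, sigsq, nk, y, tau_sq);
        for (int j = 0; j < n; ++j) keep_c(r, j) = cvec[j];
        keep_params[r] = List::create(
          _["mu"] = NumericVector(mu.begin(), mu.end()),
          _["sigma_sq"] = NumericVector(sigsq.begin(), sigsq.end()),
          _["size"] = IntegerVector(nk.begin(), nk.end()));
      }
    }
  }

  return List::create(_["K"] = keep_K, _["nll"] = keep_nll,
                      _["assignments"] = keep_c, _["params"] = keep_params);
}
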
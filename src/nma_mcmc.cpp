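#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for two-arm evidence networks.
//
// Trial i contributes either a contrast-level observation
//   y_i ~ Normal(delta_i, s_i^2)
// or an arm-level binary observation
//   r_ref_i ~ Binomial(n_ref_i, plogis(mu_i))
//   r_alt_i ~ Binomial(n_alt_i, plogis(mu_i + delta_i)).
// The trial-level effect delta_i has mean X[i,] %*% b, where b holds the
// free effect parameters (basic parameters d_k under consistency, one
// parameter per edge under the UME model, or basic + split-edge direct
// parameter for node-splitting).  Random-effects model:
//   delta_i ~ Normal(X[i,] b, tau^2),  tau ~ Uniform(0, tau_upper);
// fixed-effect model: delta_i == X[i,] b.
// Priors: b_k ~ Normal(0, prior_sd_effect^2), mu_i ~ Normal(0, prior_sd_mu^2).
//
// Normal full conditionals (delta and, given delta, b in the random model;
// b in the fixed-effect contrast model) are sampled by exact Gibbs steps;
// all remaining parameters use random-walk Metropolis with per-parameter
// proposal scales adapted during burn-in only, so the post-burn-in chain is
// a fixed-kernel Markov chain.  All randomness comes from R's RNG, so runs
// are reproducible given set.seed().

static inline double softplus(double x) {
  return x > 35.0 ? x : std::log1p(std::exp(x));
}
// log plogis(x) and log(1 - plogis(x))
static inline double logp(double x) { return -softplus(-x); }
static inline double log1mp(double x) { return -softplus(x); }

static inline double binom_ll(int r, int n, double eta) {
  return r * logp(eta) + (n - r) * log1mp(eta);
}

// residual deviance contribution of one binomial arm
static inline double binom_dev(int r, int n, double p) {
  double d = 0.0;
  double fit = n * p;
  if (r > 0) d += r * std::log(r / fit);
  if (n - r > 0) d += (n - r) * std::log((n - r) / (n - fit));
  return 2.0 * d;
}

// [[Rcpp::export]]
List nma_mcmc_cpp(int data_kind,            // 0 = contrast, 1 = binary
                  NumericMatrix X,          // N x P design for E[delta]
                  NumericVector y, NumericVector s,
                  IntegerVector r_ref, IntegerVector n_ref,
                  IntegerVector r_alt, IntegerVector n_alt,
                  bool random,
                  double prior_sd_effect, double prior_sd_mu,
                  double tau_upper,
                  int chains, int burn, int kept_iter, int thin,
                  NumericVector init_offsets,
                  NumericVector mu_init) {
  const int N = X.nrow(), P = X.ncol();
  const bool binary = (data_kind == 1);
  const int kept_per_chain = kept_iter / thin;
  const double prec_prior_b = 1.0 / (prior_sd_effect * prior_sd_effect);
  const double prec_prior_mu = 1.0 / (prior_sd_mu * prior_sd_mu);

  // trials touched by each effect parameter
  std::vector< std::vector<int> > hit(P);
  for (int k = 0; k < P; ++k)
    for (int i = 0; i < N; ++i)
      if (X(i, k) != 0.0) hit[k].push_back(i);

  const int ncol_out = P + (random ? 1 : 0) + (random ? N : 0) +
                       (binary ? N : 0) + 1;
  NumericMatrix draws(chains * kept_per_chain, ncol_out);
  IntegerVector chain_id(chains * kept_per_chain);
  NumericVector accept(P + 2);  // b params, mu (pooled), tau
  double acc_n = 0.0;

  std::vector<double> prec_y(N);
  if (!binary) for (int i = 0; i < N; ++i) prec_y[i] = 1.0 / (s[i] * s[i]);

  int row = 0;
  for (int c = 0; c < chains; ++c) {
    // overdispersed starting points, scaled off the effect prior
    double off = init_offsets[c % init_offsets.size()];
    std::vector<double> b(P, off * prior_sd_effect * 0.1);
    std::vector<double> Xb(N), delta(N), mu(N, 0.0);
    auto refresh_Xb = [&]() {
      for (int i = 0; i < N; ++i) {
        double v = 0.0;
        for (int k = 0; k < P; ++k) v += X(i, k) * b[k];
        Xb[i] = v;
      }
    };
    refresh_Xb();
    for (int i = 0; i < N; ++i) delta[i] = Xb[i];
    if (binary) for (int i = 0; i < N; ++i) mu[i] = mu_init[i];
    double tau = random ? tau_upper * (c + 1.0) / (chains + 1.0) : 0.0;

    // adaptive proposal scales
    std::vector<double> sc_b(P, 0.5), sc_mu(N, 0.5), sc_delta(N, 0.5);
    double sc_tau = 0.25 * tau_upper;
    std::vector<int> acc_b(P, 0), acc_mu(N, 0), acc_delta(N, 0);
    int acc_tau = 0, batch = 0;

    const int total = burn + kept_iter;
    for (int it = 0; it < total; ++it) {
      const bool adapting = it < burn;
      const double tau2 = tau * tau;

      if (!binary) {
        if (random) {
          // delta_i | rest : exact Gibbs (normal-normal)
          for (int i = 0; i < N; ++i) {
            double prec = prec_y[i] + 1.0 / tau2;
            double m = (y[i] * prec_y[i] + Xb[i] / tau2) / prec;
            delta[i] = m + R::rnorm(0.0, 1.0) / std::sqrt(prec);
          }
          // b_k | delta, tau : exact Gibbs
          for (int k = 0; k < P; ++k) {
            double prec = prec_prior_b, num = 0.0;
            for (int idx : hit[k]) {
              double x = X(idx, k);
              prec += x * x / tau2;
              num += x * (delta[idx] - (Xb[idx] - x * b[k])) / tau2;
            }
            double bnew = num / prec + R::rnorm(0.0, 1.0) / std::sqrt(prec);
            double db = bnew - b[k];
            b[k] = bnew;
            for (int idx : hit[k]) Xb[idx] += X(idx, k) * db;
          }
        } else {
          // fixed effect: b_k | y : exact Gibbs
          for (int k = 0; k < P; ++k) {
            double prec = prec_prior_b, num = 0.0;
            for (int idx : hit[k]) {
              double x = X(idx, k);
              prec += x * x * prec_y[idx];
              num += x * (y[idx] - (Xb[idx] - x * b[k])) * prec_y[idx];
            }
            double bnew = num / prec + R::rnorm(0.0, 1.0) / std::sqrt(prec);
            double db = bnew - b[k];
            b[k] = bnew;
            for (int idx : hit[k]) Xb[idx] += X(idx, k) * db;
          }
        }
      } else {
        // binary likelihood: mu_i by Metropolis
        for (int i = 0; i < N; ++i) {
          double d_i = random ? delta[i] : Xb[i];
          double prop = mu[i] + sc_mu[i] * R::rnorm(0.0, 1.0);
          double lr =
            binom_ll(r_ref[i], n_ref[i], prop) -
            binom_ll(r_ref[i], n_ref[i], mu[i]) +
            binom_ll(r_alt[i], n_alt[i], prop + d_i) -
            binom_ll(r_alt[i], n_alt[i], mu[i] + d_i) +
            0.5 * prec_prior_mu * (mu[i] * mu[i] - prop * prop);
          if (std::log(R::runif(0.0, 1.0)) < lr) { mu[i] = prop; acc_mu[i]++; }
        }
        if (random) {
          // delta_i by Metropolis (binomial x normal prior)
          for (int i = 0; i < N; ++i) {
            double prop = delta[i] + sc_delta[i] * R::rnorm(0.0, 1.0);
            double lr =
              binom_ll(r_alt[i], n_alt[i], mu[i] + prop) -
              binom_ll(r_alt[i], n_alt[i], mu[i] + delta[i]) +
              (-(prop - Xb[i]) * (prop - Xb[i]) +
                (delta[i] - Xb[i]) * (delta[i] - Xb[i])) / (2.0 * tau2);
            if (std::log(R::runif(0.0, 1.0)) < lr) { delta[i] = prop; acc_delta[i]++; }
          }
          // b_k | delta, tau : exact Gibbs as in the contrast model
          for (int k = 0; k < P; ++k) {
            double prec = prec_prior_b, num = 0.0;
            for (int idx : hit[k]) {
              double x = X(idx, k);
              prec += x * x / tau2;
              num += x * (delta[idx] - (Xb[idx] - x * b[k])) / tau2;
            }
            double bnew = num / prec + R::rnorm(0.0, 1.0) / std::sqrt(prec);
            double db = bnew - b[k];
            b[k] = bnew;
            for (int idx : hit[k]) Xb[idx] += X(idx, k) * db;
          }
        } else {
          // fixed effect: b_k by Metropolis against the binomial likelihood
          for (int k = 0; k < P; ++k) {
            double prop = b[k] + sc_b[k] * R::rnorm(0.0, 1.0);
            double db = prop - b[k];
            double lr = 0.5 * prec_prior_b * (b[k] * b[k] - prop * prop);
            for (int idx : hit[k]) {
              double eta_new = mu[idx] + Xb[idx] + X(idx, k) * db;
              double eta_old = mu[idx] + Xb[idx];
              lr += binom_ll(r_alt[idx], n_alt[idx], eta_new) -
                    binom_ll(r_alt[idx], n_alt[idx], eta_old);
            }
            if (std::log(R::runif(0.0, 1.0)) < lr) {
              b[k] = prop;
              for (int idx : hit[k]) Xb[idx] += X(idx, k) * db;
              acc_b[k]++;
            }
          }
        }
      }

      if (random) {
        // tau by Metropolis under Uniform(0, tau_upper) prior
        double prop = tau + sc_tau * R::rnorm(0.0, 1.0);
        if (prop > 0.0 && prop < tau_upper) {
          double ss = 0.0;
          for (int i = 0; i < N; ++i) {
            double e = delta[i] - Xb[i];
            ss += e * e;
          }
          double lr = -N * (std::log(prop) - std::log(tau)) -
                      ss / 2.0 * (1.0 / (prop * prop) - 1.0 / tau2);
          if (std::log(R::runif(0.0, 1.0)) < lr) { tau = prop; acc_tau++; }
        }
      }

      // adapt proposal scales during burn-in (batches of 50)
      if (adapting && (it + 1) % 50 == 0) {
        batch++;
        double step = std::min(0.25, 2.0 / std::sqrt((double)batch));
        auto tune = [&](double &sc, int &acc) {
          double rate = acc / 50.0;
          sc *= std::exp(step * (rate - 0.44));
          acc = 0;
        };
        for (int k = 0; k < P; ++k) tune(sc_b[k], acc_b[k]);
        for (int i = 0; i < N; ++i) { tune(sc_mu[i], acc_mu[i]); tune(sc_delta[i], acc_delta[i]); }
        tune(sc_tau, acc_tau);
      }
      if (it == burn - 1) {  // reset counters at end of burn-in
        std::fill(acc_b.begin(), acc_b.end(), 0);
        std::fill(acc_mu.begin(), acc_mu.end(), 0);
        std::fill(acc_delta.begin(), acc_delta.end(), 0);
        acc_tau = 0;
      }

      if (it >= burn && (it - burn + 1) % thin == 0) {
        int j = 0;
        for (int k = 0; k < P; ++k) draws(row, j++) = b[k];
        if (random) draws(row, j++) = tau;
        if (random) for (int i = 0; i < N; ++i) draws(row, j++) = delta[i];
        if (binary) for (int i = 0; i < N; ++i) draws(row, j++) = mu[i];
        // total residual deviance
        double dev = 0.0;
        if (!binary) {
          for (int i = 0; i < N; ++i) {
            double th = random ? delta[i] : Xb[i];
            double e = (y[i] - th) / s[i];
            dev += e * e;
          }
        } else {
          for (int i = 0; i < N; ++i) {
            double d_i = random ? delta[i] : Xb[i];
            double p0 = 1.0 / (1.0 + std::exp(-mu[i]));
            double p1 = 1.0 / (1.0 + std::exp(-(mu[i] + d_i)));
            dev += binom_dev(r_ref[i], n_ref[i], p0) +
                   binom_dev(r_alt[i], n_alt[i], p1);
          }
        }
        draws(row, j) = dev;
        chain_id[row] = c + 1;
        row++;
      }
    }
    // post-burn-in acceptance summary (per chain, averaged later)
    double kept = (double)kept_iter;
    for (int k = 0; k < P; ++k) accept[k] += acc_b[k] / kept / chains;
    double mu_acc = 0.0;
    for (int i = 0; i < N; ++i) mu_acc += acc_mu[i] / kept;
    accept[P] += mu_acc / N / chains;
    accept[P + 1] += acc_tau / kept / chains;
    acc_n += 1.0;
  }

  return List::create(_["draws"] = draws, _["chain"] = chain_id,
                      _["accept"] = accept);
}
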
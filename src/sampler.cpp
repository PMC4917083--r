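#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-site adaptive random-walk Metropolis-within-Gibbs for the
// hierarchical power-law learning-curve model
//   y_st ~ Normal(I_s + C_s (1 - R_s^(t-1)), sigma_obs[g(s)])
//   I_s ~ N(muI_g, sigI_g), C_s ~ N(muC_g, sigC_g), R_s ~ N(muR_g, sigR_g)
//   muI, muC ~ N(0, mu_sd^2); muR ~ U(0,1); all sigmas ~ Half-N(0, sig_scale^2)
// R_s is updated on the logit scale (Jacobian included) so proposals never
// hit the (0,1) boundary. Proposal scales adapt toward 0.44 acceptance in
// batches during burn-in and are frozen afterwards. Uses R's RNG, so results
// are reproducible under set.seed().

static inline double inv_logit(double x) {
  if (x > 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

struct Model {
  const NumericVector &y;
  const IntegerVector &t;       // trial index per observation
  const IntegerVector &off;     // length S+1, observation offsets per subject
  const IntegerVector &grp;     // 0-based group per subject
  int S, G;

  double sse_subject(int s, double I, double C, double R) const {
    double sse = 0.0;
    for (int j = off[s]; j < off[s + 1]; ++j) {
      double mu = I + C * (1.0 - std::pow(R, (double)(t[j] - 1)));
      double r = y[j] - mu;
      sse += r * r;
    }
    return sse;
  }
  int n_obs(int s) const { return off[s + 1] - off[s]; }
};

// half-normal log density up to its constant (support checked by caller)
static inline double hn_lpdf(double x, double scale) {
  return -0.5 * (x / scale) * (x / scale);
}

// [[Rcpp::export]]
List mwg_sample(NumericVector y, IntegerVector t, IntegerVector off,
                IntegerVector grp, int n_group,
                NumericVector I0, NumericVector C0, NumericVector lR0,
                NumericMatrix mu0, NumericMatrix sig0, NumericVector sobs0,
                int n_iter, int n_burnin, int thin, int adapt_batch,
                double mu_sd, double sig_scale,
                bool flat, bool fix_R, bool fix_sobs) {
  Model m{y, t, off, grp, (int)I0.size(), n_group};
  const int S = m.S, G = n_group;

  std::vector<double> I(I0.begin(), I0.end());
  std::vector<double> C(C0.begin(), C0.end());
  std::vector<double> lR(lR0.begin(), lR0.end());
  std::vector<double> R(S);
  for (int s = 0; s < S; ++s) R[s] = inv_logit(lR[s]);

  // hyperparameters: [G x 3] means/sds over (I, C, R), plus sigma_obs[G]
  std::vector<double> mu(3 * G), sig(3 * G), sobs(sobs0.begin(), sobs0.end());
  for (int g = 0; g < G; ++g)
    for (int k = 0; k < 3; ++k) {
      mu[3 * g + k] = mu0(g, k);
      sig[3 * g + k] = sig0(g, k);
    }

  // cached sum of squared residuals per subject
  std::vector<double> sse(S);
  for (int s = 0; s < S; ++s) sse[s] = m.sse_subject(s, I[s], C[s], R[s]);

  // group bookkeeping
  std::vector<std::vector<int>> members(G);
  for (int s = 0; s < S; ++s) members[grp[s]].push_back(s);
  std::vector<int> grp_nobs(G, 0);
  for (int s = 0; s < S; ++s) grp_nobs[grp[s]] += m.n_obs(s);

  // adaptive proposal log-scales: 3S subject sites + 7G hyper sites
  const int P_upd = 3 * S + 7 * G;
  std::vector<double> lsc(P_upd);
  for (int s = 0; s < S; ++s) {
    lsc[3 * s] = std::log(0.5);
    lsc[3 * s + 1] = std::log(0.5);
    lsc[3 * s + 2] = std::log(0.5);
  }
  for (int g = 0; g < G; ++g)
    for (int k = 0; k < 7; ++k) lsc[3 * S + 7 * g + k] = std::log(0.3);
  std::vector<int> acc(P_upd, 0), tries(P_upd, 0);

  const int n_keep = (n_iter - n_burnin) / thin;
  const int P_out = 3 * S + 7 * G;
  NumericMatrix draws(n_keep, P_out);

  int kept = 0, batch_no = 0;
  for (int it = 1; it <= n_iter; ++it) {
    // ---- subject-level updates -------------------------------------------
    for (int s = 0; s < S; ++s) {
      const int g = grp[s];
      const double tau = 1.0 / (2.0 * sobs[g] * sobs[g]);

      // I_s
      {
        int p = 3 * s;
        double prop = I[s] + R::rnorm(0.0, std::exp(lsc[p]));
        double sse_new = m.sse_subject(s, prop, C[s], R[s]);
        double d = -(sse_new - sse[s]) * tau;
        if (!flat) {
          double mI = mu[3 * g], sI = sig[3 * g];
          d += (-(prop - mI) * (prop - mI) + (I[s] - mI) * (I[s] - mI)) /
               (2.0 * sI * sI);
        }
        ++tries[p];
        if (std::log(R::runif(0.0, 1.0)) < d) {
          I[s] = prop; sse[s] = sse_new; ++acc[p];
        }
      }
      // C_s
      {
        int p = 3 * s + 1;
        double prop = C[s] + R::rnorm(0.0, std::exp(lsc[p]));
        double sse_new = m.sse_subject(s, I[s], prop, R[s]);
        double d = -(sse_new - sse[s]) * tau;
        if (!flat) {
          double mC = mu[3 * g + 1], sC = sig[3 * g + 1];
          d += (-(prop - mC) * (prop - mC) + (C[s] - mC) * (C[s] - mC)) /
               (2.0 * sC * sC);
        }
        ++tries[p];
        if (std::log(R::runif(0.0, 1.0)) < d) {
          C[s] = prop; sse[s] = sse_new; ++acc[p];
        }
      }
      // R_s on logit scale (skip when fixed)
      if (!fix_R) {
        int p = 3 * s + 2;
        double lprop = lR[s] + R::rnorm(0.0, std::exp(lsc[p]));
        double Rprop = inv_logit(lprop);
        if (Rprop > 0.0 && Rprop < 1.0) {
          double sse_new = m.sse_subject(s, I[s], C[s], Rprop);
          double d = -(sse_new - sse[s]) * tau;
          // Jacobian of the logit map: log R (1 - R)
          d += std::log(Rprop * (1.0 - Rprop)) -
               std::log(R[s] * (1.0 - R[s]));
          if (!flat) {
            double mR = mu[3 * g + 2], sR = sig[3 * g + 2];
            d += (-(Rprop - mR) * (Rprop - mR) + (R[s] - mR) * (R[s] - mR)) /
                 (2.0 * sR * sR);
          }
          ++tries[p];
          if (std::log(R::runif(0.0, 1.0)) < d) {
            lR[s] = lprop; R[s] = Rprop; sse[s] = sse_new; ++acc[p];
          }
        } else {
          ++tries[p];
        }
      }
    }

    // ---- group-level updates ---------------------------------------------
    if (!flat) {
      for (int g = 0; g < G; ++g) {
        // means and SDs of (I, C, R)
        for (int k = 0; k < 3; ++k) {
          const double *par = (k == 0) ? I.data() : (k == 1) ? C.data()
                                                             : R.data();
          // mu_{g,k}
          {
            int p = 3 * S + 7 * g + k;
            double cur = mu[3 * g + k], sd = sig[3 * g + k];
            double prop = cur + R::rnorm(0.0, std::exp(lsc[p]));
            ++tries[p];
            bool ok = (k == 2) ? (prop > 0.0 && prop < 1.0) : true;
            if (ok) {
              double d = 0.0;
              for (int s : members[g]) {
                double a = par[s] - prop, b = par[s] - cur;
                d += (-a * a + b * b) / (2.0 * sd * sd);
              }
              if (k != 2)
                d += (-prop * prop + cur * cur) / (2.0 * mu_sd * mu_sd);
              if (std::log(R::runif(0.0, 1.0)) < d) {
                mu[3 * g + k] = prop; ++acc[p];
              }
            }
          }
          // sigma_{g,k}
          {
            int p = 3 * S + 7 * g + 3 + k;
            double cur = sig[3 * g + k], mn = mu[3 * g + k];
            double prop = cur + R::rnorm(0.0, std::exp(lsc[p]));
            ++tries[p];
            if (prop > 1e-6) {
              double n_g = (double)members[g].size();
              double d = n_g * (std::log(cur) - std::log(prop));
              double ip = 1.0 / (2.0 * prop * prop),
                     ic = 1.0 / (2.0 * cur * cur);
              for (int s : members[g]) {
                double a = par[s] - mn;
                d += a * a * (ic - ip);
              }
              d += hn_lpdf(prop, sig_scale) - hn_lpdf(cur, sig_scale);
              if (std::log(R::runif(0.0, 1.0)) < d) {
                sig[3 * g + k] = prop; ++acc[p];
              }
            }
          }
        }
        // sigma_obs[g]
        if (!fix_sobs) {
          int p = 3 * S + 7 * g + 6;
          double cur = sobs[g];
          double prop = cur + R::rnorm(0.0, std::exp(lsc[p]));
          ++tries[p];
          if (prop > 1e-6) {
            double sse_g = 0.0;
            for (int s : members[g]) sse_g += sse[s];
            double d = (double)grp_nobs[g] * (std::log(cur) - std::log(prop));
            d += sse_g * (1.0 / (2.0 * cur * cur) - 1.0 / (2.0 * prop * prop));
            d += hn_lpdf(prop, sig_scale) - hn_lpdf(cur, sig_scale);
            if (std::log(R::runif(0.0, 1.0)) < d) {
              sobs[g] = prop; ++acc[p];
            }
          }
        }
      }
    }

    // ---- adaptation (burn-in only) ---------------------------------------
    if (it <= n_burnin && it % adapt_batch == 0) {
      ++batch_no;
      double step = std::min(0.1, 1.0 / std::sqrt((double)batch_no));
      for (int p = 0; p < P_upd; ++p) {
        if (tries[p] == 0) continue;
        double rate = (double)acc[p] / (double)tries[p];
        lsc[p] += (rate > 0.44) ? step : -step;
        acc[p] = 0; tries[p] = 0;
      }
    }

    // ---- recording -------------------------------------------------------
    if (it > n_burnin && (it - n_burnin) % thin == 0) {
      int col = 0;
      for (int s = 0; s < S; ++s) draws(kept, col++) = I[s];
      for (int s = 0; s < S; ++s) draws(kept, col++) = C[s];
      for (int s = 0; s < S; ++s) draws(kept, col++) = R[s];
      for (int k = 0; k < 3; ++k)
        for (int g = 0; g < G; ++g) draws(kept, col++) = mu[3 * g + k];
      for (int k = 0; k < 3; ++k)
        for (int g = 0; g < G; ++g) draws(kept, col++) = sig[3 * g + k];
      for (int g = 0; g < G; ++g) draws(kept, col++) = sobs[g];
      ++kept;
    }
  }

  NumericVector scales(P_upd);
  for (int p = 0; p < P_upd; ++p) scales[p] = std::exp(lsc[p]);
  return List::create(_["draws"] = draws, _["proposal_scales"] = scales);
}
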
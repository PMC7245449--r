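// Metropolis-within-Gibbs sampler for the binomial space-time model
//   Y_ij ~ Binomial(n_ij, pi_ij),  logit(pi_ij) = alpha + phi_i + gamma_j + nu_ij
// with an intrinsic CAR prior on phi (binary common-boundary weights,
// exchangeable N(0, 1/tau_phi) fallback for isolated districts), an RW1
// prior on gamma, iid N(0, 1/tau_nu) interaction nu, conjugate Gamma
// updates for the three precisions, and scalar random-walk Metropolis
// for the location parameters. Sum-to-zero is enforced after the phi and
// gamma sweeps by moving the block mean into alpha (a likelihood- and
// prior-preserving reparameterisation along the flat directions).
// Uses R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double lse1p(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// [[Rcpp::export]]
List car_st_mcmc_cpp(NumericMatrix Y, NumericMatrix n, List nb,
                     int n_iter, int thin,
                     double alpha, NumericVector phi_, NumericVector gamma_,
                     NumericMatrix nu_, double tau_phi, double tau_gamma,
                     double tau_nu, NumericVector prop_sd_, bool adapt,
                     double hyper_shape, double hyper_rate,
                     int rank_phi, bool use_phi, bool use_gamma, bool use_nu,
                     bool save_draws) {
  const int I = Y.nrow(), J = Y.ncol();
  NumericVector phi = clone(phi_), gam = clone(gamma_), prop_sd = clone(prop_sd_);
  NumericMatrix nu = clone(nu_);

  std::vector< std::vector<int> > nbr(I);
  for (int i = 0; i < I; ++i) {
    IntegerVector v = nb[i];
    nbr[i].assign(v.begin(), v.end());  // 0-based
  }

  // eta cache
  NumericMatrix eta(I, J);
  for (int i = 0; i < I; ++i)
    for (int j = 0; j < J; ++j)
      eta(i, j) = alpha + phi[i] + gam[j] + nu(i, j);

  const int n_save = save_draws ? n_iter / thin : 0;
  NumericMatrix pi_draws(n_save, I * J);
  NumericVector alpha_draws(n_save), tphi_draws(n_save), tgam_draws(n_save),
                tnu_draws(n_save);

  // acceptance bookkeeping: 0 alpha, 1 phi, 2 gamma, 3 nu
  std::vector<long> acc(4, 0), tot(4, 0);
  std::vector<long> acc_win(4, 0), tot_win(4, 0);

  int save_k = 0;
  for (int it = 1; it <= n_iter; ++it) {
    // --- alpha (flat prior) ---
    {
      double prop = alpha + R::norm_rand() * prop_sd[0];
      double d = prop - alpha, dlp = 0.0;
      for (int i = 0; i < I; ++i)
        for (int j = 0; j < J; ++j) {
          if (n(i, j) <= 0) continue;
          double e0 = eta(i, j), e1 = e0 + d;
          dlp += Y(i, j) * d - n(i, j) * (lse1p(e1) - lse1p(e0));
        }
      ++tot[0]; ++tot_win[0];
      if (std::log(R::unif_rand()) < dlp) {
        alpha = prop; ++acc[0]; ++acc_win[0];
        for (int i = 0; i < I; ++i)
          for (int j = 0; j < J; ++j) eta(i, j) += d;
      }
    }

    // --- phi sweep ---
    if (use_phi) {
      for (int i = 0; i < I; ++i) {
        double prop = phi[i] + R::norm_rand() * prop_sd[1];
        double d = prop - phi[i], dlp = 0.0;
        for (int j = 0; j < J; ++j) {
          if (n(i, j) <= 0) continue;
          double e0 = eta(i, j), e1 = e0 + d;
          dlp += Y(i, j) * d - n(i, j) * (lse1p(e1) - lse1p(e0));
        }
        const int m = nbr[i].size();
        if (m > 0) {
          double s = 0.0;
          for (int k = 0; k < m; ++k) s += phi[nbr[i][k]];
          double mu = s / m;
          dlp += -0.5 * tau_phi * m * ((prop - mu) * (prop - mu) -
                                       (phi[i] - mu) * (phi[i] - mu));
        } else {
          dlp += -0.5 * tau_phi * (prop * prop - phi[i] * phi[i]);
        }
        ++tot[1]; ++tot_win[1];
        if (std::log(R::unif_rand()) < dlp) {
          phi[i] = prop; ++acc[1]; ++acc_win[1];
          for (int j = 0; j < J; ++j) eta(i, j) += d;
        }
      }
      // recentre: move the mean into alpha (eta unchanged)
      double mbar = 0.0;
      for (int i = 0; i < I; ++i) mbar += phi[i];
      mbar /= I;
      for (int i = 0; i < I; ++i) phi[i] -= mbar;
      alpha += mbar;
    }

    // --- gamma sweep (RW1) ---
    if (use_gamma) {
      for (int j = 0; j < J; ++j) {
        double prop = gam[j] + R::norm_rand() * prop_sd[2];
        double d = prop - gam[j], dlp = 0.0;
        for (int i = 0; i < I; ++i) {
          if (n(i, j) <= 0) continue;
          double e0 = eta(i, j), e1 = e0 + d;
          dlp += Y(i, j) * d - n(i, j) * (lse1p(e1) - lse1p(e0));
        }
        if (j > 0) {
          double a = prop - gam[j - 1], b = gam[j] - gam[j - 1];
          dlp += -0.5 * tau_gamma * (a * a - b * b);
        }
        if (j < J - 1) {
          double a = gam[j + 1] - prop, b = gam[j + 1] - gam[j];
          dlp += -0.5 * tau_gamma * (a * a - b * b);
        }
        ++tot[2]; ++tot_win[2];
        if (std::log(R::unif_rand()) < dlp) {
          gam[j] = prop; ++acc[2]; ++acc_win[2];
          for (int i = 0; i < I; ++i) eta(i, j) += d;
        }
      }
      double mbar = 0.0;
      for (int j = 0; j < J; ++j) mbar += gam[j];
      mbar /= J;
      for (int j = 0; j < J; ++j) gam[j] -= mbar;
      alpha += mbar;
    }

    // --- nu sweep (iid, conditionally independent cells) ---
    if (use_nu) {
      for (int i = 0; i < I; ++i)
        for (int j = 0; j < J; ++j) {
          double prop = nu(i, j) + R::norm_rand() * prop_sd[3];
          double d = prop - nu(i, j), dlp = 0.0;
          if (n(i, j) > 0) {
            double e0 = eta(i, j), e1 = e0 + d;
            dlp += Y(i, j) * d - n(i, j) * (lse1p(e1) - lse1p(e0));
          }
          dlp += -0.5 * tau_nu * (prop * prop - nu(i, j) * nu(i, j));
          ++tot[3]; ++tot_win[3];
          if (std::log(R::unif_rand()) < dlp) {
            nu(i, j) = prop; ++acc[3]; ++acc_win[3];
            eta(i, j) += d;
          }
        }
    }

    // --- conjugate precision updates ---
    if (use_phi) {
      double q = 0.0;
      for (int i = 0; i < I; ++i) {
        const int m = nbr[i].size();
        if (m == 0) { q += phi[i] * phi[i]; continue; }
        for (int k = 0; k < m; ++k) {
          int j2 = nbr[i][k];
          if (j2 > i) { double dd = phi[i] - phi[j2]; q += dd * dd; }
        }
      }
      tau_phi = R::rgamma(hyper_shape + 0.5 * rank_phi,
                          1.0 / (hyper_rate + 0.5 * q));
    }
    if (use_gamma) {
      double q = 0.0;
      for (int j = 1; j < J; ++j) {
        double dd = gam[j] - gam[j - 1]; q += dd * dd;
      }
      tau_gamma = R::rgamma(hyper_shape + 0.5 * (J - 1),
                            1.0 / (hyper_rate + 0.5 * q));
    }
    if (use_nu) {
      double q = 0.0;
      for (int i = 0; i < I; ++i)
        for (int j = 0; j < J; ++j) q += nu(i, j) * nu(i, j);
      tau_nu = R::rgamma(hyper_shape + 0.5 * I * J,
                         1.0 / (hyper_rate + 0.5 * q));
    }

    // --- joint scale moves: (tau, u) -> (c*tau, u/sqrt(c)) ---
    // keeps u*sqrt(tau) fixed so the precision can traverse scales even
    // when the effects are pinned; acceptance factor is
    // c^(a + (r - K)/2) * exp(-b*tau*(c-1)) * likelihood ratio, with r
    // the prior rank, K the block dimension, (a, b) the Gamma hyperprior.
    if (use_nu) {
      double c = std::exp(0.6 * R::norm_rand());
      double s = 1.0 / std::sqrt(c);
      double dlp = 0.0;
      for (int i = 0; i < I; ++i)
        for (int j = 0; j < J; ++j) {
          if (n(i, j) <= 0) continue;
          double e0 = eta(i, j), e1 = e0 + nu(i, j) * (s - 1.0);
          dlp += Y(i, j) * (e1 - e0) - n(i, j) * (lse1p(e1) - lse1p(e0));
        }
      // r = K = I*J for the iid block, so the rank/dimension term vanishes
      dlp += hyper_shape * std::log(c) - hyper_rate * tau_nu * (c - 1.0);
      if (std::log(R::unif_rand()) < dlp) {
        for (int i = 0; i < I; ++i)
          for (int j = 0; j < J; ++j) {
            eta(i, j) += nu(i, j) * (s - 1.0);
            nu(i, j) *= s;
          }
        tau_nu *= c;
      }
    }
    if (use_phi) {
      double c = std::exp(0.6 * R::norm_rand());
      double s = 1.0 / std::sqrt(c);
      double dlp = 0.0;
      for (int i = 0; i < I; ++i) {
        double de = phi[i] * (s - 1.0);
        for (int j = 0; j < J; ++j) {
          if (n(i, j) <= 0) continue;
          double e0 = eta(i, j), e1 = e0 + de;
          dlp += Y(i, j) * de - n(i, j) * (lse1p(e1) - lse1p(e0));
        }
      }
      dlp += (hyper_shape + 0.5 * (rank_phi - I)) * std::log(c) -
             hyper_rate * tau_phi * (c - 1.0);
      if (std::log(R::unif_rand()) < dlp) {
        for (int i = 0; i < I; ++i) {
          double de = phi[i] * (s - 1.0);
          for (int j = 0; j < J; ++j) eta(i, j) += de;
          phi[i] *= s;
        }
        tau_phi *= c;
      }
    }
    if (use_gamma) {
      double c = std::exp(0.6 * R::norm_rand());
      double s = 1.0 / std::sqrt(c);
      double dlp = 0.0;
      for (int j = 0; j < J; ++j) {
        double de = gam[j] * (s - 1.0);
        for (int i = 0; i < I; ++i) {
          if (n(i, j) <= 0) continue;
          double e0 = eta(i, j), e1 = e0 + de;
          dlp += Y(i, j) * de - n(i, j) * (lse1p(e1) - lse1p(e0));
        }
      }
      dlp += (hyper_shape + 0.5 * ((J - 1) - J)) * std::log(c) -
             hyper_rate * tau_gamma * (c - 1.0);
      if (std::log(R::unif_rand()) < dlp) {
        for (int j = 0; j < J; ++j) {
          double de = gam[j] * (s - 1.0);
          for (int i = 0; i < I; ++i) eta(i, j) += de;
          gam[j] *= s;
        }
        tau_gamma *= c;
      }
    }

    // --- proposal adaptation (burn-in only) ---
    if (adapt && it % 50 == 0) {
      for (int b = 0; b < 4; ++b) {
        if (tot_win[b] == 0) continue;
        double r = (double)acc_win[b] / (double)tot_win[b];
        prop_sd[b] *= std::exp(0.5 * (r - 0.44));
        if (prop_sd[b] < 1e-4) prop_sd[b] = 1e-4;
        if (prop_sd[b] > 5.0) prop_sd[b] = 5.0;
        acc_win[b] = 0; tot_win[b] = 0;
      }
    }

    if (save_draws && it % thin == 0) {
      for (int i = 0; i < I; ++i)
        for (int j = 0; j < J; ++j)
          pi_draws(save_k, j * I + i) = 1.0 / (1.0 + std::exp(-eta(i, j)));
      alpha_draws[save_k] = alpha;
      tphi_draws[save_k] = tau_phi;
      tgam_draws[save_k] = tau_gamma;
      tnu_draws[save_k] = tau_nu;
      ++save_k;
    }
  }

  NumericVector acc_rate(4);
  for (int b = 0; b < 4; ++b)
    acc_rate[b] = tot[b] > 0 ? (double)acc[b] / (double)tot[b] : NA_REAL;

  return List::create(
    _["pi"] = pi_draws, _["alpha"] = alpha_draws,
    _["tau_phi"] = tphi_draws, _["tau_gamma"] = tgam_draws,
    _["tau_nu"] = tnu_draws,
    _["state"] = List::create(
      _["alpha"] = alpha, _["phi"] = phi, _["gamma"] = gam, _["nu"] = nu,
      _["tau_phi"] = tau_phi, _["tau_gamma"] = tau_gamma,
      _["tau_nu"] = tau_nu),
    _["prop_sd"] = prop_sd, _["acc_rate"] = acc_rate);
}
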
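#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the hierarchical multi-species
// occupancy model with latent-state augmentation.
//
//   logit(p_ijk)   = Xdet_i  %*% alpha_k      (detection; constant over j)
//   logit(psi_ik)  = Xocc_i  %*% beta_k       (occupancy)
//   z_ik  ~ Bern(psi_ik);  y_ijk ~ Bern(z_ik * p_ijk)
//   alpha_qk ~ N(mu_det_q,  sigma_det_q^2)    (community random effects)
//   beta_pk  ~ N(mu_occ_p,  sigma_occ_p^2)
//   mu ~ N(0, mu_prior_var);  sigma ~ half-Normal(scale sigma_scale)
//
// Detection covariates are site-level, so the per-site sufficient
// statistics are the detection count sumy_ik and occasion count nocc_i.
// z has a closed-form full conditional; species coefficients move by
// per-parameter adaptive random-walk Metropolis; community means get a
// conjugate draw plus an interweaving "shift" move (mean and all species
// deviations translated together) and the sds an interweaving "rescale"
// move, both run every iteration; community sds also move by random walk
// on the log scale.  log(p) and log(1-p) caches avoid recomputing the
// accepted state's likelihood, proposal buffers avoid recomputing the
// proposed state's on acceptance, and log(sigma(eta)) / log(1-sigma(eta))
// are always derived from a single exponential.

static inline double log_plogis(double eta) {
  // log(1/(1+exp(-eta))) computed stably
  return eta > 0 ? -log1p(std::exp(-eta)) : eta - log1p(std::exp(eta));
}

static inline void log_plogis_pair(double eta, double &l1, double &l0) {
  // log(sigma(eta)) and log(1 - sigma(eta)) from one exponential
  if (eta > 0) {
    double t = log1p(std::exp(-eta));
    l1 = -t;
    l0 = -eta - t;
  } else {
    double t = log1p(std::exp(eta));
    l1 = eta - t;
    l0 = -t;
  }
}

struct Caches {
  // per site x species: linear predictors and their log-probabilities
  NumericMatrix eta_det, eta_occ, ld1, ld0, lo1, lo0;
  Caches(int M, int K)
      : eta_det(M, K), eta_occ(M, K), ld1(M, K), ld0(M, K), lo1(M, K),
        lo0(M, K) {}
  void refresh_det(int i, int k) {
    log_plogis_pair(eta_det(i, k), ld1(i, k), ld0(i, k));
  }
  void refresh_occ(int i, int k) {
    log_plogis_pair(eta_occ(i, k), lo1(i, k), lo0(i, k));
  }
};

// [[Rcpp::export]]
List occ_mcmc_cpp(IntegerMatrix sumy, IntegerMatrix anydet,
                  IntegerVector nocc,
                  NumericMatrix Xdet, NumericMatrix Xocc,
                  int n_iter, int n_burn, int thin,
                  double mu_prior_var, double sigma_scale,
                  bool fixed_hyper,
                  NumericVector mu_det_init, NumericVector sigma_det_init,
                  NumericVector mu_occ_init, NumericVector sigma_occ_init,
                  NumericMatrix alpha_init, NumericMatrix beta_init,
                  IntegerMatrix z_init,
                  bool save_z) {
  const int M = sumy.nrow(), K = sumy.ncol();
  const int Q = Xdet.ncol(), P = Xocc.ncol();
  const int n_total = n_burn + n_iter;
  const int S = n_iter / thin;

  NumericMatrix alpha(clone(alpha_init));   // Q x K
  NumericMatrix beta(clone(beta_init));     // P x K
  IntegerMatrix z(clone(z_init));           // M x K
  NumericVector mu_det(clone(mu_det_init)), sigma_det(clone(sigma_det_init));
  NumericVector mu_occ(clone(mu_occ_init)), sigma_occ(clone(sigma_occ_init));

  Caches ch(M, K);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < M; ++i) {
      double ed = 0.0, eo = 0.0;
      for (int q = 0; q < Q; ++q) ed += Xdet(i, q) * alpha(q, k);
      for (int p = 0; p < P; ++p) eo += Xocc(i, p) * beta(p, k);
      ch.eta_det(i, k) = ed;
      ch.eta_occ(i, k) = eo;
      ch.refresh_det(i, k);
      ch.refresh_occ(i, k);
    }

  // proposal buffers: per-species (length M) and per-family (length M*K)
  std::vector<double> be(M), bl1(M), bl0(M);
  std::vector<double> Fe((size_t)M * K), F1((size_t)M * K),
      F0((size_t)M * K);

  // adaptive proposal scales (log scale) and acceptance tallies
  NumericMatrix ls_alpha(Q, K), ls_beta(P, K);
  std::fill(ls_alpha.begin(), ls_alpha.end(), std::log(0.4));
  std::fill(ls_beta.begin(), ls_beta.end(), std::log(0.4));
  IntegerMatrix acc_alpha(Q, K), acc_beta(P, K);
  NumericVector ls_sd(Q + P, std::log(0.3)), ls_shift(Q + P, std::log(0.1)),
      ls_scale(Q + P, std::log(0.1));
  IntegerVector acc_sd(Q + P), acc_shift(Q + P), acc_scale(Q + P);
  const int batch = 50;
  int n_batch = 0;

  const int n_par = (Q + P) * K + 2 * (Q + P);
  NumericMatrix par_draws(S, n_par);
  IntegerMatrix richness(S, M);
  NumericMatrix z_sum(M, K);
  IntegerVector z_draws(save_z ? (size_t)S * M * K : (size_t)0);
  long long acc_a_total = 0, acc_b_total = 0,
            try_a_total = 0, try_b_total = 0;

  const int *nocc_p = INTEGER(nocc);

  int stored = 0;
  for (int t = 1; t <= n_total; ++t) {

    // --- latent occupancy states -------------------------------------
    for (int k = 0; k < K; ++k) {
      int *zk = &z(0, k);
      const int *ak = &anydet(0, k);
      const double *lo1k = &ch.lo1(0, k), *lo0k = &ch.lo0(0, k);
      const double *ld0k = &ch.ld0(0, k);
      for (int i = 0; i < M; ++i) {
        if (ak[i]) { zk[i] = 1; continue; }
        // P(z=1 | no detections) on the log scale
        double l_occ_nodet = lo1k[i] + nocc_p[i] * ld0k[i];
        double pz = 1.0 / (1.0 + std::exp(lo0k[i] - l_occ_nodet));
        zk[i] = (unif_rand() < pz) ? 1 : 0;
      }
    }

    // --- species detection coefficients ------------------------------
    for (int k = 0; k < K; ++k) {
      const int *zk = &z(0, k), *syk = &sumy(0, k);
      double *edk = &ch.eta_det(0, k);
      double *l1k = &ch.ld1(0, k), *l0k = &ch.ld0(0, k);
      for (int q = 0; q < Q; ++q) {
        const double *xq = &Xdet(0, q);
        double cur = alpha(q, k);
        double prop = cur + std::exp(ls_alpha(q, k)) * norm_rand();
        double d = prop - cur;
        double dll = 0.0;
        // only occupied sites with a nonzero covariate value contribute
        // to the ratio (indicator columns are zero at most sites)
        for (int i = 0; i < M; ++i) {
          if (!zk[i] || xq[i] == 0.0) continue;
          double e1 = edk[i] + d * xq[i], p1, p0;
          log_plogis_pair(e1, p1, p0);
          dll += syk[i] * (p1 - l1k[i]) +
                 (nocc_p[i] - syk[i]) * (p0 - l0k[i]);
          be[i] = e1; bl1[i] = p1; bl0[i] = p0;
        }
        double sd2 = sigma_det[q] * sigma_det[q];
        dll += (-(prop - mu_det[q]) * (prop - mu_det[q]) +
                (cur - mu_det[q]) * (cur - mu_det[q])) / (2.0 * sd2);
        ++try_a_total;
        if (std::log(unif_rand()) < dll) {
          alpha(q, k) = prop;
          for (int i = 0; i < M; ++i) {
            if (xq[i] == 0.0) continue;
            if (zk[i]) {
              edk[i] = be[i]; l1k[i] = bl1[i]; l0k[i] = bl0[i];
            } else {
              edk[i] += d * xq[i];
              log_plogis_pair(edk[i], l1k[i], l0k[i]);
            }
          }
          ++acc_alpha(q, k);
          ++acc_a_total;
        }
      }
    }

    // --- species occupancy coefficients ------------------------------
    for (int k = 0; k < K; ++k) {
      const int *zk = &z(0, k);
      double *eok = &ch.eta_occ(0, k);
      double *o1k = &ch.lo1(0, k), *o0k = &ch.lo0(0, k);
      for (int p = 0; p < P; ++p) {
        const double *xp = &Xocc(0, p);
        double cur = beta(p, k);
        double prop = cur + std::exp(ls_beta(p, k)) * norm_rand();
        double d = prop - cur;
        double dll = 0.0;
        for (int i = 0; i < M; ++i) {
          if (xp[i] == 0.0) continue;
          double e1 = eok[i] + d * xp[i], p1, p0;
          log_plogis_pair(e1, p1, p0);
          dll += zk[i] ? (p1 - o1k[i]) : (p0 - o0k[i]);
          be[i] = e1; bl1[i] = p1; bl0[i] = p0;
        }
        double sd2 = sigma_occ[p] * sigma_occ[p];
        dll += (-(prop - mu_occ[p]) * (prop - mu_occ[p]) +
                (cur - mu_occ[p]) * (cur - mu_occ[p])) / (2.0 * sd2);
        ++try_b_total;
        if (std::log(unif_rand()) < dll) {
          beta(p, k) = prop;
          for (int i = 0; i < M; ++i) {
            if (xp[i] == 0.0) continue;
            eok[i] = be[i]; o1k[i] = bl1[i]; o0k[i] = bl0[i];
          }
          ++acc_beta(p, k);
          ++acc_b_total;
        }
      }
    }

    // --- community hyperparameters ------------------------------------
    if (!fixed_hyper) {
      for (int f = 0; f < Q + P; ++f) {
        bool det = f < Q;
        int idx = det ? f : f - Q;
        const double *xv = det ? &Xdet(0, idx) : &Xocc(0, idx);
        double sig = det ? sigma_det[idx] : sigma_occ[idx];
        double sum = 0.0;
        for (int k = 0; k < K; ++k)
          sum += det ? alpha(idx, k) : beta(idx, k);

        // conjugate normal draw for the community mean
        double prec = K / (sig * sig) + 1.0 / mu_prior_var;
        double mean = (sum / (sig * sig)) / prec;
        double mu_new = mean + norm_rand() / std::sqrt(prec);
        if (det) mu_det[idx] = mu_new; else mu_occ[idx] = mu_new;

        // interweaving shift: translate the mean and every species
        // coefficient together; species deviations (hence the random-effect
        // density) are unchanged, so only the data likelihood and the
        // hyperprior on the mean enter the ratio
        double d = std::exp(ls_shift[f]) * norm_rand();
        double dll = 0.0;
        if (det) {
          for (int k = 0; k < K; ++k) {
            const int *zk = &z(0, k), *syk = &sumy(0, k);
            const double *edk = &ch.eta_det(0, k);
            const double *l1k = &ch.ld1(0, k), *l0k = &ch.ld0(0, k);
            double *fe = &Fe[(size_t)k * M], *f1 = &F1[(size_t)k * M],
                   *f0 = &F0[(size_t)k * M];
            for (int i = 0; i < M; ++i) {
              if (!zk[i] || xv[i] == 0.0) continue;
              double e1 = edk[i] + d * xv[i], p1, p0;
              log_plogis_pair(e1, p1, p0);
              dll += syk[i] * (p1 - l1k[i]) +
                     (nocc_p[i] - syk[i]) * (p0 - l0k[i]);
              fe[i] = e1; f1[i] = p1; f0[i] = p0;
            }
          }
        } else {
          for (int k = 0; k < K; ++k) {
            const int *zk = &z(0, k);
            const double *eok = &ch.eta_occ(0, k);
            const double *o1k = &ch.lo1(0, k), *o0k = &ch.lo0(0, k);
            double *fe = &Fe[(size_t)k * M], *f1 = &F1[(size_t)k * M],
                   *f0 = &F0[(size_t)k * M];
            for (int i = 0; i < M; ++i) {
              if (xv[i] == 0.0) continue;
              double e1 = eok[i] + d * xv[i], p1, p0;
              log_plogis_pair(e1, p1, p0);
              dll += zk[i] ? (p1 - o1k[i]) : (p0 - o0k[i]);
              fe[i] = e1; f1[i] = p1; f0[i] = p0;
            }
          }
        }
        double mu_cur = det ? mu_det[idx] : mu_occ[idx];
        dll += (-(mu_cur + d) * (mu_cur + d) + mu_cur * mu_cur) /
               (2.0 * mu_prior_var);
        if (std::log(unif_rand()) < dll) {
          if (det) {
            mu_det[idx] += d;
            for (int k = 0; k < K; ++k) {
              alpha(idx, k) += d;
              const int *zk = &z(0, k);
              double *edk = &ch.eta_det(0, k);
              double *l1k = &ch.ld1(0, k), *l0k = &ch.ld0(0, k);
              const double *fe = &Fe[(size_t)k * M],
                           *f1 = &F1[(size_t)k * M],
                           *f0 = &F0[(size_t)k * M];
              for (int i = 0; i < M; ++i) {
                if (xv[i] == 0.0) continue;
                if (zk[i]) {
                  edk[i] = fe[i]; l1k[i] = f1[i]; l0k[i] = f0[i];
                } else {
                  edk[i] += d * xv[i];
                  log_plogis_pair(edk[i], l1k[i], l0k[i]);
                }
              }
            }
          } else {
            mu_occ[idx] += d;
            for (int k = 0; k < K; ++k) {
              beta(idx, k) += d;
              double *eok = &ch.eta_occ(0, k);
              double *o1k = &ch.lo1(0, k), *o0k = &ch.lo0(0, k);
              const double *fe = &Fe[(size_t)k * M],
                           *f1 = &F1[(size_t)k * M],
                           *f0 = &F0[(size_t)k * M];
              for (int i = 0; i < M; ++i) {
                if (xv[i] == 0.0) continue;
                eok[i] = fe[i]; o1k[i] = f1[i]; o0k[i] = f0[i];
              }
            }
          }
          ++acc_shift[f];
        }

        // interweaving rescale: multiply the community sd and every species
        // deviation from the mean by a common factor c = exp(d).  In
        // non-centred coordinates the standardized deviations are held
        // fixed, so the random-effect densities cancel up to a factor 1/c^K
        // which, with the c^(K+1) Jacobian of the map, leaves
        // likelihood ratio + half-normal prior ratio + log c.
        {
          double mu_now = det ? mu_det[idx] : mu_occ[idx];
          double sig_now = det ? sigma_det[idx] : sigma_occ[idx];
          double ds = std::exp(ls_scale[f]) * norm_rand();
          double c_fac = std::exp(ds);
          double sig_new = sig_now * c_fac;
          if (sig_new > 1e-4 && sig_new < 1e4) {
            double dll2 = 0.0;
            if (det) {
              for (int k = 0; k < K; ++k) {
                double dk = (alpha(idx, k) - mu_now) * (c_fac - 1.0);
                const int *zk = &z(0, k), *syk = &sumy(0, k);
                const double *edk = &ch.eta_det(0, k);
                const double *l1k = &ch.ld1(0, k), *l0k = &ch.ld0(0, k);
                double *fe = &Fe[(size_t)k * M], *f1 = &F1[(size_t)k * M],
                       *f0 = &F0[(size_t)k * M];
                for (int i = 0; i < M; ++i) {
                  if (!zk[i] || xv[i] == 0.0) continue;
                  double e1 = edk[i] + dk * xv[i], p1, p0;
                  log_plogis_pair(e1, p1, p0);
                  dll2 += syk[i] * (p1 - l1k[i]) +
                          (nocc_p[i] - syk[i]) * (p0 - l0k[i]);
                  fe[i] = e1; f1[i] = p1; f0[i] = p0;
                }
              }
            } else {
              for (int k = 0; k < K; ++k) {
                double dk = (beta(idx, k) - mu_now) * (c_fac - 1.0);
                const int *zk = &z(0, k);
                const double *eok = &ch.eta_occ(0, k);
                const double *o1k = &ch.lo1(0, k), *o0k = &ch.lo0(0, k);
                double *fe = &Fe[(size_t)k * M], *f1 = &F1[(size_t)k * M],
                       *f0 = &F0[(size_t)k * M];
                for (int i = 0; i < M; ++i) {
                  if (xv[i] == 0.0) continue;
                  double e1 = eok[i] + dk * xv[i], p1, p0;
                  log_plogis_pair(e1, p1, p0);
                  dll2 += zk[i] ? (p1 - o1k[i]) : (p0 - o0k[i]);
                  fe[i] = e1; f1[i] = p1; f0[i] = p0;
                }
              }
            }
            dll2 += (sig_now * sig_now - sig_new * sig_new) /
                        (2.0 * sigma_scale * sigma_scale) +
                    ds;
            if (std::log(unif_rand()) < dll2) {
              if (det) {
                sigma_det[idx] = sig_new;
                for (int k = 0; k < K; ++k) {
                  double dk = (alpha(idx, k) - mu_now) * (c_fac - 1.0);
                  alpha(idx, k) += dk;
                  const int *zk = &z(0, k);
                  double *edk = &ch.eta_det(0, k);
                  double *l1k = &ch.ld1(0, k), *l0k = &ch.ld0(0, k);
                  const double *fe = &Fe[(size_t)k * M],
                               *f1 = &F1[(size_t)k * M],
                               *f0 = &F0[(size_t)k * M];
                  for (int i = 0; i < M; ++i) {
                    if (xv[i] == 0.0) continue;
                    if (zk[i]) {
                      edk[i] = fe[i]; l1k[i] = f1[i]; l0k[i] = f0[i];
                    } else {
                      edk[i] += dk * xv[i];
                      log_plogis_pair(edk[i], l1k[i], l0k[i]);
                    }
                  }
                }
              } else {
                sigma_occ[idx] = sig_new;
                for (int k = 0; k < K; ++k) {
                  double dk = (beta(idx, k) - mu_now) * (c_fac - 1.0);
                  beta(idx, k) += dk;
                  double *eok = &ch.eta_occ(0, k);
                  double *o1k = &ch.lo1(0, k), *o0k = &ch.lo0(0, k);
                  const double *fe = &Fe[(size_t)k * M],
                               *f1 = &F1[(size_t)k * M],
                               *f0 = &F0[(size_t)k * M];
                  for (int i = 0; i < M; ++i) {
                    if (xv[i] == 0.0) continue;
                    eok[i] = fe[i]; o1k[i] = f1[i]; o0k[i] = f0[i];
                  }
                }
              }
              ++acc_scale[f];
            }
          }
        }

        // log random walk for the community sd, half-normal prior
        double mu_now = det ? mu_det[idx] : mu_occ[idx];
        sig = det ? sigma_det[idx] : sigma_occ[idx];
        double ss = 0.0;
        for (int k = 0; k < K; ++k) {
          double v = (det ? alpha(idx, k) : beta(idx, k)) - mu_now;
          ss += v * v;
        }
        double lcur = std::log(sig);
        double lprop = lcur + std::exp(ls_sd[f]) * norm_rand();
        double sprop = std::exp(lprop);
        if (sprop > 1e-4 && sprop < 1e4) {
          double lt_cur = -K * lcur - ss / (2.0 * sig * sig) -
                          sig * sig / (2.0 * sigma_scale * sigma_scale) +
                          lcur;
          double lt_prop = -K * lprop - ss / (2.0 * sprop * sprop) -
                           sprop * sprop /
                               (2.0 * sigma_scale * sigma_scale) +
                           lprop;
          if (std::log(unif_rand()) < lt_prop - lt_cur) {
            if (det) sigma_det[idx] = sprop; else sigma_occ[idx] = sprop;
            ++acc_sd[f];
          }
        }
      }
    }

    // --- proposal adaptation during burn-in ---------------------------
    if (t <= n_burn && t % batch == 0) {
      ++n_batch;
      double delta = std::min(0.05, 1.0 / std::sqrt((double)n_batch)) * 2.0;
      for (int k = 0; k < K; ++k) {
        for (int q = 0; q < Q; ++q) {
          double rate = acc_alpha(q, k) / (double)batch;
          ls_alpha(q, k) += (rate > 0.44 ? delta :
                             (rate < 0.23 ? -delta : 0.0));
          acc_alpha(q, k) = 0;
        }
        for (int p = 0; p < P; ++p) {
          double rate = acc_beta(p, k) / (double)batch;
          ls_beta(p, k) += (rate > 0.44 ? delta :
                            (rate < 0.23 ? -delta : 0.0));
          acc_beta(p, k) = 0;
        }
      }
      for (int f = 0; f < Q + P; ++f) {
        double r1 = acc_sd[f] / (double)batch;
        ls_sd[f] += (r1 > 0.44 ? delta : (r1 < 0.23 ? -delta : 0.0));
        acc_sd[f] = 0;
        double r2 = acc_shift[f] / (double)batch;
        ls_shift[f] += (r2 > 0.44 ? delta : (r2 < 0.23 ? -delta : 0.0));
        acc_shift[f] = 0;
        double r3 = acc_scale[f] / (double)batch;
        ls_scale[f] += (r3 > 0.44 ? delta : (r3 < 0.23 ? -delta : 0.0));
        acc_scale[f] = 0;
      }
      acc_a_total = acc_b_total = try_a_total = try_b_total = 0;
    }

    // --- storage -------------------------------------------------------
    if (t > n_burn && (t - n_burn) % thin == 0) {
      int s = stored++;
      int c = 0;
      for (int k = 0; k < K; ++k)
        for (int q = 0; q < Q; ++q) par_draws(s, c++) = alpha(q, k);
      for (int k = 0; k < K; ++k)
        for (int p = 0; p < P; ++p) par_draws(s, c++) = beta(p, k);
      for (int q = 0; q < Q; ++q) par_draws(s, c++) = mu_det[q];
      for (int p = 0; p < P; ++p) par_draws(s, c++) = mu_occ[p];
      for (int q = 0; q < Q; ++q) par_draws(s, c++) = sigma_det[q];
      for (int p = 0; p < P; ++p) par_draws(s, c++) = sigma_occ[p];
      for (int i = 0; i < M; ++i) {
        int r = 0;
        for (int k = 0; k < K; ++k) {
          r += z(i, k);
          z_sum(i, k) += z(i, k);
          if (save_z)
            z_draws[(size_t)s * M * K + (size_t)k * M + i] = z(i, k);
        }
        richness(s, i) = r;
      }
    }
  }

  for (int k = 0; k < K; ++k)
    for (int i = 0; i < M; ++i) z_sum(i, k) /= (double)S;

  double acc_a = try_a_total ? acc_a_total / (double)try_a_total : NA_REAL;
  double acc_b = try_b_total ? acc_b_total / (double)try_b_total : NA_REAL;

  List out = List::create(
      _["par_draws"] = par_draws, _["richness"] = richness,
      _["z_mean"] = z_sum, _["accept_det"] = acc_a, _["accept_occ"] = acc_b);
  if (save_z) {
    z_draws.attr("dim") = IntegerVector::create(M, K, S);
    out["z_draws"] = z_draws;
  }
  return out;
}
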
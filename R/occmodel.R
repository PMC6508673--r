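#' Standardize a covariate
#'
#' Subtracts the mean and divides by the sample standard deviation (n - 1
#' denominator).  The constants are kept as attributes so raster predictions
#' can be placed on the survey-site scale.
#'
#' @param x Numeric vector with positive variance.
#' @return Standardized numeric vector with attributes `center` and `scale`.
#' @export
standardize <- function(x) {
  if (anyNA(x)) abort("missing values are not allowed.")
  s <- sd(x)
  if (s == 0) abort("cannot standardize a zero-variance vector.")
  m <- mean(x)
  structure((x - m) / s, center = m, scale = s)
}

#' Invert a standardization
#' @param x Standardized values.
#' @param center,scale Constants from [standardize()] (taken from `x`'s
#'   attributes when omitted).
#' @return Values on the original scale.
#' @export
unstandardize <- function(x, center = attr(x, "center"),
                          scale = attr(x, "scale")) {
  as.numeric(x) * scale + center
}

## long detection tibble -> per-site/species sufficient statistics
## (detection covariates are site-level, so counts suffice)
detection_stats <- function(y, design) {
  stopifnot(all(c("site", "occasion", "species", "detected") %in% names(y)))
  if (anyNA(y$detected) || !all(y$detected %in% c(0, 1))) {
    abort("`detected` must be binary with no missing values.")
  }
  sites <- design$site
  species <- sort(unique(y$species))
  M <- length(sites)
  K <- length(species)
  i <- match(y$site, sites)
  k <- match(y$species, species)
  if (anyNA(i)) abort("detection data contain sites absent from the design.")
  sumy <- matrix(0L, M, K)
  tab <- tapply(y$detected, list(factor(i, seq_len(M)),
                                 factor(k, seq_len(K))), sum)
  tab[is.na(tab)] <- 0L
  sumy[] <- as.integer(tab)
  nocc_obs <- tapply(y$occasion, list(factor(i, seq_len(M)),
                                      factor(k, seq_len(K))),
                     function(o) length(unique(o)))
  nocc <- as.integer(design$n_occasions)
  list(sumy = sumy, anydet = (sumy > 0) * 1L, nocc = nocc,
       species = species, sites = sites)
}

## design matrices for the sampler; returns Xdet, Xocc and coefficient names
model_matrices <- function(design,
                           occ_covariates = c("dens_mid_std",
                                              "dens_canopy_std", "burned"),
                           det_route = TRUE) {
  M <- nrow(design)
  Xdet <- matrix(1, M, 1, dimnames = list(NULL, "a0"))
  if (det_route) {
    Xdet <- cbind(Xdet,
                  a_route_a = as.numeric(design$route == "route_a"),
                  a_route_b = as.numeric(design$route == "route_b"))
  }
  occ_names <- c("b0", vapply(occ_covariates, function(v) {
    switch(v,
           dens_mid_std = "b_mid",
           dens_canopy_std = "b_canopy",
           burned = "b_burned",
           paste0("b_", v))
  }, character(1)))
  Xocc <- cbind(1, as.matrix(design[, occ_covariates, drop = FALSE]))
  colnames(Xocc) <- occ_names
  list(Xdet = Xdet, Xocc = Xocc)
}

#' Marginal log-likelihood of the multi-species occupancy model
#'
#' Evaluates the model likelihood with the latent occupancy states summed
#' out: for each site and species the contribution is
#' psi * prod_j p^y (1-p)^(1-y)  +  (1 - psi) * I(no detections),
#' over the site's observed occasions only, accumulated in log space.
#'
#' @param params A `community_params` tibble of species coefficients.
#' @param y Long-format `detection_data`.
#' @param design A `site_design`.
#' @return The log-likelihood (scalar).
#' @export
loglik_marginal <- function(params, y, design) {
  stats_ <- detection_stats(y, design)
  if (length(stats_$species) != nrow(params)) {
    abort("dimension mismatch between params and detection data.")
  }
  lp <- linear_predictors(params, design)
  log_p <- log(lp$p)
  log_q <- log1p(-lp$p)
  nocc <- matrix(stats_$nocc, nrow(design), nrow(params))
  det_ll <- stats_$sumy * log_p + (nocc - stats_$sumy) * log_q
  log_psi <- log(lp$psi)
  log_1mpsi <- log1p(-lp$psi)
  occupied <- log_psi + det_ll
  cellwise <- ifelse(stats_$anydet == 1L,
                     occupied,
                     log_add_exp(occupied, log_1mpsi))
  sum(cellwise)
}

#' Full conditional probability of occupancy given a detection history
#'
#' For one site and species: the posterior probability that the latent
#' occupancy state is 1 given occupancy probability `psi`, per-occasion
#' detection probabilities `p`, and the observed history `y`.  Any detection
#' implies presence; otherwise the probability is
#' psi * prod(1 - p) / (psi * prod(1 - p) + 1 - psi).
#'
#' @param psi Occupancy probability.
#' @param p Detection probability, scalar or one per occasion.
#' @param y Binary detection history over observed occasions.
#' @return Probability in \[0, 1\].
#' @export
full_conditional_z <- function(psi, p, y) {
  if (any(y == 1)) return(1)
  p <- rep_len(p, length(y))
  q <- prod(1 - p)
  psi * q / (psi * q + 1 - psi)
}

#' Fit the hierarchical multi-species occupancy model by MCMC
#'
#' Samples the joint posterior of the community occupancy model: latent
#' occupancy states from their closed-form full conditional, species-level
#' coefficients by per-parameter adaptive random-walk Metropolis on the
#' state-augmented Bernoulli likelihood, community means by conjugate normal
#' updates, and community standard deviations by a random walk on the log
#' scale.  Community means have Normal(0, variance 1000) hyperpriors;
#' community sds have a half-normal prior with scale `sigma_scale`.
#' Proposal scales adapt during burn-in toward a 20--40% acceptance rate.
#'
#' @param y Long-format `detection_data` (`site`, `occasion`, `species`,
#'   `detected`).
#' @param design A `site_design` with standardized covariates.
#' @param occ_covariates Occupancy covariate columns of `design`
#'   (default: standardized midstory density, standardized canopy density,
#'   burned flag).  Use `character()` for an intercept-only model.
#' @param det_route Include the two observer-route contrasts on detection.
#' @param chains,n_iter,n_burn,thin Sampler settings; `n_iter` is the total
#'   chain length including burn-in, so `(n_iter - n_burn) / thin` draws are
#'   retained per chain.  Defaults: 3 chains of 20000 iterations with 5000
#'   burn-in, thinned to every 5th.
#' @param seed Integer seed; chain c uses seed + c - 1, so runs are
#'   reproducible per (seed, chain).
#' @param sigma_scale Half-normal scale of the community-sd prior.
#' @param mu_prior_var Variance of the normal hyperprior on community means.
#' @param hyper_fixed Optionally a list with numeric vectors `mean` and `sd`
#'   (recycled over coefficient families) that pins the community
#'   distribution, turning the species-coefficient priors into fixed
#'   normals; used for non-hierarchical (e.g. single-species) fits.
#' @param save_z Keep the full binary draws of the latent states (an
#'   M x K x draws array per chain; memory-hungry for large fits).  Site
#'   richness draws and posterior z means are always kept.
#' @return An `occu_fit` object: per-chain parameter draw matrices with
#'   named columns (`a0[k]`, `b_mid[k]`, ..., `mu_*`, `sigma_*`), richness
#'   draws, posterior z means, acceptance rates, and the sampler settings.
#' @export
sample_posterior <- function(y, design,
                             occ_covariates = c("dens_mid_std",
                                                "dens_canopy_std", "burned"),
                             det_route = TRUE,
                             chains = 3, n_iter = 20000, n_burn = 5000,
                             thin = 5, seed = 1,
                             sigma_scale = 2.25, mu_prior_var = 1000,
                             hyper_fixed = NULL, save_z = FALSE) {
  stopifnot(inherits(design, "site_design") || is.data.frame(design))
  check_seed(seed)
  chains <- check_count(chains, "chains")
  if (n_burn >= n_iter) abort("`n_burn` must be smaller than `n_iter`.")
  stats_ <- detection_stats(y, design)
  mm <- model_matrices(design, occ_covariates, det_route)
  M <- nrow(design)
  K <- length(stats_$species)
  Q <- ncol(mm$Xdet)
  P <- ncol(mm$Xocc)

  fixed <- !is.null(hyper_fixed)
  mu0 <- rep(0, Q + P)
  sd0 <- rep(1, Q + P)
  if (fixed) {
    mu0 <- rep_len(hyper_fixed$mean, Q + P)
    sd0 <- rep_len(hyper_fixed$sd, Q + P)
  }

  par_names <- c(
    paste0(rep(colnames(mm$Xdet), K), "[",
           rep(stats_$species, each = Q), "]"),
    paste0(rep(colnames(mm$Xocc), K), "[",
           rep(stats_$species, each = P), "]"),
    paste0("mu_", c(colnames(mm$Xdet), colnames(mm$Xocc))),
    paste0("sigma_", c(colnames(mm$Xdet), colnames(mm$Xocc)))
  )

  run_chain <- function(chain) {
    set.seed(seed + chain - 1L)
    ## z starts at 1 wherever the species was detected, random elsewhere
    z0 <- stats_$anydet
    z0[z0 == 0L] <- rbinom(sum(z0 == 0L), 1L, 0.5)
    alpha0 <- matrix(rnorm(Q * K, mu0[seq_len(Q)], 0.25), Q, K)
    beta0 <- matrix(rnorm(P * K, mu0[Q + seq_len(P)], 0.25), P, K)
    res <- occ_mcmc_cpp(
      stats_$sumy, stats_$anydet, stats_$nocc,
      mm$Xdet, mm$Xocc,
      as.integer(n_iter - n_burn), as.integer(n_burn), as.integer(thin),
      mu_prior_var, sigma_scale, fixed,
      mu0[seq_len(Q)], sd0[seq_len(Q)],
      mu0[Q + seq_len(P)], sd0[Q + seq_len(P)],
      alpha0, beta0, z0, save_z
    )
    colnames(res$par_draws) <- par_names
    res
  }
  runs <- lapply(seq_len(chains), run_chain)

  z_mean <- Reduce(`+`, lapply(runs, `[[`, "z_mean")) / chains
  structure(
    list(
      draws = lapply(runs, `[[`, "par_draws"),
      richness = lapply(runs, `[[`, "richness"),
      z_mean = z_mean,
      z_draws = if (save_z) lapply(runs, `[[`, "z_draws") else NULL,
      accept = tibble::tibble(
        chain = seq_len(chains),
        detection = vapply(runs, `[[`, numeric(1), "accept_det"),
        occupancy = vapply(runs, `[[`, numeric(1), "accept_occ")
      ),
      species = stats_$species,
      sites = stats_$sites,
      par_names = par_names,
      settings = list(chains = chains, n_iter = n_iter, n_burn = n_burn,
                      thin = thin, seed = seed, sigma_scale = sigma_scale,
                      mu_prior_var = mu_prior_var, fixed_hyper = fixed,
                      occ_covariates = occ_covariates,
                      det_route = det_route)
    ),
    class = "occu_fit"
  )
}

#' @export
print.occu_fit <- function(x, ...) {
  s <- x$settings
  cat("Hierarchical multi-species occupancy model fit\n")
  cat(sprintf("  %d species, %d sites; %d chain(s) x %d iterations (burn-in %d, thin %d)\n",
              length(x$species), length(x$sites), s$chains, s$n_iter,
              s$n_burn, s$thin))
  cat(sprintf("  mean Metropolis acceptance: detection %.2f, occupancy %.2f\n",
              mean(x$accept$detection), mean(x$accept$occupancy)))
  invisible(x)
}

## pooled draw matrix across chains
pooled_draws <- function(fit) do.call(rbind, fit$draws)

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor computed from between- and within-chain
#' variances: with n draws per chain, W the mean within-chain variance and B
#' the between-chain variance, R-hat = sqrt(((n - 1)/n * W + B/n) / W).
#' Parameters with zero within-chain variance are reported as `NA`.
#'
#' @param x An `occu_fit`, or a numeric matrix with one column per chain.
#' @param ... Unused.
#' @return For a fit, a tibble (`term`, `rhat`); for a matrix, a single
#'   value.
#' @export
gelman_rubin <- function(x, ...) UseMethod("gelman_rubin")

rhat_one <- function(mat) {
  n <- nrow(mat)
  if (n < 2L || ncol(mat) < 2L) {
    abort("need at least 2 chains with at least 2 draws each.")
  }
  W <- mean(apply(mat, 2L, var))
  if (W == 0) return(NA_real_)
  B <- n * var(colMeans(mat))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @rdname gelman_rubin
#' @export
gelman_rubin.matrix <- function(x, ...) rhat_one(x)

#' @rdname gelman_rubin
#' @export
gelman_rubin.occu_fit <- function(x, ...) {
  if (length(x$draws) < 2L) {
    abort("need at least 2 chains with at least 2 draws each.")
  }
  vals <- vapply(seq_along(x$par_names), function(j) {
    rhat_one(vapply(x$draws, function(d) d[, j],
                    numeric(nrow(x$draws[[1]]))))
  }, numeric(1))
  tibble::tibble(term = x$par_names, rhat = vals)
}

#' Posterior summaries
#'
#' Means, standard deviations and central 95% credible intervals (equal-
#' tailed, quantiles at 2.5% and 97.5% of the pooled post-burn-in thinned
#' draws, type-7 quantile rule) for every parameter.
#'
#' @param x An `occu_fit`, or a numeric vector/matrix of draws (columns =
#'   parameters).
#' @param ... Unused.
#' @return A tibble with `term`, `mean`, `sd`, `conf.low`, `conf.high`.
#' @export
summarize_posterior <- function(x, ...) UseMethod("summarize_posterior")

#' @rdname summarize_posterior
#' @export
summarize_posterior.occu_fit <- function(x, ...) {
  summarize_posterior(pooled_draws(x))
}

#' @rdname summarize_posterior
#' @export
summarize_posterior.default <- function(x, ...) {
  m <- as.matrix(x)
  if (is.null(colnames(m))) {
    colnames(m) <- if (ncol(m) == 1L) "value" else paste0("V", seq_len(ncol(m)))
  }
  qs <- t(apply(m, 2L, quantile, probs = c(0.025, 0.975), type = 7,
                names = FALSE))
  tibble::tibble(
    term = colnames(m),
    mean = unname(colMeans(m)),
    sd = unname(apply(m, 2L, sd)),
    conf.low = unname(qs[, 1L]),
    conf.high = unname(qs[, 2L])
  )
}

#' Classify the support for species-level occupancy covariate effects
#'
#' A species' effect is *strong* when its 95% credible interval excludes
#' zero (an interval with an endpoint exactly at zero counts as including
#' it, hence weak), and its *direction* is the sign of the posterior mean.
#'
#' @param summary A posterior-summary tibble from [summarize_posterior()].
#' @param covariates Coefficient families to classify.
#' @return A `support_classification` tibble: `species`, `covariate`,
#'   `mean`, `conf.low`, `conf.high`, `direction`, `strength`.
#' @export
classify_support <- function(summary,
                             covariates = c("b_mid", "b_canopy",
                                            "b_burned")) {
  pattern <- paste0("^(", paste(covariates, collapse = "|"), ")\\[(.+)\\]$")
  rows <- grepl(pattern, summary$term)
  if (!any(rows)) abort("no species-level covariate terms found.")
  sub <- summary[rows, ]
  out <- tibble::tibble(
    species = sub(pattern, "\\2", sub$term),
    covariate = sub(pattern, "\\1", sub$term),
    mean = sub$mean,
    conf.low = sub$conf.low,
    conf.high = sub$conf.high,
    direction = ifelse(sub$mean < 0, "negative", "positive"),
    strength = ifelse(sub$conf.low > 0 | sub$conf.high < 0,
                      "strong", "weak")
  )
  suppressWarnings({
    num <- as.numeric(out$species)
    if (!anyNA(num)) out$species <- num
  })
  class(out) <- c("support_classification", class(out))
  out
}

#' Tally species by the sign and strength of their covariate responses
#'
#' For each vegetation covariate, counts the species whose posterior mean is
#' negative (more likely in saltwater-affected, structurally open forest)
#' and positive (more likely in unaffected forest), with the number of
#' strongly supported species alongside; plus union ("either covariate")
#' and intersection ("both covariates") rollups across the two vegetation
#' density covariates.
#'
#' @param classification A `support_classification`.
#' @param covariates The two vegetation covariates to tabulate.
#' @return A tibble: `covariate`, `n_negative`, `n_negative_strong`,
#'   `n_positive`, `n_positive_strong`.
#' @export
count_support_table <- function(classification,
                                covariates = c("b_mid", "b_canopy")) {
  cl <- dplyr::filter(classification, .data$covariate %in% covariates)
  per_cov <- cl |>
    dplyr::group_by(covariate = .data$covariate) |>
    dplyr::summarise(
      n_negative = sum(.data$mean < 0),
      n_negative_strong = sum(.data$mean < 0 & .data$strength == "strong"),
      n_positive = sum(.data$mean > 0),
      n_positive_strong = sum(.data$mean > 0 & .data$strength == "strong"),
      .groups = "drop"
    )
  roll <- function(label, combine) {
    by_sp <- cl |>
      dplyr::group_by(species = .data$species) |>
      dplyr::summarise(
        neg = combine(.data$mean < 0),
        neg_strong = combine(.data$mean < 0 & .data$strength == "strong"),
        pos = combine(.data$mean > 0),
        pos_strong = combine(.data$mean > 0 & .data$strength == "strong"),
        .groups = "drop"
      )
    tibble::tibble(
      covariate = label,
      n_negative = sum(by_sp$neg),
      n_negative_strong = sum(by_sp$neg_strong),
      n_positive = sum(by_sp$pos),
      n_positive_strong = sum(by_sp$pos_strong)
    )
  }
  dplyr::bind_rows(
    per_cov,
    roll("either covariate", any),
    roll("both covariates", all)
  )
}
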
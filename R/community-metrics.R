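#' Posterior species richness per site
#'
#' Within each retained MCMC draw the latent occupancy states are summed
#' across species at each site; the resulting per-site richness draws are
#' summarised by their posterior mean, median and central 95% interval.
#'
#' @param x An `occu_fit`, or an M x K x draws array of binary latent
#'   states.
#' @param ... Unused.
#' @return A `richness_posterior` tibble: `site`, `mean`, `median`,
#'   `conf.low`, `conf.high`, with the draws matrix (draws x sites)
#'   attached as attribute `draws`.
#' @export
richness_posterior <- function(x, ...) UseMethod("richness_posterior")

#' @rdname richness_posterior
#' @export
richness_posterior.occu_fit <- function(x, ...) {
  draws <- do.call(rbind, x$richness)
  richness_from_draws(draws, x$sites)
}

#' @rdname richness_posterior
#' @export
richness_posterior.array <- function(x, ...) {
  stopifnot(length(dim(x)) == 3L)
  draws <- t(apply(x, c(1L, 3L), sum))  # draws x sites
  richness_from_draws(draws, seq_len(dim(x)[1]))
}

richness_from_draws <- function(draws, sites) {
  qs <- t(apply(draws, 2L, quantile, probs = c(0.025, 0.5, 0.975),
                type = 7, names = FALSE))
  out <- tibble::tibble(
    site = sites,
    mean = colMeans(draws),
    median = qs[, 2L],
    conf.low = qs[, 1L],
    conf.high = qs[, 3L]
  )
  attr(out, "draws") <- draws
  class(out) <- c("richness_posterior", class(out))
  out
}

#' Regress site richness on vegetation metrics
#'
#' Fits a separate ordinary least-squares regression of posterior median
#' species richness on each vegetation metric, with the usual t-test on the
#' slope.
#'
#' @param richness A `richness_posterior` tibble (or any tibble with `site`
#'   and `median` columns).
#' @param covariates Tibble with a `site` column and the metric columns.
#' @param metrics Character vector of metric column names.
#' @return A tibble: `metric`, `intercept`, `slope`, `std.error`,
#'   `p.value`, `r.squared`.
#' @export
regress_richness <- function(richness, covariates,
                             metrics = c("dens_mid", "dens_canopy")) {
  df <- dplyr::inner_join(richness[, c("site", "median")], covariates,
                          by = "site")
  purrr::map_dfr(metrics, function(m) {
    xv <- df[[m]]
    if (sd(xv) == 0) abort(sprintf("metric `%s` is constant.", m))
    fit <- lm(df$median ~ xv)
    s <- summary(fit)
    tibble::tibble(
      metric = m,
      intercept = coef(fit)[[1]],
      slope = coef(fit)[[2]],
      std.error = s$coefficients[2, 2],
      p.value = s$coefficients[2, 4],
      r.squared = s$r.squared
    )
  })
}

#' Average conservation-priority score of ghost- and unaffected-forest birds
#'
#' Species with at least one strongly supported *negative* vegetation-
#' density effect are grouped as ghost-forest associated (they favour the
#' structurally open conditions ghost forests create); species with at
#' least one strongly supported *positive* effect are grouped as
#' unaffected-forest associated.  A species with opposite strong effects
#' appears in both groups.  The mean conservation-priority score is
#' reported per group (`NA` when a group is empty).
#'
#' @param classification A `support_classification`.
#' @param pif A `pif_table` (`species`, `pif_score`).
#' @param covariates The vegetation-density covariates defining the groups.
#' @return A tibble: `group`, `n_species`, `mean_score`.
#' @export
group_pif_scores <- function(classification, pif,
                             covariates = c("b_mid", "b_canopy")) {
  cl <- dplyr::filter(classification,
                      .data$covariate %in% covariates,
                      .data$strength == "strong")
  ghost_sp <- unique(cl$species[cl$direction == "negative"])
  unaff_sp <- unique(cl$species[cl$direction == "positive"])
  score <- function(sp) {
    if (!length(sp)) return(NA_real_)
    mean(pif$pif_score[match(sp, pif$species)])
  }
  tibble::tibble(
    group = c("ghost", "unaffected"),
    n_species = c(length(ghost_sp), length(unaff_sp)),
    mean_score = c(score(ghost_sp), score(unaff_sp))
  )
}
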
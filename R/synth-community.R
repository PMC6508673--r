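#' Community-level hyperparameters for a synthetic bird community
#'
#' Species-level coefficients in the multi-species occupancy model are treated
#' as random effects drawn from community-level normal distributions.  This
#' constructor bundles the six (mean, sd) pairs that govern, on the logit
#' scale: the detection intercept, the observer-route contrasts (both
#' contrasts share one pair), the occupancy intercept, and the midstory-
#' density, canopy-density and burned effects on occupancy.
#'
#' The defaults give a community with mean occupancy of about 0.4 and mean
#' per-occasion detection probability of about 0.5 at average covariate
#' values, moderately positive mean responses to vegetation density, and a
#' mostly negative response to fire.
#'
#' @param mean,sd Numeric vectors of length 6 in the order: detection
#'   intercept, route contrasts, occupancy intercept, midstory effect,
#'   canopy effect, burned effect.
#' @return A `community_hyper` tibble with columns `family`, `mean`, `sd`.
#' @export
#' @examples
#' community_hyper()
community_hyper <- function(mean = c(0, 0, -0.4, 0.5, 0.5, -0.5),
                            sd = c(0.75, 0.5, 1, 0.75, 0.75, 0.5)) {
  families <- c("det_intercept", "det_route", "occ_intercept",
                "occ_mid", "occ_canopy", "occ_burned")
  if (length(mean) != 6L || length(sd) != 6L) {
    abort("`mean` and `sd` must each have 6 values.")
  }
  if (any(!is.finite(mean)) || any(!is.finite(sd))) {
    abort("hyperparameters must be finite.")
  }
  if (any(sd < 0)) {
    abort("invalid hyperparameters: standard deviations must be >= 0.")
  }
  out <- tibble::tibble(family = families, mean = mean, sd = sd)
  class(out) <- c("community_hyper", class(out))
  out
}

#' Draw species-level coefficients from community hyperparameters
#'
#' Each species' logit-scale coefficients are drawn independently from the
#' normal distribution given by the corresponding hyperparameter pair.  The
#' two observer-route contrasts are separate draws from the shared
#' route-contrast pair.
#'
#' @param hyper A [community_hyper()] object.
#' @param n_species Number of species.
#' @param seed Integer seed; identical seeds give identical draws.
#' @return A `community_params` tibble with one row per species and columns
#'   `species`, `a0`, `a_route_a`, `a_route_b`, `b0`, `b_mid`, `b_canopy`,
#'   `b_burned`.
#' @export
draw_community_params <- function(hyper = community_hyper(), n_species,
                                  seed = 1) {
  stopifnot(inherits(hyper, "community_hyper"))
  n_species <- check_count(n_species, "n_species")
  check_seed(seed)
  if (any(hyper$sd < 0)) {
    abort("invalid hyperparameters: standard deviations must be >= 0.")
  }
  h <- function(f) hyper[hyper$family == f, ]
  set.seed(seed)
  draw <- function(f) {
    row <- h(f)
    rnorm(n_species, row$mean, row$sd)
  }
  out <- tibble::tibble(
    species = seq_len(n_species),
    a0 = draw("det_intercept"),
    a_route_a = draw("det_route"),
    a_route_b = draw("det_route"),
    b0 = draw("occ_intercept"),
    b_mid = draw("occ_mid"),
    b_canopy = draw("occ_canopy"),
    b_burned = draw("occ_burned")
  )
  class(out) <- c("community_params", class(out))
  out
}

#' Build the site-level design table for the occupancy model
#'
#' Extracts midstory and canopy density at the survey sites from one epoch of
#' the landscape, standardizes them (subtract the mean, divide by the sample
#' standard deviation over sites), and attaches the burned flag and
#' observer-route label.  The standardization constants are stored as an
#' attribute so that raster predictions later use the survey-site scale.
#'
#' @param landscape A `ghost_landscape`.
#' @param sites A `survey_design` from [sample_sites()].
#' @param epoch Which epoch's metrics to extract (`"later"` is the survey
#'   epoch).
#' @return A `site_design` tibble: `site`, `route`, `n_occasions`, `burned`
#'   (0/1), raw and standardized `dens_mid` / `dens_canopy`, with a
#'   `standardizers` attribute.
#' @export
site_design <- function(landscape, sites, epoch = c("later", "baseline")) {
  stopifnot(inherits(landscape, "ghost_landscape"),
            inherits(sites, "survey_design"))
  epoch <- match.arg(epoch)
  raster <- landscape[[epoch]]
  idx <- match(sites$cell, raster$cell)
  mid <- standardize(raster$dens_mid[idx])
  can <- standardize(raster$dens_canopy[idx])
  out <- tibble::tibble(
    site = sites$site,
    route = sites$route,
    n_occasions = sites$n_occasions,
    burned = as.integer(raster$burned[idx]),
    dens_mid = raster$dens_mid[idx],
    dens_canopy = raster$dens_canopy[idx],
    dens_mid_std = as.numeric(mid),
    dens_canopy_std = as.numeric(can)
  )
  attr(out, "standardizers") <- list(
    dens_mid = c(center = attr(mid, "center"), scale = attr(mid, "scale")),
    dens_canopy = c(center = attr(can, "center"), scale = attr(can, "scale"))
  )
  class(out) <- c("site_design", class(out))
  out
}

## linear predictors for all site x species combinations
linear_predictors <- function(params, design) {
  route_a <- as.numeric(design$route == "route_a")
  route_b <- as.numeric(design$route == "route_b")
  ## M x K matrices
  psi <- inv_logit(
    outer(rep(1, nrow(design)), params$b0) +
      outer(design$dens_mid_std, params$b_mid) +
      outer(design$dens_canopy_std, params$b_canopy) +
      outer(design$burned, params$b_burned)
  )
  p <- inv_logit(
    outer(rep(1, nrow(design)), params$a0) +
      outer(route_a, params$a_route_a) +
      outer(route_b, params$a_route_b)
  )
  list(psi = psi, p = p)
}

#' Simulate repeat-survey detection histories
#'
#' Generates detection/non-detection data under the hierarchical occupancy
#' model: each species' occupancy state at each site is Bernoulli with
#' probability given by the occupancy linear predictor, and detections on
#' each sampling occasion are Bernoulli with the route-specific detection
#' probability, conditional on presence.  Occasions beyond a site's occasion
#' count are not recorded (missing by design).
#'
#' @param params A `community_params` tibble of species coefficients.
#' @param design A `site_design` tibble (standardized covariates).
#' @param seed Integer seed.
#' @return A `detection_data` tibble in long format (`site`, `occasion`,
#'   `species`, `detected`), with the simulated truth (`z`, `psi`, `p`
#'   matrices) attached as the `truth` attribute.
#' @export
simulate_detections <- function(params, design, seed = 1) {
  stopifnot(inherits(params, "community_params"),
            inherits(design, "site_design"))
  check_seed(seed)
  set.seed(seed)
  M <- nrow(design)
  K <- nrow(params)
  lp <- linear_predictors(params, design)
  z <- matrix(rbinom(M * K, 1L, lp$psi), M, K)

  long <- tidyr::expand_grid(
    site = design$site,
    species = params$species
  )
  long <- dplyr::inner_join(
    tidyr::uncount(
      tibble::tibble(site = design$site, n = design$n_occasions),
      .data$n, .id = "occasion"
    ),
    long,
    by = "site", relationship = "many-to-many"
  )
  i <- match(long$site, design$site)
  k <- match(long$species, params$species)
  pr <- z[cbind(i, k)] * lp$p[cbind(i, k)]
  long$detected <- rbinom(nrow(long), 1L, pr)
  out <- dplyr::arrange(
    tibble::as_tibble(long[, c("site", "occasion", "species", "detected")]),
    site, occasion, species
  )
  out$occasion <- as.integer(out$occasion)
  attr(out, "truth") <- list(z = z, psi = lp$psi, p = lp$p)
  class(out) <- c("detection_data", class(out))
  out
}

#' Simulate conservation-priority scores for synthetic species
#'
#' Draws an integer Partners-in-Flight-style conservation priority score for
#' each species, uniform on 4--14, emulating the range of scores observed in
#' real forest-bird communities.
#'
#' @param species Vector of species identifiers.
#' @param seed Integer seed.
#' @return A `pif_table` tibble with columns `species` and `pif_score`.
#' @export
simulate_pif_scores <- function(species, seed = 1) {
  check_seed(seed)
  set.seed(seed)
  out <- tibble::tibble(
    species = species,
    pif_score = sample(4:14, length(species), replace = TRUE)
  )
  class(out) <- c("pif_table", class(out))
  out
}
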
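## Internal helpers shared across modules.

inv_logit <- stats::plogis
logit <- stats::qlogis

#' @noRd
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1].", name))
  }
  invisible(x)
}

#' @noRd
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

#' @noRd
check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  invisible(as.integer(seed))
}

## clamp to [lo, hi]
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

## log(exp(a) + exp(b)) computed stably, vectorised
log_add_exp <- function(a, b) {
  m <- pmax(a, b)
  ## both -Inf -> -Inf without NaN
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

## separable Gaussian smoothing of a matrix; sigma in cells.
## Used to give synthetic covariate surfaces spatial autocorrelation.
smooth_field <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_apply <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1L], half), v, rep(v[n], half))
    as.numeric(stats::filter(vp, k, sides = 2))[(half + 1L):(half + n)]
  }
  out <- apply(mat, 2L, pad_apply)
  t(apply(out, 1L, pad_apply))
}

## names of the seven vegetation-structure metrics, in canonical order
metric_names <- function() {
  c("mean_height", "max_height", "sd_height",
    "dens_mid", "dens_lower", "dens_canopy", "dens_total")
}
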
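#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy posterior summaries of an occupancy-model fit
#'
#' One row per parameter with the posterior mean, sd, 95% credible interval
#' and the Gelman-Rubin diagnostic.
#'
#' @param x An `occu_fit`.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `rhat`.
#' @export
tidy.occu_fit <- function(x, ...) {
  s <- summarize_posterior(x)
  out <- tibble::tibble(
    term = s$term,
    estimate = s$mean,
    std.error = s$sd,
    conf.low = s$conf.low,
    conf.high = s$conf.high
  )
  if (length(x$draws) >= 2L) {
    out <- dplyr::left_join(out, gelman_rubin(x), by = "term")
  }
  out
}

#' One-row fit summary of an occupancy-model fit
#'
#' @param x An `occu_fit`.
#' @param ... Unused.
#' @return A tibble with the problem size, draw count, worst Gelman-Rubin
#'   value, and mean Metropolis acceptance rates.
#' @export
glance.occu_fit <- function(x, ...) {
  max_rhat <- if (length(x$draws) >= 2L) {
    max(gelman_rubin(x)$rhat, na.rm = TRUE)
  } else {
    NA_real_
  }
  tibble::tibble(
    n_sites = length(x$sites),
    n_species = length(x$species),
    chains = x$settings$chains,
    n_draws = sum(vapply(x$draws, nrow, integer(1))),
    max_rhat = max_rhat,
    accept_detection = mean(x$accept$detection),
    accept_occupancy = mean(x$accept$occupancy)
  )
}

#' Tidy a ghost-forest logistic fit
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`.
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = as.numeric(x$coefficients))
}

#' @rdname tidy.logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(log_lik = x$log_lik, aic = x$aic,
                 n_terms = length(x$coefficients),
                 separation = x$separation)
}

#' Tidy the candidate table of a stepwise selection
#'
#' @param x A `stepwise_result`.
#' @param ... Unused.
#' @return The per-step candidate tibble (`step`, `candidate`, `model`,
#'   `log_lik`, `aic`, `delta_aic`, `accepted`).
#' @export
tidy.stepwise_result <- function(x, ...) x$steps

#' @rdname tidy.stepwise_result
#' @export
glance.stepwise_result <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    model = paste(x$selected, collapse = " + "),
    aic = x$fit$aic,
    log_lik = x$fit$log_lik
  )
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("Correlation-constrained stepwise AIC selection\n")
  cat("  selected:", paste(x$selected, collapse = " + "),
      sprintf("(AIC %.1f)\n", x$fit$aic))
  cat(sprintf("  %d candidate models over %d steps; |r| gate < %.2f\n",
              nrow(x$steps), max(x$steps$step), x$corr_threshold))
  invisible(x)
}
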
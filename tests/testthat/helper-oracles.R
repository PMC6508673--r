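## Independent oracles: latent-state enumeration for the marginal
## likelihood, 2-D grid integration for the single-species posterior, a
## hand-rolled Newton solver for logistic regression, and a batch-means
## Monte-Carlo standard error.  These deliberately avoid the package's own
## computational paths.

log_sum_exp <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log(exp(a - m) + exp(b - m)))
}

## brute-force marginal log-likelihood: sum over all 2^(M*K) latent
## occupancy configurations
enum_loglik <- function(params, y, design) {
  M <- nrow(design)
  K <- nrow(params)
  stopifnot(M * K <= 12)
  psi <- p <- matrix(0, M, K)
  for (k in seq_len(K)) {
    psi[, k] <- plogis(params$b0[k] +
                         params$b_mid[k] * design$dens_mid_std +
                         params$b_canopy[k] * design$dens_canopy_std +
                         params$b_burned[k] * design$burned)
    p[, k] <- plogis(params$a0[k] +
                       params$a_route_a[k] * (design$route == "route_a") +
                       params$a_route_b[k] * (design$route == "route_b"))
  }
  obs <- lapply(seq_len(M), function(i) lapply(seq_len(K), function(k) {
    y$detected[y$site == design$site[i] & y$species == params$species[k]]
  }))
  n_cells <- M * K
  total <- -Inf
  for (code in 0:(2^n_cells - 1)) {
    zvec <- as.integer(intToBits(code))[seq_len(n_cells)]
    ll <- 0
    for (idx in seq_len(n_cells)) {
      i <- (idx - 1) %% M + 1
      k <- (idx - 1) %/% M + 1
      ys <- obs[[i]][[k]]
      if (zvec[idx] == 1) {
        ll <- ll + log(psi[i, k]) +
          sum(ys * log(p[i, k]) + (1 - ys) * log(1 - p[i, k]))
      } else if (any(ys == 1)) {
        ll <- -Inf
        break
      } else {
        ll <- ll + log(1 - psi[i, k])
      }
    }
    total <- log_sum_exp(total, ll)
  }
  total
}

## posterior mean of psi for the single-species intercept-only model by
## grid integration over (logit psi, logit p), priors N(0, sd prior_sd).
## The grid must span the full prior, not just the likelihood bulk: the
## likelihood is asymptotically constant along the psi -> 1 ridge, so with
## a vague prior substantial posterior mass sits at large logit(psi) and a
## narrow grid is biased low.
grid_posterior_psi <- function(sumy, nocc, prior_sd = sqrt(1000),
                               lim = 4 * prior_sd, n_grid = 3000) {
  g <- seq(-lim, lim, length.out = n_grid)
  lp <- outer(g, g, function(b0, a0) {
    ll <- 0
    psi <- plogis(b0)
    p <- plogis(a0)
    for (i in seq_along(sumy)) {
      det_l <- p^sumy[i] * (1 - p)^(nocc[i] - sumy[i])
      ll <- ll + if (sumy[i] > 0) log(psi * det_l) else
        log(psi * det_l + (1 - psi))
    }
    ll
  }) + dnorm(g, 0, prior_sd, log = TRUE) +
    rep(dnorm(g, 0, prior_sd, log = TRUE), each = n_grid)
  w <- exp(lp - max(lp))
  sum(plogis(g) * rowSums(w)) / sum(w)
}

## independent Newton-Raphson logistic MLE (intercept prepended)
newton_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  X <- cbind(1, X)
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    p <- plogis(drop(X %*% beta))
    step <- solve(crossprod(X * (p * (1 - p)), X), crossprod(X, y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

## batch-means Monte-Carlo standard error of the mean of pooled chains
mcse_batch <- function(chains, n_batch = 20) {
  means <- unlist(lapply(chains, function(x) {
    b <- floor(length(x) / n_batch)
    vapply(seq_len(n_batch), function(j) mean(x[(j - 1) * b + seq_len(b)]),
           numeric(1))
  }))
  sd(means) / sqrt(length(means))
}
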
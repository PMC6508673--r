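test_that("standardization matches its closed forms and round-trips", {
  z <- standardize(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_equal(attr(z, "center"), 2)
  expect_equal(attr(z, "scale"), 1)
  x <- rnorm(40)
  zz <- standardize(as.numeric(standardize(x)))
  expect_equal(as.numeric(zz), as.numeric(standardize(x)),
               tolerance = 1e-12)
  expect_equal(unstandardize(standardize(x)), x, tolerance = 1e-12)
  expect_error(standardize(rep(2, 5)), "zero-variance")
})

test_that("marginal log-likelihood matches closed forms", {
  design <- toy_design(mid = 0, n_occasions = 2L)
  ## psi ~= 1, p = .5, y = (1, 0) -> log(.25)
  p1 <- toy_params(1, a0 = 0, b0 = 50)
  y1 <- toy_detections(array(c(1, 0), c(1, 2, 1)), design)
  expect_equal(loglik_marginal(p1, y1, design), log(0.25),
               tolerance = 1e-10)
  ## psi = .5, p = .5, y = (0, 0) -> log(.5 * .25 + .5)
  p2 <- toy_params(1, a0 = 0, b0 = 0)
  y2 <- toy_detections(array(c(0, 0), c(1, 2, 1)), design)
  expect_equal(loglik_marginal(p2, y2, design), log(0.625),
               tolerance = 1e-12)
})

test_that("marginal log-likelihood equals latent-state enumeration", {
  set.seed(19)
  design <- toy_design(mid = rnorm(3), canopy = rnorm(3),
                       burned = c(0L, 1L, 0L),
                       route = c("off_route", "route_a", "route_b"))
  params <- toy_params(2, a0 = rnorm(2), a_route_a = rnorm(2),
                       a_route_b = rnorm(2), b0 = rnorm(2),
                       b_mid = rnorm(2), b_canopy = rnorm(2),
                       b_burned = rnorm(2))
  y <- simulate_detections(params, design, seed = 23)
  expect_equal(loglik_marginal(params, y, design),
               enum_loglik(params, y, design), tolerance = 1e-10)
})

test_that("the z full conditional matches Bayes' rule", {
  expect_equal(full_conditional_z(0.2, 0.9, c(0, 1, 0)), 1)
  expect_equal(full_conditional_z(0.5, 0.5, 0), 1 / 3)
  ## hand Bayes: psi = .8, p = .3, three zeros
  q <- 0.7^3
  expect_equal(full_conditional_z(0.8, 0.3, c(0, 0, 0)),
               0.8 * q / (0.8 * q + 0.2))
})

test_that("the sampler is deterministic per seed and respects detections", {
  set.seed(41)
  design <- toy_design(mid = rnorm(25), canopy = rnorm(25))
  params <- toy_params(3, a0 = 1.5, b0 = 0.5)
  y <- simulate_detections(params, design, seed = 3)
  fit1 <- sample_posterior(y, design, chains = 2, n_iter = 400,
                           n_burn = 100, thin = 2, seed = 7)
  fit2 <- sample_posterior(y, design, chains = 2, n_iter = 400,
                           n_burn = 100, thin = 2, seed = 7)
  expect_identical(fit1$draws, fit2$draws)
  ## any detection pins the latent state at 1
  det <- tapply(y$detected, list(y$site, y$species), max)
  expect_true(all(fit1$z_mean[det == 1] == 1))
  ## retained draws per chain = (n_iter - n_burn) / thin
  expect_equal(nrow(fit1$draws[[1]]), (400 - 100) / 2)
})

test_that("Gelman-Rubin matches its formula and limiting behavior", {
  ## hand computation: chains (1,2,3) and (2,3,4): W = 1, B = 1.5,
  ## R-hat = sqrt((2/3 * 1 + 0.5) / 1) = sqrt(7/6)
  m <- cbind(c(1, 2, 3), c(2, 3, 4))
  expect_equal(gelman_rubin(m), sqrt(7 / 6), tolerance = 1e-12)
  ## independent same-distribution chains converge to 1
  set.seed(15)
  big <- matrix(rnorm(30000), ncol = 3)
  expect_lt(abs(gelman_rubin(big) - 1), 0.01)
  ## separated chains diverge
  expect_gt(gelman_rubin(cbind(rnorm(100), rnorm(100, 50))), 10)
  ## zero within-chain variance is undefined
  expect_true(is.na(gelman_rubin(cbind(rep(1, 5), rep(2, 5)))))
})

test_that("Gelman-Rubin agrees with the coda reference implementation", {
  ## coda implements the Brooks-Gelman corrected PSRF, which adds a
  ## (1 + 1/m) factor on the between-chain term plus a d.f. correction;
  ## this package computes the classic statistic.  The variants coincide
  ## near convergence, so compare on long chains with slight separation.
  set.seed(27)
  draws <- lapply(c(-0.05, 0, 0.05), function(mu) rnorm(2000, mu))
  m <- do.call(cbind, draws)
  ref <- unname(coda::gelman.diag(
    coda::mcmc.list(lapply(draws, coda::mcmc)),
    autoburnin = FALSE, transform = FALSE
  )$psrf[1, 1])
  expect_equal(gelman_rubin(m), ref, tolerance = 0.01)
})

test_that("posterior summaries follow the stated quantile rule", {
  const <- matrix(0.7, 50, 1, dimnames = list(NULL, "c"))
  s <- summarize_posterior(const)
  expect_equal(s$mean, 0.7)
  expect_equal(s$conf.low, 0.7)
  expect_equal(s$conf.high, 0.7)
  s2 <- summarize_posterior(matrix(1:100, 100, 1,
                                   dimnames = list(NULL, "x")))
  expect_equal(s2$conf.low, 3.475)   # type-7 quantile rule
  expect_equal(s2$conf.high, 97.525)
  sym <- matrix(c(-3, -1, 0, 1, 3), 5, 1, dimnames = list(NULL, "s"))
  s3 <- summarize_posterior(sym)
  expect_equal(s3$mean, 0)
})

test_that("support classification applies the interval rule", {
  summary <- tibble::tibble(
    term = c("b_mid[1]", "b_mid[2]", "b_mid[3]"),
    mean = c(0.5, 0.1, -0.2),
    sd = 1,
    conf.low = c(0.2, -0.1, -0.5),
    conf.high = c(0.9, 0.4, 0.0)
  )
  cl <- classify_support(summary, covariates = "b_mid")
  expect_equal(cl$direction, c("positive", "positive", "negative"))
  ## an endpoint exactly at zero counts as including zero
  expect_equal(cl$strength, c("strong", "weak", "weak"))
})

test_that("support counts equal an independent recount", {
  set.seed(33)
  K <- 40
  cl <- tibble::tibble(
    species = rep(seq_len(K), 2),
    covariate = rep(c("b_mid", "b_canopy"), each = K),
    mean = rnorm(2 * K),
    conf.low = NA_real_, conf.high = NA_real_,
    direction = NA_character_,
    strength = sample(c("strong", "weak"), 2 * K, replace = TRUE)
  )
  cl$direction <- ifelse(cl$mean < 0, "negative", "positive")
  class(cl) <- c("support_classification", class(cl))
  tab <- count_support_table(cl)

  recount <- function(cov) {
    sub <- cl[cl$covariate == cov, ]
    c(sum(sub$mean < 0),
      sum(sub$mean < 0 & sub$strength == "strong"),
      sum(sub$mean > 0),
      sum(sub$mean > 0 & sub$strength == "strong"))
  }
  for (cov in c("b_mid", "b_canopy")) {
    row <- tab[tab$covariate == cov, ]
    expect_equal(unlist(row[, -1], use.names = FALSE), recount(cov))
    ## negative + positive counts partition the species
    expect_equal(row$n_negative + row$n_positive, K)
  }
  ## union / intersection rollups recounted per species
  either_neg <- sum(vapply(seq_len(K), function(s) {
    any(cl$mean[cl$species == s] < 0)
  }, logical(1)))
  both_neg <- sum(vapply(seq_len(K), function(s) {
    all(cl$mean[cl$species == s] < 0)
  }, logical(1)))
  expect_equal(tab$n_negative[tab$covariate == "either covariate"],
               either_neg)
  expect_equal(tab$n_negative[tab$covariate == "both covariates"],
               both_neg)
})
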
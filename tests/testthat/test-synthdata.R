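test_that("degenerate hyperparameters give every species the same coefficients", {
  hyper <- community_hyper(mean = c(0.2, -0.1, 0.5, 1.0, 0.8, -0.3),
                           sd = rep(0, 6))
  params <- draw_community_params(hyper, n_species = 7, seed = 3)
  expect_equal(params$a0, rep(0.2, 7))
  expect_equal(params$a_route_a, rep(-0.1, 7))
  expect_equal(params$a_route_b, rep(-0.1, 7))
  expect_equal(params$b0, rep(0.5, 7))
  expect_equal(params$b_mid, rep(1.0, 7))
  expect_equal(params$b_canopy, rep(0.8, 7))
  expect_equal(params$b_burned, rep(-0.3, 7))
})

test_that("large communities recover the hyperparameter law", {
  hyper <- community_hyper(mean = rep(0, 6), sd = rep(1, 6))
  params <- draw_community_params(hyper, n_species = 10000, seed = 8)
  expect_lt(abs(mean(params$b_mid)), 0.05)
  expect_lt(abs(sd(params$b_mid) - 1), 0.05)
  expect_lt(abs(mean(params$a0)), 0.05)
  expect_lt(abs(sd(params$a0) - 1), 0.05)
})

test_that("parameter draws are deterministic under a seed and reject bad sds", {
  expect_identical(draw_community_params(community_hyper(), 12, seed = 5),
                   draw_community_params(community_hyper(), 12, seed = 5))
  expect_error(community_hyper(sd = c(1, 1, -0.1, 1, 1, 1)),
               "standard deviations")
})

test_that("without ghost transitions the later epoch changes only in burned cells", {
  land <- simulate_landscape(dims = c(80, 80), ghost_fraction = 0,
                             seed = 2)
  unburned <- !land$baseline$burned
  for (col in all_metrics) {
    expect_identical(land$later[[col]][unburned],
                     land$baseline[[col]][unburned])
  }
  expect_false(any(land$masks$ghost))
})

test_that("ghost-transition count matches its expectation within sampling error", {
  land <- simulate_landscape(dims = c(100, 100), ghost_fraction = 0.2,
                             seed = 7)
  n_ghost <- sum(land$masks$ghost)
  ## sum of independent Bernoulli cells with expected total 2000:
  ## sd <= sqrt(2000), so 5 sd is a generous bound
  expect_lt(abs(n_ghost - 2000), 5 * sqrt(2000))
  expect_true(all(land$masks$cell[land$masks$ghost] %in%
                    land$masks$cell[land$masks$lowlying]))
})

test_that("metric surfaces respect their ranges after perturbation", {
  land <- simulate_landscape(dims = c(80, 80), seed = 4)
  for (r in list(land$baseline, land$later)) {
    for (col in c("dens_mid", "dens_lower", "dens_canopy", "dens_total")) {
      expect_true(all(r[[col]] >= 0 & r[[col]] <= 1))
    }
    for (col in c("mean_height", "max_height", "sd_height")) {
      expect_true(all(r[[col]] >= 0))
    }
  }
  expect_false(any(land$masks$lowlying & land$masks$burned))
})

test_that("landscapes are bit-reproducible under a seed", {
  a <- simulate_landscape(dims = c(60, 60), seed = 9)
  b <- simulate_landscape(dims = c(60, 60), seed = 9)
  expect_identical(a$baseline, b$baseline)
  expect_identical(a$later, b$later)
  expect_identical(a$masks, b$masks)
})

test_that("infeasible fraction combinations raise a configuration error", {
  expect_error(
    simulate_landscape(dims = c(30, 30), ghost_fraction = 0.5,
                       lowlying_fraction = 0.1, seed = 1),
    "too small"
  )
})

test_that("biomass-change labels track the ghost-transition mask", {
  land <- default_landscape()
  labels <- simulate_biomass_change(land)
  ## ghost-transition cells lose midstory and canopy density, so the
  ## structural proxy always decreases there
  expect_true(all(labels$ghost[land$masks$ghost]))
  ## agreement on unburned cells (burned cells also lose biomass, by design)
  unburned <- !land$masks$burned
  agree <- mean(labels$ghost[unburned] == land$masks$ghost[unburned])
  expect_gte(agree, 0.95)
})

test_that("survey sites respect spacing and the route split", {
  land <- simulate_landscape(dims = c(300, 300), seed = 21)
  two <- sample_sites(land, n_sites = 2, min_spacing = 400, seed = 1)
  d <- sqrt(diff(two$x)^2 + diff(two$y)^2) * land$cell_size
  expect_gte(d, 400)

  sites <- sample_sites(land, n_sites = 156, min_spacing = 200,
                        route_split = c(0.2, 0.2, 0.6), seed = 2)
  dd <- as.matrix(dist(cbind(sites$x, sites$y))) * land$cell_size
  expect_true(all(dd[upper.tri(dd)] >= 200))
  counts <- table(sites$route)
  ## multinomial: sd of a route count is sqrt(156 * .2 * .8) ~= 5
  expect_lt(abs(counts[["route_a"]] - 31.2), 4 * sqrt(156 * 0.2 * 0.8))
  expect_lt(abs(counts[["route_b"]] - 31.2), 4 * sqrt(156 * 0.2 * 0.8))
  expect_lt(abs(counts[["off_route"]] - 93.6), 4 * sqrt(156 * 0.6 * 0.4))
  expect_identical(sites,
                   sample_sites(land, n_sites = 156, min_spacing = 200,
                                route_split = c(0.2, 0.2, 0.6), seed = 2))
})

test_that("detection simulation saturates at extreme intercepts", {
  design <- toy_design(mid = rnorm(20), canopy = rnorm(20))
  sat <- simulate_detections(toy_params(3, a0 = 20, b0 = 20), design,
                             seed = 1)
  expect_true(all(sat$detected == 1))
  none <- simulate_detections(toy_params(3, a0 = 20, b0 = -20), design,
                              seed = 1)
  expect_true(all(none$detected == 0))
})

test_that("at-least-one-detection frequency matches the closed form", {
  M <- 2000
  design <- toy_design(mid = rep(0, M))
  params <- toy_params(1, a0 = 0, b0 = qlogis(0.6))  # psi = .6, p = .5
  y <- simulate_detections(params, design, seed = 6)
  frac <- mean(tapply(y$detected, y$site, max))
  truth <- 0.6 * (1 - 0.5^3)  # 0.525
  mcse <- sqrt(truth * (1 - truth) / M)
  expect_lt(abs(frac - truth), 3 * mcse)
  ## per-occasion detection frequency converges to psi * p
  per_occ <- mean(y$detected)
  expect_lt(abs(per_occ - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(y)))
})

test_that("missing occasions exactly match the design's occasion counts", {
  design <- toy_design(mid = rnorm(30),
                       n_occasions = rep(c(1L, 2L, 3L), 10))
  y <- simulate_detections(toy_params(4), design, seed = 2)
  occ <- tapply(y$occasion, y$site, function(o) length(unique(o)))
  expect_equal(as.integer(occ), design$n_occasions)
  expect_true(all(y$occasion <= design$n_occasions[match(y$site,
                                                         design$site)]))
})
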
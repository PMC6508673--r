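make_raster <- function(values, nr, nc, cell_size = 12, burned = FALSE) {
  xy <- expand.grid(x = seq_len(nr), y = seq_len(nc))
  new_covariate_raster(
    tibble::tibble(x = xy$x, y = xy$y, cell = seq_len(nr * nc),
                   dens_mid = values, dens_canopy = values,
                   burned = rep_len(burned, nr * nc), valid = TRUE),
    cell_size, "baseline"
  )
}

unit_standardizers <- list(dens_mid = c(center = 0, scale = 1),
                           dens_canopy = c(center = 0, scale = 1))

test_that("aggregation takes block means, majorities and scales the cell", {
  const <- make_raster(rep(0.4, 64), 8, 8)
  agg <- aggregate_raster(const, 4)
  expect_equal(agg$dens_mid, rep(0.4, 4))
  expect_equal(attr(agg, "cell_size"), 48)
  expect_equal(cell_area_ha(agg), 0.2304)  # 48 m cells

  ## one 2x2 block with values (0, 0, 1, 1) -> 0.5; burned majority
  r <- make_raster(c(0, 0, 1, 1), 2, 2,
                   burned = c(TRUE, TRUE, TRUE, FALSE))
  a <- aggregate_raster(r, 2)
  expect_equal(a$dens_mid, 0.5)
  expect_equal(a$burned, 1)
  expect_error(aggregate_raster(r, 0), "factor")
})

test_that("occupancy prediction matches the logit closed forms", {
  r <- make_raster(rep(0.5, 9), 3, 3)
  zero <- predict_occupancy(r, c(b0 = 0, b_mid = 0, b_canopy = 0,
                                 b_burned = 0), unit_standardizers)
  expect_equal(zero$psi, rep(0.5, 9))
  sat <- predict_occupancy(r, c(b0 = 20), unit_standardizers)
  expect_true(all(sat$psi > 0.999999))

  ## single-cell hand computation
  one <- make_raster(1, 1, 1)
  one$dens_mid <- 0.3
  one$dens_canopy <- -0.4
  p <- predict_occupancy(one, c(b0 = 0.5, b_mid = -1.2, b_canopy = 0.8),
                         unit_standardizers)
  expect_equal(p$psi, 1 / (1 + exp(-(0.5 - 1.2 * 0.3 + 0.8 * (-0.4)))),
               tolerance = 1e-12)
  expect_error(predict_occupancy(r, c(b0 = 0), NULL), "standardizers")
})

test_that("delta psi is a bounded antisymmetric difference", {
  r <- make_raster(runif(16), 4, 4)
  pa <- predict_occupancy(r, c(b0 = 0.2, b_mid = 1), unit_standardizers)
  r2 <- r
  r2$dens_mid <- r$dens_mid + 0.3
  pb <- predict_occupancy(r2, c(b0 = 0.2, b_mid = 1), unit_standardizers)
  expect_equal(delta_psi(pa, pa)$delta, rep(0, 16))
  d <- delta_psi(pa, pb)
  expect_true(all(abs(d$delta) <= 1))
  expect_equal(delta_psi(pb, pa)$delta, -d$delta)
})

test_that("change classification uses strict inequalities at the boundary", {
  d <- tibble::tibble(x = 1, y = 1:5, cell = 1:5,
                      delta = c(-0.31, -0.30, 0, 0.30, 0.31))
  cl <- classify_change(d, threshold = 0.3)
  expect_equal(as.character(cl$change),
               c("loss", "none", "none", "none", "gain"))
  expect_error(classify_change(d, threshold = 0), "threshold")
  expect_error(classify_change(d, threshold = 1.2), "threshold")
})

test_that("area accounting multiplies counts by the cell area", {
  d <- tibble::tibble(x = 1, y = 1:20, cell = 1:20,
                      delta = c(rep(-0.5, 4), rep(0.5, 10), rep(0, 6)))
  ch <- classify_change(d)
  out <- summarize_area(ch)
  expect_equal(out$loss_ha, 4 * 0.2304)
  expect_equal(out$gain_ha, 10 * 0.2304)
  expect_equal(out$net_ha, 6 * 0.2304)
  ## single loss cell inside a mask
  one <- summarize_area(ch, mask = 1)
  expect_equal(one$loss_ha, 0.2304)
  empty <- summarize_area(ch, mask = integer(0))
  expect_equal(unlist(empty), c(loss_ha = 0, gain_ha = 0, net_ha = 0,
                                n_cells = 0))
  ## counts partition the cells
  expect_equal(sum(ch$change == "loss") + sum(ch$change == "gain") +
                 sum(ch$change == "none"), nrow(ch))
})

test_that("stratified accounting obeys its structural invariants", {
  land <- simulate_landscape(dims = c(200, 200), seed = 17)
  coefs <- tibble::tibble(species = c("flat", "closed"),
                          b0 = c(0.4, 0), b_mid = c(0, 2),
                          b_canopy = c(0, 2), b_burned = c(0, 0))
  std <- list(dens_mid = c(center = 0.3, scale = 0.15),
              dens_canopy = c(center = 0.25, scale = 0.15))
  tab <- stratified_change(land, coefs, std,
                           strata = c("whole_area", "burned", "lowlying",
                                      "ghost"))
  ## zero-effect species: psi constant, so no change anywhere
  flat <- tab[tab$species == "flat", ]
  expect_true(all(flat$loss_ha == 0 & flat$gain_ha == 0))
  ## net = gain - loss and non-negative areas
  expect_equal(tab$net_ha, tab$gain_ha - tab$loss_ha)
  expect_true(all(tab$loss_ha >= 0 & tab$gain_ha >= 0))
  ## nested strata never exceed the whole area
  cl <- tab[tab$species == "closed", ]
  whole <- cl[cl$stratum == "whole_area", ]
  for (s in c("burned", "lowlying", "ghost")) {
    sub <- cl[cl$stratum == s, ]
    expect_lte(sub$loss_ha + sub$gain_ha, whole$loss_ha + whole$gain_ha)
  }

  ## identical epochs give identically zero tables
  land0 <- land
  land0$later <- land$baseline
  tab0 <- stratified_change(land0, coefs, std)
  expect_true(all(tab0$loss_ha == 0 & tab0$gain_ha == 0))

  ## raising the threshold never increases areas
  tab_hi <- stratified_change(land, coefs, std, threshold = 0.5)
  expect_true(all(tab_hi$loss_ha <= tab$loss_ha[match(
    paste(tab_hi$species, tab_hi$stratum),
    paste(tab$species, tab$stratum))]))
})

test_that("fire losses exceed saltwater losses when the burn is larger", {
  ## closed-canopy specialist on a landscape where the burned perimeter
  ## covers more area than the ghost transitions
  land <- simulate_landscape(dims = c(250, 250), burn_fraction = 0.2,
                             ghost_fraction = 0.08, seed = 29)
  coefs <- tibble::tibble(species = "closed", b0 = 0.5, b_mid = 2,
                          b_canopy = 2, b_burned = 0)
  std <- list(dens_mid = c(center = 0.3, scale = 0.15),
              dens_canopy = c(center = 0.25, scale = 0.15))
  tab <- stratified_change(land, coefs, std)
  burned <- tab[tab$stratum == "burned", ]
  lowlying <- tab[tab$stratum == "lowlying", ]
  expect_lt(burned$net_ha, 0)
  expect_lt(lowlying$net_ha, 0)
  expect_gt(abs(burned$net_ha), abs(lowlying$net_ha))
})

test_that("species coefficient extraction is consistent across sources", {
  params <- draw_community_params(community_hyper(), 5, seed = 2)
  direct <- species_coefficients(params)
  expect_equal(names(direct), c("species", "b0", "b_mid", "b_canopy",
                                "b_burned"))
  summary <- tibble::tibble(
    term = c("b0[1]", "b_mid[1]", "b_canopy[1]", "b_burned[1]"),
    mean = c(0.1, 0.2, 0.3, 0.4), sd = 1,
    conf.low = 0, conf.high = 1
  )
  wide <- species_coefficients(summary)
  expect_equal(wide$b_mid, 0.2)
  expect_equal(wide$b_burned, 0.4)
})

test_that("rasters round-trip through their CSV representation", {
  r <- make_raster(runif(12), 3, 4, cell_size = 24)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  write_raster_csv(r, path)
  back <- read_raster_csv(path)
  expect_equal(attr(back, "cell_size"), 24)
  expect_equal(back$dens_mid, r$dens_mid, tolerance = 1e-12)

  design <- toy_design(mid = rnorm(4))
  y <- simulate_detections(toy_params(2), design, seed = 1)
  path2 <- tempfile(fileext = ".csv")
  on.exit(unlink(path2), add = TRUE)
  write_detections(y, path2)
  y2 <- read_detections(path2)
  ## the simulation-only `truth` attribute is not part of the CSV contract
  expect_equal(as.data.frame(y2), as.data.frame(y[, names(y2)]),
               ignore_attr = "truth")
})
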
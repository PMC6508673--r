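## Small constructors used across tests: hand-built site designs, species
## coefficient tables and long-format detection data, independent of the
## package's synthetic generator.

all_metrics <- c("mean_height", "max_height", "sd_height",
                 "dens_mid", "dens_lower", "dens_canopy", "dens_total")

toy_design <- function(mid, canopy = rep(0, length(mid)),
                       burned = rep(0L, length(mid)),
                       route = rep("off_route", length(mid)),
                       n_occasions = rep(3L, length(mid))) {
  M <- length(mid)
  out <- tibble::tibble(
    site = seq_len(M),
    route = factor(rep_len(route, M),
                   levels = c("off_route", "route_a", "route_b")),
    n_occasions = as.integer(rep_len(n_occasions, M)),
    burned = as.integer(rep_len(burned, M)),
    dens_mid = mid,
    dens_canopy = canopy,
    dens_mid_std = mid,
    dens_canopy_std = canopy
  )
  attr(out, "standardizers") <- list(
    dens_mid = c(center = 0, scale = 1),
    dens_canopy = c(center = 0, scale = 1)
  )
  class(out) <- c("site_design", class(out))
  out
}

toy_params <- function(n_species, a0 = 0, a_route_a = 0, a_route_b = 0,
                       b0 = 0, b_mid = 0, b_canopy = 0, b_burned = 0) {
  out <- tibble::tibble(
    species = seq_len(n_species),
    a0 = rep_len(a0, n_species),
    a_route_a = rep_len(a_route_a, n_species),
    a_route_b = rep_len(a_route_b, n_species),
    b0 = rep_len(b0, n_species),
    b_mid = rep_len(b_mid, n_species),
    b_canopy = rep_len(b_canopy, n_species),
    b_burned = rep_len(b_burned, n_species)
  )
  class(out) <- c("community_params", class(out))
  out
}

## long detection tibble from an M x J x K binary array (NA = unsurveyed)
toy_detections <- function(y_arr, design) {
  M <- dim(y_arr)[1]; J <- dim(y_arr)[2]; K <- dim(y_arr)[3]
  long <- expand.grid(site = seq_len(M), occasion = seq_len(J),
                      species = seq_len(K))
  long$detected <- y_arr[cbind(long$site, long$occasion, long$species)]
  long <- long[!is.na(long$detected), ]
  out <- tibble::as_tibble(long[order(long$site, long$occasion,
                                      long$species), ])
  class(out) <- c("detection_data", class(out))
  out
}

## one default landscape, generated once per test run and shared
the <- new.env(parent = emptyenv())
default_landscape <- function() {
  if (is.null(the$land)) the$land <- simulate_landscape(seed = 42)
  the$land
}
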
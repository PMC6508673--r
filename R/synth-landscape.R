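#' Simulate a two-epoch coastal-forest landscape
#'
#' Generates gridded vegetation-structure metrics for two LiDAR-style epochs
#' (a baseline and a later acquisition) together with the spatial masks the
#' downstream analysis needs: a burned perimeter, unburned low-lying forest,
#' and the ghost-forest transition cells where saltwater exposure has thinned
#' the midstory and canopy between epochs.
#'
#' Seven metrics are generated per cell: mean, maximum and standard deviation
#' of vegetation height (m), and the fraction of returns in the midstory
#' (4.5--10 m), lower canopy (10--20 m) and canopy (20--30 m) layers plus total
#' vegetation density (all in \[0, 1\]).  Surfaces are built from smoothed
#' Gaussian noise so neighbouring cells are correlated, and share latent
#' "stand maturity" structure so the metrics are collinear, as LiDAR metrics
#' of real forests are.
#'
#' The later epoch equals the baseline except that ghost-transition cells
#' (drawn inside the unburned low-lying mask) have their midstory and canopy
#' densities multiplied by `ghost_reduction`, and burned cells receive an
#' independent structural perturbation emulating fire damage.
#'
#' @param dims Integer vector of length 2, grid rows and columns.
#' @param ghost_fraction Expected fraction of *all* grid cells that transition
#'   to ghost forest; transitions are confined to the unburned low-lying mask.
#' @param burn_fraction Fraction of cells inside the burned perimeter.
#' @param lowlying_fraction Fraction of cells classed as low-lying (before
#'   removing burned overlap).
#' @param ghost_reduction Multiplier (< 1) applied to midstory and canopy
#'   density in ghost-transition cells.
#' @param cell_size Cell edge length in metres.
#' @param smooth_sigma Gaussian smoothing radius, in cells, controlling the
#'   spatial correlation length of the metric surfaces.
#' @param seed Integer seed; landscapes are bit-reproducible given the seed.
#'
#' @return An object of class `ghost_landscape`: a list with covariate-raster
#'   tibbles `baseline` and `later` (columns `x`, `y`, `cell`, the seven
#'   metrics, `burned`, `valid`), a `masks` tibble (`ghost`, `burned`,
#'   `lowlying` logicals per cell), and scalars `cell_size`, `dims`,
#'   `ghost_reduction`.
#' @export
#' @examples
#' land <- simulate_landscape(dims = c(60, 60), seed = 1)
#' dplyr::glimpse(land$baseline)
simulate_landscape <- function(dims = c(800, 800),
                               ghost_fraction = 0.1,
                               burn_fraction = 0.15,
                               lowlying_fraction = 0.35,
                               ghost_reduction = 0.3,
                               cell_size = 12,
                               smooth_sigma = 6,
                               seed = 1) {
  nr <- check_count(dims[1], "dims[1]", min = 4L)
  nc <- check_count(dims[2], "dims[2]", min = 4L)
  check_fraction(ghost_fraction, "ghost_fraction")
  check_fraction(burn_fraction, "burn_fraction")
  check_fraction(lowlying_fraction, "lowlying_fraction")
  check_seed(seed)
  if (ghost_reduction < 0 || ghost_reduction >= 1) {
    abort("`ghost_reduction` must be in [0, 1).")
  }

  set.seed(seed)
  n <- nr * nc
  field <- function() {
    f <- smooth_field(matrix(rnorm(n), nr, nc), smooth_sigma)
    as.numeric((f - mean(f)) / sd(f))
  }

  ## latent structure: stand maturity drives heights and canopy; two further
  ## fields decorrelate the midstory and lower-canopy layers
  maturity <- stats::pnorm(field())
  shrub    <- stats::pnorm(field())
  subcan   <- stats::pnorm(field())
  elev     <- field()
  fire     <- field()
  exposure <- field()   # clumps saltwater exposure into shoreline patches

  noise <- function(s) rnorm(n, sd = s)

  mean_height <- pmax(0, 2 + 23 * maturity + noise(1.2))
  max_height  <- mean_height * (1.35 + 0.25 * stats::pnorm(noise(1)))
  sd_height   <- pmax(0, 0.5 + 4.5 * maturity + noise(0.5))
  dens_canopy <- clamp(0.60 * maturity - 0.10 + noise(0.05))
  dens_mid    <- clamp(0.12 + 0.28 * maturity + 0.30 * shrub + noise(0.04))
  dens_lower  <- clamp(0.08 + 0.14 * maturity + 0.38 * subcan + noise(0.04))
  dens_total  <- clamp(0.20 + 0.65 * maturity + noise(0.05))

  burned   <- fire >= quantile(fire, 1 - burn_fraction)
  if (burn_fraction == 0) burned[] <- FALSE
  lowlying <- (elev <= quantile(elev, lowlying_fraction)) & !burned
  if (lowlying_fraction == 0) lowlying[] <- FALSE

  n_ghost_target <- ghost_fraction * n
  eligible <- which(lowlying)
  if (ghost_fraction > 0 && n_ghost_target > length(eligible)) {
    abort(paste0(
      "grid too small to honour the requested fractions: ",
      "ghost_fraction * ncell exceeds the unburned low-lying cell count."
    ))
  }
  ## ghost transitions are independent Bernoulli draws whose per-cell
  ## probability follows the smoothed exposure field, so transitions clump
  ## into patches (as saltwater-killed stands do) while the expected count
  ## stays at ghost_fraction * ncell
  ghost <- rep(FALSE, n)
  if (ghost_fraction > 0 && length(eligible)) {
    w <- exp(2.5 * exposure[eligible])
    cc <- n_ghost_target / sum(w)
    for (it in 1:50) {
      p_cell <- pmin(cc * w, 1)
      s <- sum(p_cell)
      if (s >= n_ghost_target * 0.9999) break
      cc <- cc * n_ghost_target / s
    }
    ghost[eligible] <- runif(length(eligible)) < p_cell
  }

  xy <- expand.grid(x = seq_len(nr), y = seq_len(nc))
  base <- tibble::tibble(
    x = xy$x, y = xy$y, cell = seq_len(n),
    mean_height = mean_height, max_height = max_height,
    sd_height = sd_height, dens_mid = dens_mid, dens_lower = dens_lower,
    dens_canopy = dens_canopy, dens_total = dens_total,
    burned = burned, valid = TRUE
  )

  later <- base
  if (any(ghost)) {
    ## severity varies cell to cell around the configured reduction
    ## (a gradient of saltwater exposure), so ghost and unaffected stands
    ## overlap in structure instead of separating perfectly
    fac <- clamp(ghost_reduction * exp(rnorm(sum(ghost), 0, 0.5)),
                 0.02, 0.9)
    later$dens_mid[ghost]    <- later$dens_mid[ghost] * fac
    later$dens_canopy[ghost] <- later$dens_canopy[ghost] * fac
  }
  if (any(burned)) {
    u <- runif(sum(burned), 0.2, 0.7)
    for (col in c("dens_mid", "dens_lower", "dens_canopy", "dens_total")) {
      later[[col]][burned] <- clamp(later[[col]][burned] * u)
    }
    h <- 0.5 + 0.5 * u
    later$mean_height[burned] <- later$mean_height[burned] * h
    later$max_height[burned]  <- later$max_height[burned] * h
    later$sd_height[burned]   <- later$sd_height[burned] * h
  }

  structure(
    list(
      baseline = new_covariate_raster(base, cell_size, "baseline"),
      later = new_covariate_raster(later, cell_size, "later"),
      masks = tibble::tibble(
        x = xy$x, y = xy$y, cell = seq_len(n),
        ghost = ghost, burned = burned, lowlying = lowlying
      ),
      cell_size = cell_size,
      dims = c(nr, nc),
      ghost_reduction = ghost_reduction,
      seed = as.integer(seed)
    ),
    class = "ghost_landscape"
  )
}

#' Construct a covariate raster tibble
#'
#' A covariate raster is a tibble with one row per grid cell (`x`, `y`,
#' `cell`), vegetation-metric columns, a `burned` flag and a `valid` mask,
#' carrying the cell edge length (m) and epoch label as attributes.
#'
#' @param df Tibble of per-cell values.
#' @param cell_size Cell edge length in metres.
#' @param epoch Epoch label.
#' @return The tibble with class `covariate_raster` prepended.
#' @export
new_covariate_raster <- function(df, cell_size, epoch) {
  if (cell_size <= 0) abort("`cell_size` must be > 0.")
  out <- tibble::as_tibble(df)
  attr(out, "cell_size") <- cell_size
  attr(out, "epoch") <- epoch
  class(out) <- c("covariate_raster", class(out))
  out
}

#' Cell area of a covariate raster, in hectares
#' @param raster A `covariate_raster`.
#' @return A single numeric (ha).
#' @export
cell_area_ha <- function(raster) {
  attr(raster, "cell_size")^2 / 1e4
}

#' Label ghost forest from a biomass-change proxy
#'
#' Computes a simple structural biomass proxy for each epoch -- the sum of
#' layer densities weighted by the layer mid-heights (midstory 7.25 m, lower
#' canopy 15 m, canopy 25 m) -- and labels a cell `ghost` where the proxy
#' decreased between epochs and `unaffected` otherwise.  These labels are the
#' binary response used to train the ghost-forest classifier, mirroring
#' classification of change from repeat LiDAR biomass estimates; only the sign
#' of the change is used, so any monotone structural proxy gives the same
#' labels.
#'
#' @param landscape A `ghost_landscape`.
#' @return Tibble with `x`, `y`, `cell`, `biomass_baseline`, `biomass_later`
#'   and logical `ghost`.
#' @export
simulate_biomass_change <- function(landscape) {
  stopifnot(inherits(landscape, "ghost_landscape"))
  proxy <- function(r) {
    7.25 * r$dens_mid + 15 * r$dens_lower + 25 * r$dens_canopy
  }
  b0 <- proxy(landscape$baseline)
  b1 <- proxy(landscape$later)
  tibble::tibble(
    x = landscape$baseline$x, y = landscape$baseline$y,
    cell = landscape$baseline$cell,
    biomass_baseline = b0, biomass_later = b1,
    ghost = b1 < b0
  )
}

## random sequential placement with a bucket grid for the spacing check
place_points <- function(candidates, nr, min_cells, n_points,
                         max_tries = 50L) {
  bucket <- max(1, ceiling(min_cells))
  for (try in seq_len(max_tries)) {
    ord <- sample(candidates)
    chosen <- integer(0)
    buckets <- new.env(hash = TRUE, parent = emptyenv())
    cx <- integer(0); cy <- integer(0)
    for (cand in ord) {
      px <- (cand - 1L) %% nr + 1L
      py <- (cand - 1L) %/% nr + 1L
      bx <- px %/% bucket; by <- py %/% bucket
      ok <- TRUE
      for (dx in -1:1) {
        for (dy in -1:1) {
          key <- paste(bx + dx, by + dy)
          idx <- buckets[[key]]
          if (!is.null(idx) &&
              any((cx[idx] - px)^2 + (cy[idx] - py)^2 < min_cells^2)) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (ok) {
        chosen <- c(chosen, cand)
        cx <- c(cx, px); cy <- c(cy, py)
        key <- paste(bx, by)
        buckets[[key]] <- c(buckets[[key]], length(chosen))
        if (length(chosen) == n_points) return(chosen)
      }
    }
  }
  abort(paste0(
    "could not place ", n_points, " points at the requested spacing; ",
    "use a larger grid or a smaller `min_spacing`."
  ))
}

#' Sample survey sites on a landscape
#'
#' Places point-count survey sites at grid cells with a minimum pairwise
#' spacing and assigns each site an observer-route label (two survey routes
#' plus off-route points, each route run by a distinct observer) and a number
#' of sampling occasions.  Route sites are visited on 3 occasions; off-route
#' sites on 1 to 3.  The defaults mirror a design of 156 points, a 400-m
#' minimum spacing, and roughly 40% of points on the two routes.
#'
#' @param landscape A `ghost_landscape`.
#' @param n_sites Number of sites to place.
#' @param min_spacing Minimum pairwise distance between sites, metres.
#' @param route_split Length-3 proportions for (route-A, route-B, off-route);
#'   normalised to sum to one.
#' @param seed Integer seed.
#' @return A `survey_design` tibble: `site`, `x`, `y`, `cell`, `route`
#'   (factor with reference level `off_route`), `n_occasions`, with
#'   `min_spacing` and `cell_size` attributes.
#' @export
sample_sites <- function(landscape, n_sites = 156, min_spacing = 400,
                         route_split = c(0.2, 0.2, 0.6), seed = 1) {
  stopifnot(inherits(landscape, "ghost_landscape"))
  n_sites <- check_count(n_sites, "n_sites")
  check_seed(seed)
  if (length(route_split) != 3L || any(route_split < 0) ||
      sum(route_split) <= 0) {
    abort("`route_split` must be 3 non-negative proportions.")
  }
  route_split <- route_split / sum(route_split)

  set.seed(seed)
  nr <- landscape$dims[1]
  min_cells <- min_spacing / landscape$cell_size
  cells <- place_points(seq_len(prod(landscape$dims)), nr, min_cells, n_sites)

  route <- sample(c("route_a", "route_b", "off_route"), n_sites,
                  replace = TRUE, prob = route_split)
  n_occ <- ifelse(route == "off_route",
                  sample(1:3, n_sites, replace = TRUE,
                         prob = c(0.2, 0.3, 0.5)),
                  3L)

  out <- tibble::tibble(
    site = seq_len(n_sites),
    x = (cells - 1L) %% nr + 1L,
    y = (cells - 1L) %/% nr + 1L,
    cell = cells,
    route = factor(route, levels = c("off_route", "route_a", "route_b")),
    n_occasions = as.integer(n_occ)
  )
  attr(out, "min_spacing") <- min_spacing
  attr(out, "cell_size") <- landscape$cell_size
  class(out) <- c("survey_design", class(out))
  out
}

#' Sample a labelled vegetation-metric table for classifier training
#'
#' Draws spatially separated points inside the unburned low-lying mask (the
#' stratum where saltwater-driven change occurs and fire does not confound
#' it), extracts the seven later-epoch vegetation metrics at those points,
#' and labels each point ghost/unaffected from the biomass-change proxy.
#' The default of 248 points mirrors the classifier-training design; the
#' default spacing is scaled to the generator's short spatial-correlation
#' length (see the methods vignette).
#'
#' @param landscape A `ghost_landscape`.
#' @param n_points Number of points.
#' @param min_spacing Minimum pairwise spacing in metres.
#' @param seed Integer seed.
#' @return A `metric_table` tibble: the seven metrics plus logical `ghost`.
#' @export
sample_metric_table <- function(landscape, n_points = 248,
                                min_spacing = 100, seed = 1) {
  stopifnot(inherits(landscape, "ghost_landscape"))
  n_points <- check_count(n_points, "n_points")
  check_seed(seed)
  set.seed(seed)
  candidates <- landscape$masks$cell[landscape$masks$lowlying]
  if (length(candidates) < n_points) {
    abort("fewer unburned low-lying cells than requested points.")
  }
  min_cells <- min_spacing / landscape$cell_size
  cells <- place_points(candidates, landscape$dims[1], min_cells, n_points)
  labels <- simulate_biomass_change(landscape)
  idx <- match(cells, landscape$later$cell)
  out <- dplyr::bind_cols(
    landscape$later[idx, metric_names()],
    tibble::tibble(ghost = labels$ghost[match(cells, labels$cell)])
  )
  out <- tibble::as_tibble(out)
  class(out) <- c("metric_table", class(out))
  out
}
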
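#' Aggregate a covariate raster to a coarser resolution
#'
#' Block-aggregates a cell-per-row raster tibble by an integer factor:
#' numeric columns become block means over valid cells, logical columns and
#' the named flag/mask columns (`burned`, `ghost`, `lowlying`) become the
#' block majority, and the cell edge length is multiplied by the factor.  Edge blocks that do not
#' divide evenly are kept and flagged through the validity mask of the
#' cells they contain.
#'
#' @param raster A `covariate_raster` (or any tibble with `x`, `y` and
#'   value columns).
#' @param factor Integer aggregation factor (e.g. 4 turns a 12-m grid into
#'   a 48-m grid).
#' @param cell_size Fine-cell edge length (m); taken from the raster's
#'   attribute when present.
#' @return A `covariate_raster` on the coarse grid.
#' @export
aggregate_raster <- function(raster, factor,
                             cell_size = attr(raster, "cell_size")) {
  factor <- check_count(factor, "factor")
  if (is.null(cell_size)) abort("`cell_size` is required.")
  df <- tibble::as_tibble(raster)
  if (!"valid" %in% names(df)) df$valid <- TRUE
  bx <- (df$x - 1L) %/% factor + 1L
  by <- (df$y - 1L) %/% factor + 1L
  gid <- (by - 1L) * max(bx) + bx
  value_cols <- setdiff(names(df), c("x", "y", "cell", "valid"))

  vn <- as.numeric(df$valid)
  n_valid <- unname(drop(rowsum(vn, gid)))   # ordered by sorted unique gid
  keys <- sort(unique(gid))
  flag_cols <- c("burned", "ghost", "lowlying")
  agg_one <- function(v, nm) {
    s <- unname(drop(rowsum(as.numeric(v) * vn, gid)))
    m <- ifelse(n_valid > 0, s / n_valid, NA_real_)
    if (is.logical(v) || nm %in% flag_cols) {
      as.numeric(m > 0.5)                    # flag column: block majority
    } else {
      m                                      # continuous: block mean
    }
  }
  out <- tibble::tibble(
    x = (keys - 1L) %% max(bx) + 1L,
    y = (keys - 1L) %/% max(bx) + 1L,
    cell = seq_along(keys)
  )
  for (col in value_cols) out[[col]] <- agg_one(df[[col]], col)
  out$valid <- n_valid > 0
  new_covariate_raster(out, cell_size * factor, attr(raster, "epoch"))
}

#' Predict per-cell occupancy probability for one species
#'
#' Applies a species' occupancy coefficients across a covariate raster:
#' psi = inverse-logit(b0 + b_mid * mid* + b_canopy * can* + b_burned *
#' burned), where mid* and can* are the raster densities standardized with
#' the constants fitted at the survey sites.
#'
#' @param raster A `covariate_raster` with `dens_mid`, `dens_canopy` and
#'   `burned` columns.
#' @param coefficients Named numeric vector (or one-row data frame) with
#'   `b0`, `b_mid`, `b_canopy`, `b_burned` (missing terms are treated as
#'   zero).
#' @param standardizers The `standardizers` attribute of a [site_design()]
#'   (a list of `c(center, scale)` per metric).
#' @param burned Optional override for the burned flag (recycled);
#'   defaults to the raster's observed status.
#' @return Tibble `x`, `y`, `cell`, `psi` over valid cells.
#' @export
predict_occupancy <- function(raster, coefficients, standardizers,
                              burned = NULL) {
  if (is.null(standardizers)) abort("`standardizers` is required.")
  cf <- as.list(coefficients)
  g <- function(nm) if (is.null(cf[[nm]]) || is.na(cf[[nm]])) 0 else
    as.numeric(cf[[nm]])
  df <- tibble::as_tibble(raster)
  if (!"valid" %in% names(df)) df$valid <- TRUE
  df <- df[df$valid, ]
  mid <- (df$dens_mid - standardizers$dens_mid[["center"]]) /
    standardizers$dens_mid[["scale"]]
  can <- (df$dens_canopy - standardizers$dens_canopy[["center"]]) /
    standardizers$dens_canopy[["scale"]]
  brn <- if (is.null(burned)) as.numeric(df$burned) else
    rep_len(as.numeric(burned), nrow(df))
  eta <- g("b0") + g("b_mid") * mid + g("b_canopy") * can +
    g("b_burned") * brn
  tibble::tibble(x = df$x, y = df$y, cell = df$cell, psi = inv_logit(eta))
}

#' Change in occupancy probability between two epochs
#'
#' @param psi_early,psi_late Prediction tibbles from [predict_occupancy()]
#'   on the same grid.
#' @return Tibble `x`, `y`, `cell`, `delta` (late minus early) over the
#'   common valid cells.
#' @export
delta_psi <- function(psi_early, psi_late) {
  if (nrow(psi_early) != nrow(psi_late) ||
      !all(psi_early$cell == psi_late$cell)) {
    common <- intersect(psi_early$cell, psi_late$cell)
    if (!length(common)) abort("prediction grids do not match.")
    psi_early <- psi_early[match(common, psi_early$cell), ]
    psi_late <- psi_late[match(common, psi_late$cell), ]
    if (!all(psi_early$x == psi_late$x & psi_early$y == psi_late$y)) {
      abort("prediction grids do not match.")
    }
  }
  tibble::tibble(
    x = psi_early$x, y = psi_early$y, cell = psi_early$cell,
    delta = psi_late$psi - psi_early$psi
  )
}

#' Classify occupancy change into habitat loss, gain, or no change
#'
#' A cell is habitat loss where the occupancy change is below `-threshold`
#' and habitat gain where it exceeds `+threshold`; both inequalities are
#' strict, so a change of exactly the threshold magnitude is classed as no
#' change.
#'
#' @param delta Tibble from [delta_psi()] (or any tibble with a `delta`
#'   column).
#' @param threshold Positive change threshold in (0, 1); default 0.3.
#' @return The input with a `change` factor column (`loss`, `none`,
#'   `gain`).
#' @export
classify_change <- function(delta, threshold = 0.3) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single value in (0, 1).")
  }
  out <- tibble::as_tibble(delta)
  out$change <- factor(
    ifelse(out$delta < -threshold, "loss",
           ifelse(out$delta > threshold, "gain", "none")),
    levels = c("loss", "none", "gain")
  )
  out
}

#' Habitat loss and gain in hectares within a stratum
#'
#' Counts loss and gain cells inside a spatial stratum and converts counts
#' to area; at the 48-m analysis resolution one cell is 0.2304 ha.  Net
#' change is gain minus loss.
#'
#' @param change Tibble from [classify_change()].
#' @param mask Optional logical vector (aligned with `change`) or vector of
#'   cell ids defining the stratum; `NULL` uses every cell.
#' @param cell_area Cell area in hectares.
#' @return Tibble `loss_ha`, `gain_ha`, `net_ha`, `n_cells`.
#' @export
summarize_area <- function(change, mask = NULL, cell_area = 0.2304) {
  df <- change
  if (!is.null(mask)) {
    if (is.logical(mask)) {
      if (length(mask) != nrow(df)) {
        abort("logical `mask` must match the change raster rows.")
      }
      df <- df[mask, ]
    } else {
      df <- df[df$cell %in% mask, ]
    }
  }
  n_loss <- sum(df$change == "loss")
  n_gain <- sum(df$change == "gain")
  ## net is computed from the cell-count difference so that counts map to
  ## areas exactly (no intermediate rounding)
  tibble::tibble(loss_ha = n_loss * cell_area, gain_ha = n_gain * cell_area,
                 net_ha = (n_gain - n_loss) * cell_area,
                 n_cells = nrow(df))
}

#' Species-level occupancy coefficients as a wide table
#'
#' Extracts per-species posterior means of the occupancy coefficients from
#' a fitted model (or posterior summary) into one row per species, the
#' form the habitat-change prediction consumes.  A table already in that
#' wide form (e.g. a `community_params` tibble of simulated truth, or any
#' data frame with `species`, `b0`, `b_mid`, `b_canopy`, `b_burned`)
#' passes through unchanged.
#'
#' @param x An `occu_fit`, a posterior-summary tibble, or a wide
#'   per-species coefficient table.
#' @return Tibble with `species`, `b0`, `b_mid`, `b_canopy`, `b_burned`.
#' @export
species_coefficients <- function(x) {
  wide_cols <- c("species", "b0", "b_mid", "b_canopy", "b_burned")
  if (inherits(x, "community_params") ||
      (is.data.frame(x) && all(wide_cols %in% names(x)))) {
    return(tibble::as_tibble(x)[, wide_cols])
  }
  summary <- if (inherits(x, "occu_fit")) summarize_posterior(x) else x
  pattern <- "^(b0|b_mid|b_canopy|b_burned)\\[(.+)\\]$"
  sub <- summary[grepl(pattern, summary$term), c("term", "mean")]
  if (!nrow(sub)) abort("no occupancy coefficient terms found.")
  sub$coef <- sub(pattern, "\\1", sub$term)
  sub$species <- sub(pattern, "\\2", sub$term)
  out <- tidyr::pivot_wider(sub[, c("species", "coef", "mean")],
                            names_from = "coef", values_from = "mean")
  suppressWarnings({
    num <- as.numeric(out$species)
    if (!anyNA(num)) out$species <- num
  })
  dplyr::arrange(out, .data$species)
}

#' Decadal habitat change by species and spatial stratum
#'
#' The full habitat-change accounting: both epochs' covariate rasters are
#' aggregated to the analysis resolution, per-species occupancy is
#' predicted for each epoch with the burned covariate held at its observed
#' status (so the difference isolates vegetation-structure change), the
#' change is thresholded, and loss/gain/net hectares are summed within
#' three strata: the whole area, the burned perimeter, and unburned
#' low-lying forest.
#'
#' @param landscape A `ghost_landscape`.
#' @param coefs Species coefficients: an `occu_fit`, posterior summary, or
#'   `community_params` (see [species_coefficients()]).
#' @param standardizers Survey-site standardization constants (the
#'   `standardizers` attribute of a [site_design()]).
#' @param threshold Occupancy-change threshold (default 0.3).
#' @param agg_factor Aggregation factor from the metric grid to the
#'   analysis grid (default 4: 12 m to 48 m).
#' @param strata Which strata to report; any of `"whole_area"`, `"burned"`,
#'   `"lowlying"` (unburned low-lying forest) and `"ghost"` (blocks with a
#'   majority of ghost-transition cells).
#' @return A `habitat_change_table` tibble: `species`, `stratum`,
#'   `loss_ha`, `gain_ha`, `net_ha`, `n_cells`.
#' @export
stratified_change <- function(landscape, coefs, standardizers,
                              threshold = 0.3, agg_factor = 4,
                              strata = c("whole_area", "burned",
                                         "lowlying")) {
  stopifnot(inherits(landscape, "ghost_landscape"))
  strata <- match.arg(strata, c("whole_area", "burned", "lowlying",
                                "ghost"), several.ok = TRUE)
  coefs <- species_coefficients(coefs)
  early <- aggregate_raster(landscape$baseline, agg_factor)
  late <- aggregate_raster(landscape$later, agg_factor)
  masks <- aggregate_raster(landscape$masks, agg_factor,
                            cell_size = landscape$cell_size)
  area <- cell_area_ha(early)

  strata <- lapply(setNames(strata, strata), function(s) {
    switch(s,
           whole_area = rep(TRUE, nrow(masks)),
           burned = as.logical(masks$burned),
           lowlying = as.logical(masks$lowlying),
           ghost = as.logical(masks$ghost))
  })

  out <- purrr::map_dfr(seq_len(nrow(coefs)), function(r) {
    cf <- coefs[r, ]
    p0 <- predict_occupancy(early, cf, standardizers)
    p1 <- predict_occupancy(late, cf, standardizers)
    ch <- classify_change(delta_psi(p0, p1), threshold)
    purrr::map_dfr(names(strata), function(s) {
      dplyr::bind_cols(
        tibble::tibble(species = cf$species, stratum = s),
        summarize_area(ch, mask = strata[[s]], cell_area = area)
      )
    })
  })
  attr(out, "threshold") <- threshold
  attr(out, "cell_area_ha") <- area
  class(out) <- c("habitat_change_table", class(out))
  out
}
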
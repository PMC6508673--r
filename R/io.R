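#' Read and write pipeline tables as plain CSV
#'
#' Long-format detection histories (`site`, `occasion`, `species`,
#' `detected`), covariate rasters (cell-per-row with `x`, `y` and value
#' columns; the cell size and epoch travel in a JSON-style header comment),
#' and habitat-change tables round-trip through ordinary CSV files so the
#' pipeline interoperates with GIS and survey tooling.
#'
#' @param x Object to write.
#' @param path File path.
#' @return `write_*` returns `path` invisibly; `read_*` returns a tibble.
#' @name ghostbirds-io
NULL

#' @rdname ghostbirds-io
#' @export
write_detections <- function(x, path) {
  stopifnot(all(c("site", "occasion", "species", "detected") %in% names(x)))
  utils::write.csv(as.data.frame(x)[, c("site", "occasion", "species",
                                        "detected")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname ghostbirds-io
#' @export
read_detections <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  if (anyNA(df$detected) || !all(df$detected %in% c(0, 1))) {
    abort("`detected` must be binary with no missing values.")
  }
  class(df) <- c("detection_data", class(df))
  df
}

#' @rdname ghostbirds-io
#' @export
write_raster_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cell_size=%s epoch=%s",
                     attr(x, "cell_size"), attr(x, "epoch")), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname ghostbirds-io
#' @export
read_raster_csv <- function(path) {
  header <- readLines(path, n = 1L)
  cell_size <- as.numeric(sub(".*cell_size=([0-9.]+).*", "\\1", header))
  epoch <- sub(".*epoch=([^ ]+).*", "\\1", header)
  df <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  new_covariate_raster(df, cell_size, epoch)
}
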
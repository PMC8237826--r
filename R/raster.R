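#' Planar single-band raster
#'
#' A minimal in-memory raster: a numeric matrix in a projected planar
#' coordinate system (meters). Row 1 is the *bottom* row, so the cell at
#' `[row, col]` has its center at `(x0 + (col - 0.5) * cell_size,
#' y0 + (row - 0.5) * cell_size)`. All gapmeter analyses share one planar
#' CRS; no geodesy is performed.
#'
#' @param values numeric matrix (row 1 = southernmost row) or a single value
#'   recycled to `nrow x ncol`.
#' @param x0,y0 coordinates of the grid origin (lower-left corner), meters.
#' @param cell_size cell edge length in meters.
#' @param nrow,ncol dimensions, required when `values` is not a matrix.
#' @return an object of class `gm_raster`.
#' @export
gm_raster <- function(values, x0 = 0, y0 = 0, cell_size = 1000,
                      nrow = NULL, ncol = NULL) {
  if (!is.matrix(values)) {
    stopifnot(!is.null(nrow), !is.null(ncol))
    values <- matrix(values, nrow = nrow, ncol = ncol)
  }
  stopifnot(is.numeric(values) || is.logical(values), cell_size > 0)
  structure(values * 1.0,
            x0 = as.numeric(x0), y0 = as.numeric(y0),
            cell_size = as.numeric(cell_size),
            class = c("gm_raster", "matrix", "array"))
}

#' @export
print.gm_raster <- function(x, ...) {
  cat(sprintf("<gm_raster %d x %d, cell %g m, origin (%g, %g)>\n",
              nrow(x), ncol(x), cell_size(x), attr(x, "x0"), attr(x, "y0")))
  invisible(x)
}

#' @rdname gm_raster
#' @param x a `gm_raster`.
#' @export
cell_size <- function(x) attr(x, "cell_size")

## keep geo attributes when a template is available
as_raster_like <- function(values, template) {
  gm_raster(values, x0 = attr(template, "x0"), y0 = attr(template, "y0"),
            cell_size = cell_size(template))
}

#' Cell-center coordinates of a raster or grid
#'
#' @param x a `gm_raster` or `gm_grid`.
#' @param cells optional vector of linear cell ids (column-major, as returned
#'   by [assign_to_grid()]); default all cells.
#' @return two-column matrix of x/y cell-center coordinates (meters).
#' @export
cell_centers <- function(x, cells = NULL) {
  nr <- if (inherits(x, "gm_grid")) x$nrow else nrow(x)
  nc <- if (inherits(x, "gm_grid")) x$ncol else ncol(x)
  s <- if (inherits(x, "gm_grid")) x$cell_size else cell_size(x)
  x0 <- if (inherits(x, "gm_grid")) x$x0 else attr(x, "x0")
  y0 <- if (inherits(x, "gm_grid")) x$y0 else attr(x, "y0")
  if (is.null(cells)) cells <- seq_len(nr * nc)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  cbind(x = x0 + (col - 0.5) * s, y = y0 + (row - 0.5) * s)
}

#' Read / write rasters as ESRI ASCII grid
#'
#' Plain-text single-band raster interchange. `NODATA_value` cells are read
#' back as `NA`.
#'
#' @param x a `gm_raster`.
#' @param path file path (conventionally `.asc`).
#' @return `read_ascii_grid` returns a `gm_raster`; `write_ascii_grid`
#'   returns `path` invisibly.
#' @export
write_ascii_grid <- function(x, path) {
  stopifnot(inherits(x, "gm_raster"))
  v <- unclass(x)
  v[is.na(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(x)),
    sprintf("nrows %d", nrow(x)),
    sprintf("xllcorner %.10g", attr(x, "x0")),
    sprintf("yllcorner %.10g", attr(x, "y0")),
    sprintf("cellsize %.10g", cell_size(x)),
    "NODATA_value -9999"), con)
  ## ASCII grid stores rows top-down
  for (i in rev(seq_len(nrow(x))))
    writeLines(paste(formatC(v[i, ], format = "g", digits = 15),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  v <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(v, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (!is.na(h["nodata_value"])) m[m == h[["nodata_value"]]] <- NA
  gm_raster(m, x0 = h[["xllcorner"]], y0 = h[["yllcorner"]],
            cell_size = h[["cellsize"]])
}
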
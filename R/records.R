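#' Occurrence records
#'
#' An occurrence data.frame carries one row per observation with columns
#' `species`, `lat`, `lon` (coordinate strings exactly as read — raw strings
#' are the unit of the precision filter), `date` (ISO string, may be empty)
#' and `source` (`"database"` or `"checklist"`). [as_occurrences()]
#' normalizes an arbitrary data.frame into this shape and adds parsed
#' numeric columns `lat_num` / `lon_num` (`NA` where unparseable).
#'
#' @param x data.frame with at least `species`, `lat`, `lon`.
#' @return occurrence data.frame.
#' @export
as_occurrences <- function(x) {
  stopifnot(all(c("species", "lat", "lon") %in% names(x)))
  out <- data.frame(species = as.character(x$species),
                    lat = as.character(x$lat),
                    lon = as.character(x$lon),
                    date = if ("date" %in% names(x)) as.character(x$date) else "",
                    source = if ("source" %in% names(x)) as.character(x$source) else "database",
                    stringsAsFactors = FALSE)
  out$lat_num <- suppressWarnings(as.numeric(out$lat))
  out$lon_num <- suppressWarnings(as.numeric(out$lon))
  out
}

#' Read / write occurrence CSV
#'
#' Coordinates are read as text so that trailing zeros (the coordinate
#' precision signal) survive.
#'
#' @param path CSV path with columns species, lat, lon, date, source.
#' @param records occurrence data.frame.
#' @return `read_occurrences` returns an occurrence data.frame.
#' @export
read_occurrences <- function(path) {
  as_occurrences(utils::read.csv(path, colClasses = "character"))
}

#' @rdname read_occurrences
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(records[, c("species", "lat", "lon", "date", "source")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

## trim + collapse whitespace + case-fold, for name keys
normalize_name <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

## digits after the decimal separator of a raw coordinate string ("," or ".")
count_decimals <- function(x) {
  x <- sub(",", ".", trimws(x), fixed = TRUE)
  has <- grepl(".", x, fixed = TRUE)
  n <- integer(length(x))
  n[has] <- nchar(sub("^[^.]*\\.", "", x[has]))
  n
}

#' Cleaning filters
#'
#' The five record-cleaning filters. Each returns
#' `list(records, removed, removed_records)`. Filters are pure and
#' composable; [clean_records()] applies them in the fixed order duplicates
#' -> precision -> extent -> centroid -> taxonomy so each discarded record
#' is charged to exactly one (first-matching) cause.
#'
#' * `deduplicate()`: drops records sharing (normalized species, raw lat,
#'   raw lon, date); the first occurrence is kept.
#' * `filter_precision()`: keeps a record only if *both* raw coordinate
#'   strings have at least `min_decimals` digits after the decimal
#'   separator (default 3, roughly 100 m); unparseable coordinates are
#'   removed here too.
#' * `filter_extent()`: keeps records inside the study polygon
#'   (boundary-inclusive).
#' * `filter_centroids()`: removes records within `radius_m` of any listed
#'   populated-place centroid (the paper-style rule "coordinates coinciding
#'   with the center of a city/village", operationalized as a distance
#'   threshold).
#' * `filter_taxonomy()`: canonicalizes accepted synonyms to their accepted
#'   name and removes names found in neither the valid list nor the synonym
#'   map.
#'
#' @param records occurrence data.frame (see [as_occurrences()]).
#' @param min_decimals minimum decimals required on both coordinates.
#' @param polygon study-area polygon (vertex matrix).
#' @param centroids two-column matrix/data.frame of centroid coordinates
#'   (same planar units as the records), or NULL/empty for identity.
#' @param radius_m centroid match radius, meters.
#' @param valid_names character vector of accepted names.
#' @param synonym_map data.frame with columns `synonym`, `accepted`.
#' @name cleaning-filters
NULL

filter_result <- function(records, keep) {
  list(records = records[keep, , drop = FALSE],
       removed = sum(!keep),
       removed_records = records[!keep, , drop = FALSE])
}

#' @rdname cleaning-filters
#' @export
deduplicate <- function(records) {
  key <- paste(normalize_name(records$species), records$lat, records$lon,
               records$date, sep = "\r")
  filter_result(records, !duplicated(key))
}

#' @rdname cleaning-filters
#' @export
filter_precision <- function(records, min_decimals = 3) {
  ok <- count_decimals(records$lat) >= min_decimals &
    count_decimals(records$lon) >= min_decimals &
    is.finite(records$lat_num) & is.finite(records$lon_num)
  filter_result(records, ok)
}

#' @rdname cleaning-filters
#' @export
filter_extent <- function(records, polygon) {
  pts <- cbind(records$lon_num, records$lat_num)
  ok <- is.finite(pts[, 1]) & is.finite(pts[, 2])
  ok[ok] <- point_in_polygon(pts[ok, , drop = FALSE], polygon)
  filter_result(records, ok)
}

#' @rdname cleaning-filters
#' @export
filter_centroids <- function(records, centroids, radius_m = 1000) {
  if (is.null(centroids) || NROW(centroids) == 0)
    return(filter_result(records, rep(TRUE, nrow(records))))
  cen <- as.matrix(centroids)[, 1:2, drop = FALSE]
  hit <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(cen))) {
    d2 <- (records$lon_num - cen[i, 1])^2 + (records$lat_num - cen[i, 2])^2
    hit <- hit | (is.finite(d2) & d2 <= radius_m^2)
  }
  filter_result(records, !hit)
}

#' @rdname cleaning-filters
#' @export
filter_taxonomy <- function(records, valid_names, synonym_map = NULL) {
  vkey <- normalize_name(valid_names)
  if (!is.null(synonym_map) && nrow(synonym_map)) {
    skey <- normalize_name(synonym_map$synonym)
    acc <- as.character(synonym_map$accepted)
    if (!all(normalize_name(acc) %in% vkey))
      stop("synonym map targets a name absent from the valid-name list")
  } else {
    skey <- character(0); acc <- character(0)
  }
  key <- normalize_name(records$species)
  i_syn <- match(key, skey)
  records$species[!is.na(i_syn)] <- acc[i_syn[!is.na(i_syn)]]
  ## report canonical capitalization for direct matches too
  i_val <- match(normalize_name(records$species), vkey)
  records$species[!is.na(i_val)] <- valid_names[i_val[!is.na(i_val)]]
  filter_result(records, !is.na(i_val))
}

#' Run the full cleaning pipeline
#'
#' Applies the five filters in the fixed order duplicates -> precision ->
#' extent -> centroid -> taxonomy and assembles a `cleaning_report` whose
#' per-filter counts are additive:
#' `input - sum(removed) = surviving`.
#'
#' @inheritParams cleaning-filters
#' @return list with `records` (cleaned, names canonicalized) and `report`
#'   (class `cleaning_report`).
#' @export
clean_records <- function(records, polygon, valid_names = NULL,
                          synonym_map = NULL, centroids = NULL,
                          min_decimals = 3, radius_m = 1000) {
  records <- as_occurrences(records)
  report <- list(input = nrow(records))
  st <- deduplicate(records); report$removed_duplicates <- st$removed
  st <- filter_precision(st$records, min_decimals)
  report$removed_precision <- st$removed
  st <- filter_extent(st$records, polygon)
  report$removed_extent <- st$removed
  st <- filter_centroids(st$records, centroids, radius_m)
  report$removed_centroid <- st$removed
  if (!is.null(valid_names)) {
    st <- filter_taxonomy(st$records, valid_names, synonym_map)
    report$removed_taxonomy <- st$removed
  } else report$removed_taxonomy <- 0L
  report$surviving <- nrow(st$records)
  stopifnot(report$input - report$removed_duplicates -
              report$removed_precision - report$removed_extent -
              report$removed_centroid - report$removed_taxonomy ==
              report$surviving)
  class(report) <- "cleaning_report"
  list(records = st$records, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Analysis grid
#'
#' An equal-area grid of half-open square cells
#' `[x, x + s) x [y, y + s)` anchored at the lower-left corner of the study
#' area. Every in-extent point maps to exactly one cell; a point exactly on
#' an interior edge belongs to the cell whose half-open interval starts at
#' that edge (`floor()` of the offset).
#'
#' @param x0,y0 grid origin (lower-left), meters.
#' @param cell_size cell edge, meters (default 1000, i.e. 1 km2 cells).
#' @param nrow,ncol grid dimensions in cells.
#' @return list of class `gm_grid`.
#' @export
grid_index <- function(x0, y0, cell_size = 1000, nrow, ncol) {
  stopifnot(cell_size > 0, nrow > 0, ncol > 0)
  structure(list(x0 = x0, y0 = y0, cell_size = cell_size,
                 nrow = as.integer(nrow), ncol = as.integer(ncol)),
            class = "gm_grid")
}

#' @rdname grid_index
#' @param raster a `gm_raster` to take geometry from.
#' @export
grid_from_raster <- function(raster) {
  grid_index(attr(raster, "x0"), attr(raster, "y0"), cell_size(raster),
             nrow = nrow(raster), ncol = ncol(raster))
}

#' Assign records to grid cells
#'
#' @param records occurrence data.frame with parsed coordinates (run the
#'   extent filter first: out-of-extent records are an error).
#' @param grid a [grid_index()].
#' @return the records with integer columns `row`, `col` and `cell`
#'   (column-major linear id) appended.
#' @export
assign_to_grid <- function(records, grid) {
  stopifnot(inherits(grid, "gm_grid"))
  col <- floor((records$lon_num - grid$x0) / grid$cell_size) + 1L
  row <- floor((records$lat_num - grid$y0) / grid$cell_size) + 1L
  if (any(!is.finite(row)) || any(!is.finite(col)) ||
      any(row < 1L | row > grid$nrow | col < 1L | col > grid$ncol))
    stop("record outside grid extent; run filter_extent() first")
  records$row <- as.integer(row)
  records$col <- as.integer(col)
  records$cell <- as.integer((col - 1L) * grid$nrow + row)
  records
}

#' Split records by cell
#'
#' @param records output of [assign_to_grid()].
#' @return named list (cell id -> character vector of species, one entry
#'   per record); empty cells are absent.
#' @export
records_by_cell <- function(records) {
  split(records$species, records$cell)
}
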
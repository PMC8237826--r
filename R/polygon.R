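#' Study-area polygons
#'
#' Polygons are plain two-column vertex matrices (x, y in meters, one ring,
#' not necessarily closed). Point-in-polygon tests are boundary-inclusive:
#' a point lying exactly on an edge or vertex counts as inside.
#'
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @return two-column vertex matrix of class `gm_polygon`.
#' @export
polygon_rect <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  structure(cbind(x = c(xmin, xmax, xmax, xmin),
                  y = c(ymin, ymin, ymax, ymax)),
            class = c("gm_polygon", "matrix", "array"))
}

as_polygon <- function(p) {
  p <- as.matrix(p)
  stopifnot(ncol(p) == 2, nrow(p) >= 3, all(is.finite(p)))
  ## drop a repeated closing vertex
  if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  structure(p, class = c("gm_polygon", "matrix", "array"))
}

#' Boundary-inclusive point-in-polygon test
#'
#' Interior membership is delegated to [mgcv::in.out()]; because the
#' behaviour of ray-casting on the boundary is unspecified, points within
#' `eps` of any polygon edge are additionally counted as inside.
#'
#' @param points two-column matrix of point coordinates.
#' @param poly polygon vertex matrix (see [polygon_rect()]).
#' @param eps boundary tolerance in map units; defaults to 1e-9 of the
#'   polygon's larger bounding-box dimension.
#' @return logical vector.
#' @export
point_in_polygon <- function(points, poly, eps = NULL) {
  poly <- as_polygon(poly)
  points <- matrix(as.numeric(points), ncol = 2)
  if (is.null(eps))
    eps <- 1e-9 * max(diff(range(poly[, 1])), diff(range(poly[, 2])))
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  inside <- mgcv::in.out(bnd, points)
  near <- dist_to_boundary(points, poly) <= eps
  inside | near
}

## min distance from each point to the polygon's edges
dist_to_boundary <- function(points, poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  d <- rep(Inf, nrow(points))
  for (i in seq_len(n)) {
    vx <- b[i, 1] - a[i, 1]; vy <- b[i, 2] - a[i, 2]
    wx <- points[, 1] - a[i, 1]; wy <- points[, 2] - a[i, 2]
    L2 <- vx * vx + vy * vy
    t <- if (L2 > 0) pmin(1, pmax(0, (wx * vx + wy * vy) / L2)) else 0
    dx <- wx - t * vx; dy <- wy - t * vy
    d <- pmin(d, sqrt(dx * dx + dy * dy))
  }
  d
}

polygon_area <- function(poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

#' Read / write a polygon as GeoJSON
#'
#' Handles a single `Polygon` geometry (outer ring only), either bare or as
#' the first feature of a `FeatureCollection`.
#'
#' @param path file path.
#' @param poly polygon vertex matrix.
#' @return `read_polygon_geojson` returns a `gm_polygon`.
#' @export
read_polygon_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(g$features)) g <- g$features$geometry
  coords <- g$coordinates
  if (is.list(coords)) coords <- coords[[1]]
  if (length(dim(coords)) == 3) coords <- coords[1, , ]
  as_polygon(coords)
}

#' @rdname read_polygon_geojson
#' @export
write_polygon_geojson <- function(poly, path) {
  poly <- as_polygon(poly)
  ring <- rbind(poly, poly[1, , drop = FALSE])
  obj <- list(type = "Polygon",
              coordinates = list(lapply(seq_len(nrow(ring)),
                                        function(i) as.numeric(ring[i, ]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
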
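#' Mean k-nearest-neighbour distances of a point pattern
#'
#' For each neighbour order `k = 1..K`, the mean over all points of the
#' distance to their k-th nearest *other* point. Duplicate points are
#' allowed (zero distances are legitimate). Planar coordinates.
#'
#' @param points two-column matrix of coordinates.
#' @param K maximum neighbour order; default `min(30, n - 1)`.
#' @return numeric vector of length `K` (non-decreasing in `k`).
#' @export
knn_distances <- function(points, K = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(K)) K <- min(30L, n - 1L)
  stopifnot(n >= K + 1, K >= 1)
  D <- as.matrix(stats::dist(points))
  diag(D) <- Inf
  ## k-th smallest per row, k = 1..K
  sorted <- apply(D, 1, function(r) sort.int(r, partial = seq_len(K))[seq_len(K)])
  rowMeans(matrix(sorted, nrow = K))
}

## n uniform points in a polygon by bounding-box rejection sampling
runif_polygon <- function(n, polygon) {
  polygon <- as_polygon(polygon)
  if (polygon_area(polygon) <= 0) stop("degenerate polygon")
  bx <- range(polygon[, 1]); by <- range(polygon[, 2])
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    cand <- cbind(stats::runif(m, bx[1], bx[2]), stats::runif(m, by[1], by[2]))
    out <- rbind(out, cand[point_in_polygon(cand, polygon), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Randomization null for average-nearest-neighbour curves
#'
#' Places `n_sites` points uniformly in the study polygon `n_iter` times and
#' summarizes the per-iteration mean k-NN curves into a quantile envelope.
#'
#' @param polygon study-area polygon (vertex matrix).
#' @param n_sites points per randomization.
#' @param K maximum neighbour order (default `min(30, n_sites - 1)`).
#' @param n_iter randomizations (default 1000).
#' @param seed integer seed.
#' @return list of class `ann_null`: `quantiles` (3 x K matrix: 2.5%, 50%,
#'   97.5%), `mean_curve` (length K), `expected_nn` (null mean 1-NN
#'   distance), `n_iter`.
#' @export
ann_null <- function(polygon, n_sites, K = NULL, n_iter = 1000, seed = 1L) {
  if (is.null(K)) K <- min(30L, n_sites - 1L)
  curves <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i)
      knn_distances(runif_polygon(n_sites, polygon), K), numeric(K))
  })
  curves <- matrix(curves, nrow = K)
  q <- apply(curves, 1, stats::quantile, probs = c(0.025, 0.5, 0.975))
  structure(list(quantiles = q, mean_curve = rowMeans(curves),
                 expected_nn = mean(curves[1, ]), n_iter = n_iter, K = K),
            class = "ann_null")
}

#' Per-site aggregation classification
#'
#' A site is aggregated when its own nearest-neighbour distance is lower
#' than the randomly expected mean nearest-neighbour distance, and
#' overdispersed when higher; ties count as aggregated.
#'
#' @param points two-column coordinate matrix of sites.
#' @param null_expected_nn null-model expected mean 1-NN distance (e.g.
#'   `ann_null(...)$expected_nn`).
#' @return fraction of aggregated sites in `[0, 1]`.
#' @export
classify_aggregation <- function(points, null_expected_nn) {
  points <- as.matrix(points)
  D <- as.matrix(stats::dist(points))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  mean(nn <= null_expected_nn)
}

#' Average-nearest-neighbour analysis
#'
#' Observed mean k-NN curve of the well-sampled sites against a
#' randomization envelope (uniform points in the study polygon), plus the
#' fraction of sites classified aggregated.
#'
#' @param points two-column coordinate matrix of sites.
#' @param polygon study-area polygon.
#' @param K maximum neighbour order (default `min(30, n - 1)`).
#' @param n_iter randomizations (default 1000).
#' @param seed integer seed.
#' @return list of class `ann_result`: `observed` (length-K curve), `null`
#'   (an `ann_null`), `aggregated_fraction`, `overdispersed_fraction`,
#'   `n_sites`.
#' @export
ann_analysis <- function(points, polygon, K = NULL, n_iter = 1000, seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(K)) K <- min(30L, n - 1L)
  observed <- knn_distances(points, K)
  nul <- ann_null(polygon, n, K, n_iter, seed)
  af <- classify_aggregation(points, nul$expected_nn)
  structure(list(observed = observed, null = nul,
                 aggregated_fraction = af,
                 overdispersed_fraction = 1 - af,
                 n_sites = n),
            class = "ann_result")
}

#' @export
print.ann_result <- function(x, ...) {
  cat(sprintf(
    "<ann_result n=%d, K=%d, aggregated %.0f%% (null mean 1-NN %.1f m, %d iters)>\n",
    x$n_sites, length(x$observed), 100 * x$aggregated_fraction,
    x$null$expected_nn, x$null$n_iter))
  invisible(x)
}
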
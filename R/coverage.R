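#' Schoener's D overlap between two frequency surfaces
#'
#' `D = 1 - 0.5 * sum(|p_i - q_i|)`, ranging from 0 (disjoint support,
#' total lack of congruence) to 1 (identical surfaces). Symmetric in its
#' arguments; inputs must share bins and each sum to 1.
#'
#' @param p,q `env_space` objects or numeric arrays of identical shape.
#' @return scalar D in `[0, 1]`.
#' @export
schoener_d <- function(p, q) {
  if (inherits(p, "env_space")) p <- p$p
  if (inherits(q, "env_space")) q <- q$q %||% q$p
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q)) stop("surfaces are on different bins")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("surfaces must each sum to 1")
  1 - 0.5 * sum(abs(p - q))
}

#' Coverage fraction of the occupied environmental surface
#'
#' Fraction of the occupied bins of the full-universe surface that contain
#' at least one sampled cell.
#'
#' @param space_all `env_space` of all cells.
#' @param space_sampled `env_space` of the sampled subset (shared bins).
#' @return scalar in `[0, 1]`.
#' @export
coverage_fraction <- function(space_all, space_sampled) {
  occ_all <- space_all$p > 0
  if (!any(occ_all)) stop("empty all-cells surface")
  if (any(dim(space_sampled$p) != dim(space_all$p)))
    stop("surfaces are on different bins")
  sum(occ_all & space_sampled$p > 0) / sum(occ_all)
}

#' Resampling null test for environmental coverage
#'
#' Compares the Schoener's D between the sampled cells and the full
#' universe against a null distribution built by repeatedly drawing the
#' same number of cells uniformly, without replacement, from the universe
#' and recomputing D. The default test is one-sided lower-tail (sampling
#' bias depresses coverage below random expectation):
#' `p = (1 + #\{D_null <= D_obs\}) / (1 + n_iter)`.
#'
#' @param scores numeric matrix (universe cells x 2 axes) defining the
#'   environmental space; bin edges come from these cells.
#' @param sampled integer indices (rows of `scores`) of the well-sampled
#'   cells; at least 2, at most `nrow(scores)`.
#' @param n_iter null draws (default 1000).
#' @param seed integer seed (null distribution is deterministic under it).
#' @param n_bins bins per axis (default 100).
#' @param alternative `"less"` (default), `"greater"` or `"two.sided"`.
#' @return list of class `overlap_result`: `d_observed`, `null_d`
#'   (length `n_iter`), `p_value`, `n_sampled_cells`, `coverage_fraction`.
#' @export
coverage_null_test <- function(scores, sampled, n_iter = 1000, seed = 1L,
                               n_bins = 100, alternative = "less") {
  scores <- as.matrix(scores)
  n_all <- nrow(scores)
  n_s <- length(sampled)
  if (n_s < 2) stop("need at least 2 well-sampled cells")
  if (n_s > n_all) stop("more well-sampled cells than universe cells")
  if (any(sampled < 1 | sampled > n_all))
    stop("sampled indices outside the universe")
  space_all <- build_env_space(scores, n_bins = n_bins)
  space_obs <- build_env_space(scores, cells = sampled,
                               edges = space_all$edges)
  d_obs <- schoener_d(space_all, space_obs)
  null_d <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      draw <- sample.int(n_all, n_s)
      schoener_d(space_all,
                 build_env_space(scores, cells = draw,
                                 edges = space_all$edges))
    }, numeric(1))
  })
  p <- switch(alternative,
    less = (1 + sum(null_d <= d_obs)) / (1 + n_iter),
    greater = (1 + sum(null_d >= d_obs)) / (1 + n_iter),
    two.sided = min(1, 2 * min((1 + sum(null_d <= d_obs)) / (1 + n_iter),
                               (1 + sum(null_d >= d_obs)) / (1 + n_iter))),
    stop("unknown alternative"))
  structure(list(d_observed = d_obs, null_d = null_d, p_value = p,
                 n_sampled_cells = n_s,
                 coverage_fraction = coverage_fraction(space_all, space_obs),
                 alternative = alternative),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result D=%.3f p=%.4g (n=%d sampled, %d null draws, %s), coverage fraction %.3f>\n",
    x$d_observed, x$p_value, x$n_sampled_cells, length(x$null_d),
    x$alternative, x$coverage_fraction))
  invisible(x)
}
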
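#' Kruskal-Wallis rank test (tie-corrected)
#'
#' Computed directly from the rank formula:
#' `H = [12 / (N(N+1)) * sum_i n_i * Rbar_i^2] - 3(N+1)`, divided by the
#' tie-correction factor `1 - sum_j (t_j^3 - t_j) / (N^3 - N)` (`t_j` = size
#' of the j-th tie group of pooled values). The p-value uses the chi-squared
#' approximation with `groups - 1` degrees of freedom. When all pooled
#' values are identical, `H = 0` and `p = 1`.
#'
#' @param groups list of numeric vectors, each non-empty.
#' @param exact if TRUE (two groups, pooled N <= 12 only) the p-value is
#'   computed by complete enumeration of group assignments instead of the
#'   chi-squared approximation.
#' @return list of class `kw_result`: `h`, `df`, `p_value`, `n` (group
#'   sizes), `tie_correction`, `exact`.
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) == 0)) stop("empty group")
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  df <- length(groups) - 1L
  if (length(unique(pooled)) < 2)
    return(structure(list(h = 0, df = df, p_value = 1,
                          n = vapply(groups, length, 1L),
                          tie_correction = NA_real_),
                     class = "kw_result"))
  r <- rank(pooled)
  rbar <- tapply(r, g, mean)
  n_i <- tapply(r, g, length)
  h <- 12 / (N * (N + 1)) * sum(n_i * rbar^2) - 3 * (N + 1)
  ties <- table(pooled)
  cf <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h <- h / cf
  p <- stats::pchisq(h, df, lower.tail = FALSE)
  if (exact) {
    if (length(groups) != 2 || N > 12)
      stop("exact mode supports two groups with pooled N <= 12")
    n1 <- length(groups[[1]])
    hstat <- function(idx) {
      r1 <- mean(r[idx]); r2 <- mean(r[-idx])
      (12 / (N * (N + 1)) * (n1 * r1^2 + (N - n1) * r2^2) - 3 * (N + 1)) / cf
    }
    hs <- utils::combn(N, n1, hstat)
    p <- mean(hs >= h - 1e-12)
  }
  structure(list(h = h, df = df, p_value = p,
                 n = as.integer(n_i), tie_correction = cf, exact = exact),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("<kw_result H=%.4g df=%d p=%.4g (n: %s)>\n",
              x$h, x$df, x$p_value, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Bias tests on environmental axes and rarity
#'
#' Two-group Kruskal-Wallis comparisons of the well-sampled cells against
#' *all* cells (the sampled cells included, matching the representative-
#' subset reading; set `exclusive = TRUE` to compare against the complement
#' instead).
#'
#' @param scores_all numeric matrix, all cells x axes.
#' @param sampled integer indices of well-sampled cells (rows of
#'   `scores_all`).
#' @param axis column (index or name) of the axis to test.
#' @param exclusive compare sampled vs non-sampled instead of sampled vs
#'   all.
#' @return a [kruskal_wallis()] result.
#' @export
axis_bias_test <- function(scores_all, sampled, axis = 1, exclusive = FALSE) {
  scores_all <- as.matrix(scores_all)
  stopifnot(all(sampled >= 1), all(sampled <= nrow(scores_all)))
  ref <- if (exclusive) scores_all[-sampled, axis] else scores_all[, axis]
  kruskal_wallis(list(scores_all[sampled, axis], ref))
}

#' @rdname axis_bias_test
#' @param rarity_all numeric vector of per-cell rarity scores (see
#'   [rarity_scores()]).
#' @export
rarity_bias_test <- function(rarity_all, sampled, exclusive = FALSE) {
  axis_bias_test(matrix(rarity_all, ncol = 1), sampled, 1, exclusive)
}

#' Per-stratum coverage and bias summary table
#'
#' For the whole study area and (optionally) each stratum — any named
#' subset of cells, e.g. bioregions — computes the Schoener's D null test,
#' the coverage fraction and the PC1/PC2/rarity Kruskal-Wallis tests.
#' Strata with fewer than 2 well-sampled cells are skipped with a logged
#' reason.
#'
#' @param scores numeric matrix, all cells x 2 axes (one environmental
#'   space).
#' @param sampled integer indices of well-sampled cells.
#' @param strata named list of integer cell-index vectors; the whole-area
#'   row is always included first.
#' @param n_iter,seed,n_bins null-test controls (see
#'   [coverage_null_test()]).
#' @return data.frame with columns `stratum`, `n_cells`, `n_well_sampled`,
#'   `d`, `d_p`, `coverage_fraction`, `pc1_h`, `pc1_p`, `pc2_h`, `pc2_p`,
#'   `rarity_h`, `rarity_p`, `skipped`.
#' @export
stratum_table <- function(scores, sampled, strata = list(),
                          n_iter = 1000, seed = 1L, n_bins = 100) {
  scores <- as.matrix(scores)
  all_strata <- c(list(all = seq_len(nrow(scores))), strata)
  rows <- lapply(seq_along(all_strata), function(i) {
    nm <- names(all_strata)[i]
    cells <- all_strata[[i]]
    smp_local <- which(cells %in% sampled)
    base <- data.frame(stratum = nm, n_cells = length(cells),
                       n_well_sampled = length(smp_local),
                       d = NA_real_, d_p = NA_real_,
                       coverage_fraction = NA_real_,
                       pc1_h = NA_real_, pc1_p = NA_real_,
                       pc2_h = NA_real_, pc2_p = NA_real_,
                       rarity_h = NA_real_, rarity_p = NA_real_,
                       skipped = FALSE, stringsAsFactors = FALSE)
    if (length(smp_local) < 2) {
      base$skipped <- TRUE
      message(sprintf("stratum '%s' skipped: %d well-sampled cell(s)",
                      nm, length(smp_local)))
      return(base)
    }
    sc <- scores[cells, , drop = FALSE]
    ov <- coverage_null_test(sc, smp_local, n_iter = n_iter,
                             seed = derive_seed(seed, i), n_bins = n_bins)
    space_all <- build_env_space(sc, n_bins = n_bins)
    rar <- rarity_scores(space_all)
    t1 <- axis_bias_test(sc, smp_local, 1)
    t2 <- axis_bias_test(sc, smp_local, 2)
    tr <- rarity_bias_test(rar, smp_local)
    base$d <- ov$d_observed; base$d_p <- ov$p_value
    base$coverage_fraction <- ov$coverage_fraction
    base$pc1_h <- t1$h; base$pc1_p <- t1$p_value
    base$pc2_h <- t2$h; base$pc2_p <- t2$p_value
    base$rarity_h <- tr$h; base$rarity_p <- tr$p_value
    base
  })
  do.call(rbind, rows)
}
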
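#' Standardized PCA with varimax rotation
#'
#' Variables are standardized to zero mean / unit variance, a PCA is fitted,
#' the first `n_components` loading vectors (eigenvectors scaled by the
#' component standard deviations) are varimax-rotated (Kaiser-normalized,
#' via [stats::varimax()]), and components are re-ordered by post-rotation
#' variance. Sign convention: the largest-magnitude loading of each
#' component is made positive, so results are deterministic.
#'
#' Rotation is orthonormal, so per-variable communalities over the retained
#' components are unchanged — the invariant the test-suite checks.
#'
#' @param x numeric matrix or data.frame, cells x variables. Rows with
#'   missing values are dropped (complete-case) and reported via the
#'   `kept_rows` field.
#' @param n_components number of axes retained (default 2).
#' @return list of class `pca_result`: `loadings` (variables x components),
#'   `scores` (kept cells x components, standardized scores), `rotation`
#'   (orthonormal matrix applied), `variance_explained` (fraction per
#'   component), `kept_rows` (row indices used), `dropped_vars`.
#' @export
pca_varimax <- function(x, n_components = 2) {
  x <- as.matrix(x)
  keep_rows <- which(stats::complete.cases(x))
  if (length(keep_rows) < 3) stop("need at least 3 complete cells")
  xm <- x[keep_rows, , drop = FALSE]
  sds <- apply(xm, 2, stats::sd)
  dropped <- colnames(xm)[sds == 0] %||% which(sds == 0)
  if (any(sds == 0)) {
    warning("dropping constant variable(s): ",
            paste(dropped, collapse = ", "))
    xm <- xm[, sds > 0, drop = FALSE]
  }
  p <- ncol(xm)
  if (p < n_components)
    stop("fewer non-constant variables than components requested")
  z <- scale(xm)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  k <- n_components
  sdev <- pc$sdev[seq_len(k)]
  ## loadings in the factor-analysis sense: eigenvector * component sd
  L <- pc$rotation[, seq_len(k), drop = FALSE] %*% diag(sdev, k)
  ok <- sdev > 1e-10 * max(pc$sdev)
  U <- matrix(0, nrow(z), k)            # standardized scores
  U[, ok] <- z %*% pc$rotation[, seq_len(k), drop = FALSE][, ok, drop = FALSE] %*%
    diag(1 / sdev[ok], sum(ok))
  rot <- diag(k)
  if (k == 2 && sum(ok) == k) {
    ## closed-form Kaiser angle: exact for a single component pair, and
    ## immune to the stalls of the iterative updates near symmetric loading
    ## patterns (where the unrotated solution is a stationary minimum)
    rot <- varimax2(L)
  } else if (k > 2 && sum(ok) == k) {
    ## multi-start iterative varimax, keeping the best criterion value
    crit <- function(R) sum(apply((L %*% R)^2, 2, stats::var))
    starts <- c(list(diag(k)),
                with_seed(760415L, lapply(1:4, function(i)
                  qr.Q(qr(matrix(stats::rnorm(k * k), k))))))
    for (R0 in starts) {
      vm <- stats::varimax(L %*% R0, normalize = TRUE, eps = 1e-10)
      cand <- R0 %*% unclass(vm$rotmat)
      if (crit(cand) > crit(rot)) rot <- cand
    }
  }
  Lr <- L %*% rot
  Ur <- U %*% rot
  ## order by post-rotation variance, descending; deterministic signs
  expl <- colSums(Lr^2) / p
  ord <- order(expl, decreasing = TRUE)
  Lr <- Lr[, ord, drop = FALSE]; Ur <- Ur[, ord, drop = FALSE]
  rot <- rot[, ord, drop = FALSE]; expl <- expl[ord]
  for (j in seq_len(k)) {
    if (Lr[which.max(abs(Lr[, j])), j] < 0) {
      Lr[, j] <- -Lr[, j]; Ur[, j] <- -Ur[, j]; rot[, j] <- -rot[, j]
    }
  }
  rownames(Lr) <- colnames(xm)
  colnames(Lr) <- colnames(Ur) <- paste0("PC", seq_len(k))
  structure(list(loadings = Lr, scores = Ur, rotation = rot,
                 variance_explained = expl, kept_rows = keep_rows,
                 dropped_vars = dropped),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result: %d cells, %d components; variance explained %s>\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$variance_explained),
                    collapse = ", ")))
  invisible(x)
}

## Kaiser's closed-form varimax angle for two components (row-normalized)
varimax2 <- function(L, normalize = TRUE) {
  h <- if (normalize) sqrt(rowSums(L^2)) else rep(1, nrow(L))
  h[h == 0] <- 1
  a <- L[, 1] / h; b <- L[, 2] / h
  u <- a^2 - b^2; v <- 2 * a * b
  p <- nrow(L)
  num <- 2 * (sum(u * v) - sum(u) * sum(v) / p)
  den <- sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2) / p
  th <- atan2(num, den) / 4
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Binned two-axis environmental space
#'
#' A 2-D frequency surface over the PC1 x PC2 plane. Bin edges are always
#' computed from the *full* cell set (or passed in via `edges`), so surfaces
#' of subsets share bins and are directly comparable — the property that
#' makes Schoener's D of a set with itself exactly 1.
#'
#' @param scores numeric matrix (cells x >= 2 axes); the full universe of
#'   cells when `edges` is NULL.
#' @param cells indices (into `scores` rows) of the subset to bin; default
#'   all rows.
#' @param n_bins bins per axis (default 100).
#' @param edges optional list `(x, y)` of bin-edge vectors from a previous
#'   call, to bin a subset on the universe's bins.
#' @return list of class `env_space`: `p` (n_bins x n_bins frequency
#'   matrix summing to 1), `edges`, `n` (cells binned), `bin_of` (linear
#'   bin index per binned cell).
#' @export
build_env_space <- function(scores, cells = NULL, n_bins = 100, edges = NULL) {
  scores <- as.matrix(scores)
  if (is.null(cells)) cells <- seq_len(nrow(scores))
  if (!length(cells)) stop("empty cell set")
  if (is.null(edges)) {
    pad <- function(r) {
      if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
      r
    }
    rx <- pad(range(scores[, 1])); ry <- pad(range(scores[, 2]))
    edges <- list(x = seq(rx[1], rx[2], length.out = n_bins + 1),
                  y = seq(ry[1], ry[2], length.out = n_bins + 1))
  }
  n_bins <- length(edges$x) - 1L
  sx <- scores[cells, 1]; sy <- scores[cells, 2]
  if (any(sx < edges$x[1] | sx > edges$x[n_bins + 1] |
          sy < edges$y[1] | sy > edges$y[n_bins + 1]))
    stop("cell outside histogram range")
  bx <- findInterval(sx, edges$x, rightmost.closed = TRUE, all.inside = TRUE)
  by <- findInterval(sy, edges$y, rightmost.closed = TRUE, all.inside = TRUE)
  bin <- (by - 1L) * n_bins + bx
  p <- matrix(tabulate(bin, n_bins * n_bins) / length(cells), n_bins, n_bins)
  structure(list(p = p, edges = edges, n = length(cells), bin_of = bin),
            class = "env_space")
}

#' Rarity scores from environmental-bin frequency
#'
#' `rarity(cell) = 1 - f(bin(cell)) / max(f)`, where `f` is the bin
#' frequency of the full-universe surface: 0 in the modal bin, approaching 1
#' for conditions found in (nearly) unique cells.
#'
#' @param space_all `env_space` of the full universe.
#' @param scores optional score matrix for the cells to score; defaults to
#'   the cells binned in `space_all`.
#' @return numeric vector of rarity values in `[0, 1]`.
#' @export
rarity_scores <- function(space_all, scores = NULL) {
  stopifnot(inherits(space_all, "env_space"))
  f <- space_all$p
  fmax <- max(f)
  bins <- if (is.null(scores)) space_all$bin_of
  else build_env_space(as.matrix(scores), edges = space_all$edges)$bin_of
  1 - f[bins] / fmax
}
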
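#' Sample-based species accumulation curve
#'
#' Treats every record as an independent sample and averages the cumulative
#' species count over `n_orders` random permutations of record order.
#'
#' @param species character vector, one entry per record (the record's
#'   species identity).
#' @param n_orders number of random accumulation orders (default 100).
#' @param seed integer seed; the curve is deterministic given it.
#' @return list of class `accumulation_curve`: `t` (1..n), `s_mean` (mean
#'   cumulative richness), `n_records`, `s_obs`.
#' @export
accumulation_curve <- function(species, n_orders = 100, seed = 1L) {
  n <- length(species)
  stopifnot(n >= 1)
  sp <- as.integer(factor(species))
  s_sum <- numeric(n)
  with_seed(seed, {
    for (i in seq_len(n_orders)) {
      perm <- sample.int(n)
      s_sum <- s_sum + cumsum(!duplicated(sp[perm]))
    }
  })
  structure(list(t = seq_len(n), s_mean = s_sum / n_orders,
                 n_records = n, s_obs = length(unique(sp))),
            class = "accumulation_curve")
}

#' Exact expected accumulation curve
#'
#' Closed-form expectation of the sample-based accumulation curve under
#' uniformly random record order:
#' `E[S(t)] = sum_s (1 - choose(n - n_s, t) / choose(n, t))`
#' with `n_s` the number of records of species `s`. Equivalent to averaging
#' over all `n!` orderings; serves as the independent oracle for
#' [accumulation_curve()].
#'
#' @inheritParams accumulation_curve
#' @return numeric vector `E[S(t)]` for `t = 1..n`.
#' @export
expected_accumulation <- function(species) {
  n <- length(species)
  counts <- table(species)
  t <- seq_len(n)
  out <- numeric(n)
  for (ns in counts) {
    ## P(species unseen after t records) = C(n-ns, t)/C(n, t)
    p_unseen <- exp(lchoose(n - ns, t) - lchoose(n, t))
    p_unseen[t > n - ns] <- 0
    out <- out + (1 - p_unseen)
  }
  out
}

#' Fit the Clench saturation model to an accumulation curve
#'
#' Least-squares fit of `S(t) = a t / (1 + b t)` to the permutation-mean
#' curve, with positivity enforced by bounded L-BFGS-B optimization and
#' analytic gradients. Initial values: `a0 = S(1)`, `b0 = a0 / S_obs`.
#' The asymptote `a/b` estimates total richness; completeness is
#' `S_obs / (a/b)` — reported raw (it may exceed 1) with a `[0, 1]`-clipped
#' copy alongside.
#'
#' @param curve an [accumulation_curve()] (or any list with `t`, `s_mean`,
#'   `s_obs`).
#' @return list of class `clench_fit`: `a`, `b`, `asymptote`,
#'   `completeness`, `completeness_clipped`, `converged`, `residual_norm`.
#' @export
fit_clench <- function(curve) {
  t <- curve$t; y <- curve$s_mean
  if (length(unique(t)) < 3 || stats::sd(y) == 0)
    stop("need >= 3 distinct sample sizes and a non-constant curve")
  obj <- function(p) {
    f <- p[1] * t / (1 + p[2] * t)
    sum((y - f)^2)
  }
  grad <- function(p) {
    den <- 1 + p[2] * t
    e <- y - p[1] * t / den
    c(-2 * sum(e * t / den),
      2 * sum(e * p[1] * t^2 / den^2))
  }
  a0 <- max(y[1], 1e-6)
  p0 <- c(a0, a0 / max(curve$s_obs, 1))
  fit <- stats::optim(p0, obj, grad, method = "L-BFGS-B",
                      lower = c(1e-10, 1e-10),
                      control = list(maxit = 1000, factr = 1e4))
  a <- fit$par[1]; b <- fit$par[2]
  asym <- a / b
  conv <- fit$convergence == 0 && is.finite(asym)
  comp <- if (conv) curve$s_obs / asym else NA_real_
  structure(list(a = a, b = b, asymptote = asym,
                 completeness = comp,
                 completeness_clipped = min(1, max(0, comp)),
                 converged = conv,
                 residual_norm = sqrt(fit$value)),
            class = "clench_fit")
}

#' @export
print.clench_fit <- function(x, ...) {
  cat(sprintf("<clench_fit a=%.4g b=%.4g asymptote=%.4g completeness=%.3f%s>\n",
              x$a, x$b, x$asymptote, x$completeness,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Two-route well-sampled classification
#'
#' A cell is well-sampled when it has more than `min_records` records *and*
#' completeness higher than `min_completeness` (both strict inequalities),
#' or when it hosts a trusted exhaustive local inventory (checklist
#' override). Classification uses the raw (unclipped) completeness.
#'
#' @param n_records record count for the cell.
#' @param completeness fitted completeness (may be `NA` when the Clench fit
#'   failed; such cells can only qualify via the inventory route).
#' @param has_trusted_inventory logical.
#' @param min_records,min_completeness thresholds (defaults 50 and 0.7).
#' @return list of class `well_sampled`: `decision` (logical) and `reason`
#'   (`"records_and_completeness"`, `"trusted_inventory"`, or
#'   `"not_well_sampled"`).
#' @export
classify_well_sampled <- function(n_records, completeness,
                                  has_trusted_inventory = FALSE,
                                  min_records = 50, min_completeness = 0.7) {
  via_completeness <- isTRUE(n_records > min_records &&
                               is.finite(completeness) &&
                               completeness > min_completeness)
  decision <- via_completeness || isTRUE(has_trusted_inventory)
  reason <- if (isTRUE(has_trusted_inventory)) "trusted_inventory"
  else if (via_completeness) "records_and_completeness"
  else "not_well_sampled"
  structure(list(decision = decision, reason = reason),
            class = "well_sampled")
}

#' Per-cell completeness table
#'
#' Runs [accumulation_curve()], [fit_clench()] and
#' [classify_well_sampled()] for every cell that holds records.
#'
#' @param cell_records named list (cell id -> species vector), e.g. from
#'   [records_by_cell()].
#' @param trusted_cells vector of cell ids hosting trusted local
#'   inventories (these may be absent from `cell_records`).
#' @param n_orders,seed accumulation-curve controls; the per-cell seed is
#'   derived from `seed` and the cell id.
#' @param min_records,min_completeness classification thresholds.
#' @return data.frame with one row per cell: `cell`, `n_records`, `s_obs`,
#'   `a`, `b`, `asymptote`, `completeness`, `converged`, `trusted`,
#'   `well_sampled`, `reason`.
#' @export
completeness_by_cell <- function(cell_records, trusted_cells = integer(0),
                                 n_orders = 100, seed = 1L,
                                 min_records = 50, min_completeness = 0.7) {
  cells <- union(names(cell_records), as.character(trusted_cells))
  rows <- lapply(cells, function(id) {
    sp <- cell_records[[id]] %||% character(0)
    n <- length(sp)
    fitvals <- list(a = NA_real_, b = NA_real_, asymptote = NA_real_,
                    completeness = NA_real_, converged = FALSE)
    if (n >= 3 && length(unique(sp)) >= 1) {
      curve <- accumulation_curve(sp, n_orders = n_orders,
                                  seed = derive_seed(seed, as.integer(id)))
      if (stats::sd(curve$s_mean) > 0) {
        f <- fit_clench(curve)
        fitvals <- f[c("a", "b", "asymptote", "completeness", "converged")]
      }
    }
    trusted <- id %in% as.character(trusted_cells)
    cls <- classify_well_sampled(n, fitvals$completeness, trusted,
                                 min_records, min_completeness)
    data.frame(cell = as.integer(id), n_records = n,
               s_obs = length(unique(sp)),
               a = fitvals$a, b = fitvals$b, asymptote = fitvals$asymptote,
               completeness = fitvals$completeness,
               converged = fitvals$converged, trusted = trusted,
               well_sampled = cls$decision, reason = cls$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$cell), , drop = FALSE]
}
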
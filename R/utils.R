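#' Seed-scoped evaluation and stage-seed derivation
#'
#' RNG discipline used throughout the package: every randomized operation
#' takes an explicit seed and evaluates under R's default Mersenne-Twister
#' stream (inversion normals, rejection sampling) without disturbing the
#' caller's RNG state — identical seed and inputs give identical output,
#' across runs and platforms. `derive_seed()` maps a master seed plus a
#' stage offset to a stage seed within 32-bit integer range.
#'
#' @param seed integer seed (`NULL` evaluates `expr` on the current stream).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
  }
  expr
}

#' @rdname with_seed
#' @param offset integer stage offset.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1009 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## z-standardize, guarding constant vectors
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
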
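## Internal helpers shared across modules.

#' Derive child seeds from a root seed
#'
#' All randomness in a multi-stage run flows from one root seed. Child seeds
#' are drawn as a fixed pseudo-random stream from the root so that adding a
#' consumer never perturbs the seeds of earlier consumers: stream `i` always
#' receives the `i`-th draw.
#'
#' @param seed Integer root seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

## evaluate expr under a local RNG state seeded with `seed` (NULL = leave RNG alone)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## row-wise log-sum-exp of a matrix (pmax chain beats apply() here)
row_logsumexp <- function(m) {
  K <- ncol(m)
  mx <- m[, 1L]
  if (K > 1L) for (k in 2L:K) mx <- pmax(mx, m[, k])
  mx + log(rowSums(exp(m - mx)))
}

## first column = sample id, remaining numeric columns = features
df_to_matrix <- function(df, id_col = 1L) {
  stopifnot(is.data.frame(df), ncol(df) >= 2)
  ids <- as.character(df[[id_col]])
  x <- as.matrix(df[, -id_col, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- ids
  x
}

matrix_to_df <- function(x, id_name = "sample_id") {
  out <- as_tibble(x)
  out <- tibble::add_column(out, !!id_name := rownames(x), .before = 1)
  out
}

check_prob_vector <- function(p, name, tol = 1e-12) {
  if (any(!is.finite(p)) || any(p < 0))
    abort(sprintf("`%s` must be a vector of non-negative finite probabilities", name))
  if (abs(sum(p) - 1) > max(tol, 1e-8))
    abort(sprintf("`%s` must sum to 1 (got %.12f)", name, sum(p)))
  invisible(p)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x))
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples.
#' Thin wrapper around [mclust::adjustedRandIndex()].
#'
#' @param x,y Label vectors of equal length.
#' @return A single number, 1 for identical partitions, about 0 at chance.
#' @export
adjusted_rand <- function(x, y) {
  stopifnot(length(x) == length(y))
  mclust::adjustedRandIndex(x, y)
}
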
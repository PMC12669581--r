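## Proteome reduction: per-protein standardization, principal-component
## summary, percentile categorization of the component scores, and
## entropy-guided selection among competing categorization schemes.
##
## Quantile convention throughout: linear interpolation between order
## statistics (stats::quantile type 7). Cutpoints are computed once on
## training scores and frozen for any external application.

#' Standardize a protein matrix to mean 0, SD 1 per protein
#'
#' Column-wise z-scores using the sample standard deviation (denominator
#' n - 1). The training means and SDs are retained so the identical
#' transformation can later be applied to an external cohort.
#'
#' @param proteins Data frame: first column sample id, remaining columns
#'   continuous protein values (no missing values).
#' @return An object of class `hfc_std`: `data` (standardized tibble),
#'   `center` and `scale` (named per-protein means and SDs).
#' @export
standardize_proteins <- function(proteins) {
  x <- df_to_matrix(proteins)
  if (anyNA(x)) abort("protein matrix must not contain missing values")
  center <- colMeans(x)
  scale <- apply(x, 2L, sd)
  zero <- names(scale)[scale <= 0 | !is.finite(scale)]
  if (length(zero))
    abort(sprintf("zero-variance protein(s): %s",
                  paste(head(zero, 10), collapse = ", ")))
  z <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
  structure(list(data = matrix_to_df(z, names(proteins)[1]),
                 center = center, scale = scale),
            class = "hfc_std")
}

## apply frozen training means/SDs to (a subset of) an external matrix
apply_standardization <- function(x, center, scale) {
  sweep(sweep(x, 2L, center[colnames(x)], "-"), 2L, scale[colnames(x)], "/")
}

#' Principal-component reduction of a standardized protein matrix
#'
#' Singular-value decomposition of the standardized matrix; components are
#' ordered by explained variance. Sign convention making the fit
#' deterministic across platforms: within each component the
#' largest-magnitude loading is made positive.
#'
#' @param std An `hfc_std` object from [standardize_proteins()].
#' @param n_components Number of components retained (20 by default; 30 is
#'   the sensitivity setting).
#' @return An object of class `hfc_pca`: `protein_ids`, frozen `center` and
#'   `scale`, `rotation` (p x C loadings), `explained_variance` (proportion
#'   per retained component), and training `scores` (tibble).
#' @export
fit_pca <- function(std, n_components = 20) {
  stopifnot(inherits(std, "hfc_std"))
  x <- df_to_matrix(std$data)
  n <- nrow(x); p <- ncol(x)
  n_components <- check_count(n_components, "n_components")
  if (n_components > min(n - 1L, p))
    abort(sprintf("n_components = %d exceeds min(n - 1, p) = %d",
                  n_components, min(n - 1L, p)))
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  ## deterministic sign: largest-|loading| entry positive per component
  flip <- vapply(seq_len(n_components), function(c) {
    v <- rot[, c]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  rot <- sweep(rot, 2L, flip, "*")
  scores <- x %*% rot
  colnames(scores) <- colnames(rot) <- paste0("PC", seq_len(n_components))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    protein_ids = colnames(x), center = std$center, scale = std$scale,
    rotation = rot, n_components = n_components,
    explained_variance = ev[seq_len(n_components)],
    scores = matrix_to_df(scores)
  ), class = "hfc_pca")
}

#' @export
print.hfc_pca <- function(x, ...) {
  cat(sprintf("<hfc_pca> %d components over %d proteins; cumulative EV %.1f%%\n",
              x$n_components, length(x$protein_ids),
              100 * sum(x$explained_variance)))
  invisible(x)
}

#' Project a (possibly external) protein matrix onto fitted components
#'
#' External cohorts measured on a different panel are projected through the
#' intersection of their protein identifiers with the training loadings,
#' after standardizing the shared proteins with the frozen TRAINING means
#' and SDs. The shared-protein fraction is reported and must reach
#' `min_shared`.
#'
#' @param pca An `hfc_pca` model.
#' @param proteins Data frame of raw protein values (first column sample id).
#' @param min_shared Minimum tolerated fraction of training proteins present
#'   (default 0.8).
#' @return Tibble of scores (sample_id + PC columns) with attribute
#'   `shared_fraction`.
#' @export
project_scores <- function(pca, proteins, min_shared = 0.8) {
  stopifnot(inherits(pca, "hfc_pca"))
  x <- df_to_matrix(proteins)
  shared <- intersect(pca$protein_ids, colnames(x))
  frac <- length(shared) / length(pca$protein_ids)
  if (length(shared) == 0L) abort("no proteins shared with the model")
  if (frac < min_shared)
    abort(sprintf("shared-protein fraction %.3f below floor %.2f", frac,
                  min_shared))
  z <- apply_standardization(x[, shared, drop = FALSE], pca$center, pca$scale)
  scores <- z %*% pca$rotation[shared, , drop = FALSE]
  out <- matrix_to_df(scores, names(proteins)[1])
  attr(out, "shared_fraction") <- frac
  out
}

#' Percentile-based categorization schemes for component scores
#'
#' Four competing schemes: `quartiles` (cuts at the 25th/50th/75th
#' percentiles, 4 categories), `deciles` (10% intervals, 10 categories),
#' and the low/middle/high groupings `p10_90` (10th and 90th) and `p20_80`
#' (20th and 80th), 3 categories each.
#'
#' @param name Scheme name.
#' @return An object of class `hfc_scheme` with `name`, `percentiles` and
#'   `n_categories` (cutpoints empty until fitted by [fit_cutpoints()]).
#' @export
categorization_scheme <- function(name = c("quartiles", "deciles", "p10_90",
                                           "p20_80")) {
  name <- match.arg(name)
  pct <- switch(name,
    quartiles = c(25, 50, 75),
    deciles   = seq(10, 90, by = 10),
    p10_90    = c(10, 90),
    p20_80    = c(20, 80))
  structure(list(name = name, percentiles = pct,
                 n_categories = length(pct) + 1L, cutpoints = NULL),
            class = "hfc_scheme")
}

#' Compute and freeze per-component cutpoints for a scheme
#'
#' Cutpoints are the scheme's percentiles of each training score column,
#' with linear interpolation between order statistics. Ties that collapse
#' adjacent cutpoints (leaving a bin empty) raise a warning; the bins are
#' retained.
#'
#' @param scores Score tibble (sample_id first column) or matrix.
#' @param scheme An `hfc_scheme`.
#' @return The scheme with `cutpoints` filled (cuts x components matrix).
#' @export
fit_cutpoints <- function(scores, scheme) {
  stopifnot(inherits(scheme, "hfc_scheme"))
  x <- if (is.data.frame(scores)) df_to_matrix(scores) else as.matrix(scores)
  cuts <- apply(x, 2L, quantile, probs = scheme$percentiles / 100,
                type = 7, names = FALSE)
  cuts <- matrix(cuts, nrow = length(scheme$percentiles),
                 dimnames = list(NULL, colnames(x)))
  if (any(apply(cuts, 2L, anyDuplicated) > 0))
    warn("tied cutpoints leave at least one empty category; bins retained")
  scheme$cutpoints <- cuts
  scheme
}

#' Categorize component scores under a scheme
#'
#' Each component is discretized at its cutpoints into codes `1..R`
#' (values above the last cutpoint take the highest code; values equal to a
#' cutpoint fall in the upper bin). If the scheme carries frozen training
#' cutpoints they are used bit-exactly; otherwise cutpoints are first fitted
#' on `scores` (training use).
#'
#' @param scores Score tibble or matrix.
#' @param scheme An `hfc_scheme`, fitted or not.
#' @return An `hfc_design` with `n_categories = scheme$n_categories` for
#'   every component.
#' @export
categorize_scores <- function(scores, scheme) {
  stopifnot(inherits(scheme, "hfc_scheme"))
  x <- if (is.data.frame(scores)) df_to_matrix(scores) else as.matrix(scores)
  if (is.null(scheme$cutpoints)) scheme <- fit_cutpoints(x, scheme)
  if (!identical(colnames(x), colnames(scheme$cutpoints)))
    abort("score columns do not match the scheme's fitted cutpoints")
  codes <- vapply(seq_len(ncol(x)), function(j)
    findInterval(x[, j], scheme$cutpoints[, j], left.open = FALSE) + 1L,
    integer(nrow(x)))
  codes <- matrix(as.integer(codes), nrow = nrow(x),
                  dimnames = list(NULL, colnames(x)))
  new_design(codes, rep(scheme$n_categories, ncol(x)),
             sample_ids = rownames(x))
}

#' Select the categorization scheme by highest relative entropy
#'
#' Fits the latent class model at a fixed candidate `K` to the design
#' produced by each scheme and returns the scheme whose fitted model has the
#' highest relative entropy. Schemes whose fit does not converge are
#' excluded with a warning. Ties are broken by fewer categories, then by
#' scheme name.
#'
#' @param scores Training score tibble or matrix.
#' @param schemes Character vector of scheme names (>= 2 unless exactly one
#'   is supplied, which is returned unchanged).
#' @param K Class count at which schemes are compared.
#' @param n_starts,max_iter,tol EM controls.
#' @param seed Optional integer seed.
#' @return A list of class `hfc_scheme_selection`: `best` (fitted
#'   `hfc_scheme`), `design` (the winning design), `table` (per-scheme
#'   entropy tibble).
#' @export
select_scheme <- function(scores, schemes = c("quartiles", "deciles",
                                              "p10_90", "p20_80"),
                          K = 3, n_starts = 20, max_iter = 500, tol = 1e-8,
                          seed = NULL) {
  stopifnot(length(schemes) >= 1)
  seeds <- split_seed(seed %||% sample.int(.Machine$integer.max, 1),
                      length(schemes))
  fitted <- lapply(schemes, function(nm) fit_cutpoints(
    scores, categorization_scheme(nm)))
  names(fitted) <- schemes
  designs <- lapply(fitted, function(s) categorize_scores(scores, s))

  if (length(schemes) == 1L) {
    return(structure(list(
      best = fitted[[1]], design = designs[[1]],
      table = tibble(scheme = schemes, n_categories =
                       fitted[[1]]$n_categories, entropy = NA_real_,
                     loglik = NA_real_, bic = NA_real_, converged = NA)),
      class = "hfc_scheme_selection"))
  }

  rows <- vector("list", length(schemes))
  for (i in seq_along(schemes)) {
    fit <- tryCatch(
      fit_lca(designs[[i]], K, n_starts, max_iter, tol, seed = seeds[i]),
      error = function(e) NULL)
    rows[[i]] <- tibble(
      scheme = schemes[i], n_categories = fitted[[i]]$n_categories,
      entropy = if (is.null(fit) || !fit$converged) NA_real_ else fit$entropy,
      loglik = if (is.null(fit)) NA_real_ else fit$loglik,
      bic = if (is.null(fit)) NA_real_ else fit$bic,
      converged = if (is.null(fit)) FALSE else fit$converged)
  }
  tab <- dplyr::bind_rows(rows)
  if (any(!tab$converged))
    warn(sprintf("scheme(s) excluded (no converged fit): %s",
                 paste(tab$scheme[!tab$converged], collapse = ", ")))
  ok <- tab[tab$converged & !is.na(tab$entropy), ]
  if (nrow(ok) == 0L) abort("no categorization scheme produced a converged fit")
  ok <- ok[order(-ok$entropy, ok$n_categories, ok$scheme), ]
  best <- ok$scheme[1]
  structure(list(best = fitted[[best]], design = designs[[best]], table = tab),
            class = "hfc_scheme_selection")
}

#' @export
print.hfc_scheme_selection <- function(x, ...) {
  cat(sprintf("<hfc_scheme_selection> best scheme: %s\n", x$best$name))
  print(x$table)
  invisible(x)
}
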
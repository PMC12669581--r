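## Categorical indicator designs: the input of the latent class engine.
## A design holds n x J 1-based category codes plus the number of categories
## per item. Both PC categorizations and clinical variables are expressed as
## designs, so combined (clinical + PC) clustering is plain column binding.

#' Construct a categorical design
#'
#' @param codes Integer matrix or data frame of 1-based category codes,
#'   samples in rows, items in columns. No missing values.
#' @param n_categories Optional integer vector giving the number of categories
#'   per item (defaults to the observed per-column maximum).
#' @param sample_ids Optional character vector of row identifiers.
#' @return An object of class `hfc_design` with elements `codes`,
#'   `n_categories`, `items`, `sample_ids`.
#' @export
new_design <- function(codes, n_categories = NULL, sample_ids = NULL) {
  if (is.data.frame(codes)) codes <- as.matrix(codes)
  if (!is.matrix(codes)) abort("`codes` must be a matrix or data frame")
  storage.mode(codes) <- "integer"
  if (anyNA(codes)) abort("design codes must not contain missing values")
  if (any(codes < 1L)) abort("design codes must be 1-based positive integers")
  items <- colnames(codes) %||% paste0("item", seq_len(ncol(codes)))
  if (is.null(n_categories)) n_categories <- apply(codes, 2L, max)
  n_categories <- as.integer(n_categories)
  if (length(n_categories) != ncol(codes))
    abort("`n_categories` must have one entry per item")
  bad <- which(apply(codes, 2L, max) > n_categories)
  if (length(bad))
    abort(sprintf("codes exceed declared categories for item(s): %s",
                  paste(items[bad], collapse = ", ")))
  if (is.null(sample_ids)) sample_ids <- rownames(codes) %||%
      paste0("S", seq_len(nrow(codes)))
  structure(
    list(codes = unname(codes), n_categories = n_categories,
         items = items, sample_ids = as.character(sample_ids)),
    class = "hfc_design"
  )
}

#' @export
print.hfc_design <- function(x, ...) {
  cat(sprintf("<hfc_design> %d samples x %d items; categories per item: %s\n",
              nrow(x$codes), length(x$items),
              paste(x$n_categories, collapse = "/")))
  invisible(x)
}

#' @export
dim.hfc_design <- function(x) dim(x$codes)

#' Column-bind two categorical designs
#'
#' Used for the combined clustering configuration, where clinical indicator
#' variables are concatenated with categorized principal-component scores.
#'
#' @param x,y `hfc_design` objects over identical samples (same order).
#' @return A single `hfc_design`.
#' @export
bind_designs <- function(x, y) {
  stopifnot(inherits(x, "hfc_design"), inherits(y, "hfc_design"))
  if (!identical(x$sample_ids, y$sample_ids))
    abort("designs must share identical sample ids in identical order")
  codes <- cbind(x$codes, y$codes)
  colnames(codes) <- make.unique(c(x$items, y$items))
  new_design(codes, c(x$n_categories, y$n_categories), x$sample_ids)
}

#' Build a design from a clinical table
#'
#' Complete-case construction: rows with a missing value in any of the chosen
#' variables are dropped (callers that must keep all rows should impute or
#' filter first).
#'
#' @param clinical Data frame, first column sample id, remaining columns
#'   integer category codes (missing allowed).
#' @param variables Character vector of variable names to include.
#' @return An `hfc_design` over the complete cases.
#' @export
design_from_clinical <- function(clinical, variables = NULL) {
  ids <- as.character(clinical[[1]])
  vars <- variables %||% names(clinical)[-1]
  miss <- setdiff(vars, names(clinical))
  if (length(miss)) abort(sprintf("variables not in table: %s",
                                  paste(miss, collapse = ", ")))
  sub <- clinical[, vars, drop = FALSE]
  keep <- complete.cases(sub)
  if (!any(keep)) abort("no complete cases for the requested variables")
  codes <- as.matrix(sub[keep, , drop = FALSE])
  ## recode each variable onto consecutive 1..R preserving numeric order
  codes <- apply(codes, 2L, function(v) as.integer(factor(v, sort(unique(v)))))
  colnames(codes) <- vars
  new_design(codes, sample_ids = ids[keep])
}

## one-hot encoding used by the EM engine; built once per design
design_onehot <- function(design) {
  R <- design$n_categories
  J <- length(R)
  n <- nrow(design$codes)
  offs <- c(0L, cumsum(R)[-J])
  M <- sum(R)
  oh <- matrix(0, n, M)
  for (j in seq_len(J)) oh[cbind(seq_len(n), offs[j] + design$codes[, j])] <- 1
  oh
}

## number of distinct response patterns (fit_lca precondition check)
n_patterns <- function(design) {
  nrow(unique(as.data.frame(design$codes)))
}
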
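## Orchestration: derive the full stratification model on a training
## protein matrix, serialize it, and apply it unchanged to external cohorts.
## Derivation sequence: standardize -> PCA -> categorize under each scheme
## -> entropy-based scheme selection -> BIC + bootstrap-LRT class-number
## selection -> final latent class fit -> maximum-posterior assignment.

#' Pipeline configuration
#'
#' @param n_components Principal components used (20; 30 is the sensitivity
#'   setting).
#' @param schemes Candidate categorization schemes.
#' @param scheme_k Class count at which scheme entropies are compared.
#' @param k_max Largest class count considered by [select_k()].
#' @param B Bootstrap replicates for the likelihood-ratio test (999).
#' @param n_starts,max_iter,tol EM controls.
#' @param alpha BLRT step-up threshold.
#' @param min_shared Minimum shared-protein fraction for external
#'   application.
#' @param horizon Follow-up truncation (years).
#' @param min_lfc,de_alpha Differential-expression gates.
#' @param seed Root seed for the run.
#' @return A list of class `hfc_config`.
#' @export
pipeline_config <- function(n_components = 20,
                            schemes = c("quartiles", "deciles", "p10_90",
                                        "p20_80"),
                            scheme_k = 3, k_max = 6, B = 999, n_starts = 20,
                            max_iter = 500, tol = 1e-8, alpha = 0.05,
                            min_shared = 0.8, horizon = 3, min_lfc = 1.0,
                            de_alpha = 0.05, seed = 1) {
  if (!n_components %in% c(20L, 30L))
    warn("n_components differs from the standard settings 20/30")
  bad <- setdiff(schemes, c("quartiles", "deciles", "p10_90", "p20_80"))
  if (length(bad)) abort(sprintf("unknown scheme(s): %s",
                                 paste(bad, collapse = ", ")))
  structure(list(n_components = as.integer(n_components), schemes = schemes,
                 scheme_k = check_count(scheme_k, "scheme_k"),
                 k_max = check_count(k_max, "k_max"),
                 B = check_count(B, "B"), n_starts = n_starts,
                 max_iter = max_iter, tol = tol, alpha = alpha,
                 min_shared = min_shared, horizon = horizon,
                 min_lfc = min_lfc, de_alpha = de_alpha,
                 seed = as.integer(seed)),
            class = "hfc_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [pipeline_config()].
#' @return An `hfc_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(config) digest::digest(unclass(config), algo = "sha1")

#' Derive the stratification model from a training protein matrix
#'
#' @param proteins Protein data frame (first column sample id) or a CSV
#'   path.
#' @param config An [pipeline_config()] (or YAML path).
#' @return An object of class `hfc_model`: frozen standardization, PCA
#'   loadings, fitted categorization scheme (with cutpoints), the final
#'   latent class model, training `assignments`, and a `report` (scheme
#'   entropy table, per-K fit table, BLRT trace, cluster sizes).
#' @export
derive_model <- function(proteins, config = pipeline_config()) {
  if (is.character(proteins))
    proteins <- readr::read_csv(proteins, show_col_types = FALSE)
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "hfc_config"))
  seeds <- split_seed(config$seed, 3L)

  std <- standardize_proteins(proteins)
  pca <- fit_pca(std, config$n_components)
  sel <- select_scheme(pca$scores, config$schemes, K = config$scheme_k,
                       n_starts = config$n_starts,
                       max_iter = config$max_iter, tol = config$tol,
                       seed = seeds[1])
  ks <- select_k(sel$design, k_max = config$k_max, B = config$B,
                 n_starts = config$n_starts, max_iter = config$max_iter,
                 tol = config$tol, alpha = config$alpha, seed = seeds[2])
  lca <- ks$model
  assignments <- assign_classes(class_posterior(lca, sel$design))

  structure(list(
    schema_version = "1.0",
    protein_ids = pca$protein_ids,
    center = pca$center, scale = pca$scale,
    rotation = pca$rotation,
    explained_variance = pca$explained_variance,
    scheme = sel$best,
    lca = lca,
    min_shared = config$min_shared,
    assignments = assignments,
    report = list(scheme_table = sel$table, fit_table = ks$fit_table,
                  blrt_trace = ks$blrt_trace, chosen_k = ks$k,
                  bic_k = ks$bic_k,
                  cluster_sizes = as.integer(table(assignments$class))),
    provenance = list(config = unclass(config),
                      config_hash = config_hash(config),
                      seed = config$seed)
  ), class = "hfc_model")
}

#' @export
print.hfc_model <- function(x, ...) {
  cat(sprintf("<hfc_model> K = %d classes | scheme %s | %d PCs over %d proteins\n",
              x$lca$K, x$scheme$name, ncol(x$rotation),
              length(x$protein_ids)))
  cat("  cluster sizes:", paste(x$report$cluster_sizes, collapse = "/"), "\n")
  invisible(x)
}

#' Apply a derived model to a (possibly external) protein matrix
#'
#' Projection uses the frozen training means/SDs and loadings restricted to
#' the shared proteins; categorization uses the frozen training cutpoints
#' bit-exactly; samples are then assigned by maximum posterior probability.
#'
#' @param model An `hfc_model` (or path to a serialized model).
#' @param proteins Protein data frame or CSV path.
#' @return A list of class `hfc_application`: `assignments` (tibble),
#'   `posterior` matrix, and `report` (shared-protein fraction, assignment
#'   confidence distribution).
#' @export
apply_model <- function(model, proteins) {
  if (is.character(model)) model <- read_model(model)
  stopifnot(inherits(model, "hfc_model"))
  if (is.character(proteins))
    proteins <- readr::read_csv(proteins, show_col_types = FALSE)
  pca_like <- structure(list(protein_ids = model$protein_ids,
                             center = model$center, scale = model$scale,
                             rotation = model$rotation),
                        class = "hfc_pca")
  scores <- project_scores(pca_like, proteins,
                           min_shared = model$min_shared %||% 0.8)
  design <- categorize_scores(scores, model$scheme)
  tau <- class_posterior(model$lca, design)
  rownames(tau) <- design$sample_ids
  assignments <- assign_classes(tau)
  structure(list(
    assignments = assignments, posterior = tau,
    report = list(shared_fraction = attr(scores, "shared_fraction"),
                  confidence = quantile(assignments$probability,
                                        c(0.05, 0.25, 0.5, 0.75, 0.95)),
                  cluster_sizes = as.integer(table(assignments$class)))
  ), class = "hfc_application")
}

#' @export
print.hfc_application <- function(x, ...) {
  cat(sprintf("<hfc_application> %d samples | shared proteins %.1f%% | sizes %s\n",
              nrow(x$assignments), 100 * x$report$shared_fraction,
              paste(x$report$cluster_sizes, collapse = "/")))
  invisible(x)
}

#' Serialize a derived model to JSON
#'
#' Human-readable versioned schema; numeric arrays are written at full
#' precision so deserialization reproduces assignments bit-exactly.
#'
#' @param model An `hfc_model`.
#' @param path Output file.
#' @param timestamp Include a creation timestamp (default FALSE so reruns
#'   are byte-identical).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, timestamp = FALSE) {
  stopifnot(inherits(model, "hfc_model"))
  lca <- model$lca
  obj <- list(
    schema_version = model$schema_version,
    protein_ids = model$protein_ids,
    center = unname(model$center), scale = unname(model$scale),
    rotation = unname(model$rotation),
    explained_variance = model$explained_variance,
    n_components = ncol(model$rotation),
    scheme = list(name = model$scheme$name,
                  percentiles = model$scheme$percentiles,
                  n_categories = model$scheme$n_categories,
                  cutpoints = unname(model$scheme$cutpoints)),
    min_shared = model$min_shared,
    lca = list(K = lca$K, pi = lca$pi, rho = unname(lca$rho),
               items = lca$items, n_categories = lca$n_categories,
               loglik = lca$loglik, n_params = lca$n_params, bic = lca$bic,
               entropy = lca$entropy),
    provenance = c(list(config_hash = model$provenance$config_hash,
                        seed = model$provenance$seed),
                   if (timestamp) list(created = format(Sys.time(), tz = "UTC"))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "columnmajor")
  invisible(path)
}

#' Read a serialized model
#'
#' @param path JSON file written by [write_model()].
#' @return An `hfc_model` (report and training assignments are not stored).
#' @export
read_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort(sprintf(
                    "cannot parse model file: %s", conditionMessage(e))))
  need <- c("schema_version", "protein_ids", "center", "scale", "rotation",
            "scheme", "lca")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    abort(sprintf("model file fails schema validation; missing: %s",
                  paste(miss, collapse = ", ")))
  p <- length(obj$protein_ids)
  ## matrices were serialized column-major (one JSON array per column), so
  ## the simplified value comes back with columns in rows: transpose
  as_mat <- function(m, nrow_target) {
    if (is.matrix(m)) t(m) else matrix(unlist(m), nrow = nrow_target)
  }
  rotation <- as_mat(obj$rotation, p)
  colnames(rotation) <- paste0("PC", seq_len(ncol(rotation)))
  rownames(rotation) <- obj$protein_ids
  cut <- as_mat(obj$scheme$cutpoints, length(obj$scheme$percentiles))
  colnames(cut) <- colnames(rotation)
  scheme <- structure(list(name = obj$scheme$name,
                           percentiles = obj$scheme$percentiles,
                           n_categories = obj$scheme$n_categories,
                           cutpoints = cut),
                      class = "hfc_scheme")
  R <- as.integer(obj$lca$n_categories)
  rho <- as_mat(obj$lca$rho, sum(R))
  colnames(rho) <- paste0("class", seq_len(obj$lca$K))
  lca <- structure(list(
    K = as.integer(obj$lca$K), pi = as.numeric(obj$lca$pi), rho = rho,
    item_index = rep(seq_along(R), R), items = obj$lca$items,
    n_categories = R, loglik = obj$lca$loglik,
    n_params = obj$lca$n_params, bic = obj$lca$bic,
    entropy = obj$lca$entropy, posterior = NULL, n = NA_integer_,
    converged = TRUE), class = "hfc_lca")
  structure(list(
    schema_version = obj$schema_version,
    protein_ids = obj$protein_ids,
    center = setNames(as.numeric(obj$center), obj$protein_ids),
    scale = setNames(as.numeric(obj$scale), obj$protein_ids),
    rotation = rotation, explained_variance = obj$explained_variance,
    scheme = scheme, lca = lca, min_shared = obj$min_shared %||% 0.8,
    assignments = NULL,
    report = NULL, provenance = obj$provenance
  ), class = "hfc_model")
}
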
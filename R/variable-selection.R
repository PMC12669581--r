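## Genetic-algorithm search over subsets of categorical clinical variables
## for the subset giving the best latent-class clustering, preceded by the
## candidate filters: drop variables above the missingness threshold,
## non-baseline variables, and all but one representative per group of
## related variables.

#' Filter clinical variables to clustering candidates
#'
#' Exclusion rules, applied in order: more than `max_missing` missingness;
#' not flagged as baseline; related-variable deduplication (one
#' representative kept per relatedness group — the variable with fewest
#' missing values, ties by name).
#'
#' @param clinical Data frame, first column sample id, remaining columns
#'   category codes with NA allowed.
#' @param meta Optional data frame with columns `variable`, `baseline`
#'   (logical) and `group` (character or NA); variables absent from `meta`
#'   are treated as baseline and unrelated.
#' @param max_missing Missingness threshold (default 0.05; strictly greater
#'   is excluded).
#' @return List with `candidates` (character vector) and `exclusions`
#'   (tibble of variable/reason).
#' @export
filter_candidates <- function(clinical, meta = NULL, max_missing = 0.05) {
  vars <- names(clinical)[-1]
  n <- nrow(clinical)
  miss <- vapply(vars, function(v) mean(is.na(clinical[[v]])), numeric(1))
  if (is.null(meta)) meta <- tibble(variable = character())
  meta_of <- function(v, field, default) {
    i <- match(v, meta$variable)
    if (is.na(i) || is.null(meta[[field]]) || is.na(meta[[field]][i]))
      default else meta[[field]][i]
  }
  excl <- list()
  keep <- character()
  for (v in vars) {
    if (miss[[v]] > max_missing) {
      excl[[v]] <- "missingness"
    } else if (!isTRUE(meta_of(v, "baseline", TRUE))) {
      excl[[v]] <- "non-baseline"
    } else keep <- c(keep, v)
  }
  ## relatedness dedup among survivors
  groups <- vapply(keep, function(v) as.character(meta_of(v, "group", NA_character_)),
                   character(1))
  for (g in unique(groups[!is.na(groups)])) {
    members <- keep[!is.na(groups) & groups == g]
    if (length(members) > 1L) {
      ord <- members[order(miss[members], members)]
      for (v in ord[-1]) excl[[v]] <- sprintf("related (group %s, kept %s)",
                                              g, ord[1])
      keep <- setdiff(keep, ord[-1])
    }
  }
  if (length(keep) == 0L) abort("no candidate variables survive filtering")
  list(candidates = keep,
       exclusions = tibble(variable = names(excl),
                           reason = unlist(excl, use.names = FALSE),
                           missingness = miss[names(excl)]))
}

#' Genetic-algorithm configuration
#'
#' @param population_size Chromosomes per generation (>= 4).
#' @param n_generations Generations to run.
#' @param crossover_rate Probability of uniform crossover per offspring pair.
#' @param mutation_rate Per-bit flip probability; `NULL` means `1/L` with L
#'   the candidate count.
#' @param elitism Number of best chromosomes copied unchanged.
#' @param K Class count used for fitness evaluation (3 by default).
#' @param fitness `"bic_diff"` (BIC of the one-class independence model
#'   minus BIC of the K-class model; larger is better) or `"entropy"`.
#' @param min_size,max_size Subset-size bounds enforced by repair.
#' @param n_starts,max_iter,tol EM controls for fitness fits.
#' @param seed Optional integer seed.
#' @return A list of class `hfc_ga_config`.
#' @export
ga_config <- function(population_size = 20, n_generations = 15,
                      crossover_rate = 0.8, mutation_rate = NULL,
                      elitism = 2, K = 3, fitness = c("bic_diff", "entropy"),
                      min_size = 2, max_size = Inf, n_starts = 10,
                      max_iter = 200, tol = 1e-6, seed = NULL) {
  fitness <- match.arg(fitness)
  population_size <- check_count(population_size, "population_size", min = 4L)
  if (crossover_rate < 0 || crossover_rate > 1 ||
      (!is.null(mutation_rate) && (mutation_rate < 0 || mutation_rate > 1)))
    abort("GA rates must lie in [0, 1]")
  structure(list(population_size = population_size,
                 n_generations = check_count(n_generations, "n_generations"),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism = check_count(elitism, "elitism", min = 0L),
                 K = check_count(K, "K"), fitness = fitness,
                 min_size = min_size, max_size = max_size,
                 n_starts = n_starts, max_iter = max_iter, tol = tol,
                 seed = seed),
            class = "hfc_ga_config")
}

## fitness of one chromosome: clustering evidence of its variable subset.
## Samples missing any of the subset's variables are dropped for this
## evaluation only.
ga_fitness <- function(mask, clinical, candidates, config, seed) {
  if (!any(mask)) return(-Inf)
  vars <- candidates[mask]
  design <- tryCatch(design_from_clinical(clinical, vars),
                     error = function(e) NULL)
  if (is.null(design) || nrow(design$codes) < 10L) return(-Inf)
  K <- min(config$K, n_patterns(design))
  seeds <- split_seed(seed, 2L)
  fitK <- tryCatch(fit_lca(design, K, config$n_starts, config$max_iter,
                           config$tol, seed = seeds[1]),
                   error = function(e) NULL)
  if (is.null(fitK)) return(-Inf)
  if (config$fitness == "entropy") return(fitK$entropy)
  fit1 <- fit_lca(design, 1L, 1L, config$max_iter, config$tol,
                  seed = seeds[2])
  fit1$bic - fitK$bic
}

#' Genetic-algorithm selection of clustering variables
#'
#' Binary-mask chromosomes over the candidate variables; fitness is the
#' clustering evidence of the chromosome's subset (by default the BIC of the
#' one-class independence model minus the BIC of the K-class latent class
#' model, so larger means stronger class structure). Tournament selection
#' (size 2), uniform crossover, per-bit mutation and elitism; subset-size
#' bounds are enforced by random repair. The best-ever chromosome is
#' returned and its fitness is non-decreasing across generations.
#'
#' @param clinical Clinical table (first column sample id).
#' @param candidates Character vector of candidate variables (>= 2), e.g.
#'   from [filter_candidates()].
#' @param config An [ga_config()].
#' @return An object of class `hfc_ga`: `selected` (character vector),
#'   `best_mask`, `best_fitness`, `history` (per-generation tibble),
#'   `population` (final masks) and the config.
#' @export
ga_select <- function(clinical, candidates, config = ga_config()) {
  stopifnot(inherits(config, "hfc_ga_config"))
  L <- length(candidates)
  if (L < 2L) abort("need at least 2 candidate variables")
  mut <- config$mutation_rate %||% (1 / L)
  P <- config$population_size
  lo <- max(1L, config$min_size)
  hi <- min(L, config$max_size)

  repair <- function(mask) {
    s <- sum(mask)
    if (s < lo) mask[sample(which(!mask), lo - s)] <- TRUE
    if (s > hi) mask[sample(which(mask), s - hi)] <- FALSE
    mask
  }

  root <- config$seed %||% sample.int(.Machine$integer.max, 1)
  gen_seeds <- split_seed(root, config$n_generations + 1L)
  ## fitness seed depends on the mask only, so re-evaluating an unchanged
  ## chromosome reproduces its fitness exactly
  mask_seed <- function(mask) {
    1L + abs(digest::digest2int(paste(which(mask), collapse = ","),
                                seed = root %% 1000003L))
  }

  pop <- with_seed(gen_seeds[1], {
    lapply(seq_len(P), function(i)
      repair(runif(L) < runif(1, 0.2, 0.8)))
  })
  evaluate <- function(pop) {
    vapply(pop, function(m)
      ga_fitness(m, clinical, candidates, config, seed = mask_seed(m)),
      numeric(1))
  }
  fit <- evaluate(pop)
  best_i <- which.max(fit)
  best <- list(mask = pop[[best_i]], fitness = fit[best_i])
  history <- tibble(generation = 0L, best_fitness = best$fitness,
                    mean_fitness = mean(fit[is.finite(fit)]),
                    best_size = sum(best$mask))

  for (g in seq_len(config$n_generations)) {
    pop_new <- with_seed(gen_seeds[g + 1L], {
      ord <- order(fit, decreasing = TRUE)
      elite <- pop[ord[seq_len(min(config$elitism, P))]]
      children <- list()
      while (length(children) < P - length(elite)) {
        tour <- function() {
          ij <- sample.int(P, 2L)
          pop[[ij[which.max(fit[ij])]]]
        }
        p1 <- tour(); p2 <- tour()
        if (runif(1) < config$crossover_rate) {
          sw <- runif(L) < 0.5
          c1 <- ifelse(sw, p2, p1)
          c2 <- ifelse(sw, p1, p2)
        } else { c1 <- p1; c2 <- p2 }
        for (ch in list(c1, c2)) {
          flip <- runif(L) < mut
          children[[length(children) + 1L]] <- repair(xor(ch, flip))
        }
      }
      c(elite, children[seq_len(P - length(elite))])
    })
    pop <- pop_new
    fit <- evaluate(pop)
    gi <- which.max(fit)
    if (fit[gi] > best$fitness)
      best <- list(mask = pop[[gi]], fitness = fit[gi])
    history <- dplyr::bind_rows(history, tibble(
      generation = g, best_fitness = best$fitness,
      mean_fitness = mean(fit[is.finite(fit)]), best_size = sum(best$mask)))
  }
  structure(list(selected = candidates[best$mask], best_mask = best$mask,
                 best_fitness = best$fitness, history = history,
                 population = pop, candidates = candidates, config = config),
            class = "hfc_ga")
}

#' @export
print.hfc_ga <- function(x, ...) {
  cat(sprintf("<hfc_ga> selected %d/%d variables (fitness %.3f): %s\n",
              length(x$selected), length(x$candidates), x$best_fitness,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Discretize a continuous clinical variable at declared cutoffs
#'
#' Half-open binning `[c_i, c_{i+1})`: a value equal to a cutoff falls in
#' the upper bin. Values below `min_support` or non-finite map to NA
#' (missing marker).
#'
#' @param values Numeric vector.
#' @param cutoffs Strictly increasing cutoff values (e.g. the conventional
#'   body-mass-index classes 25 and 30 for normal/overweight/obese).
#' @param min_support Lowest plausible value; below it the code is missing
#'   (default `-Inf`).
#' @return Integer codes `1..(length(cutoffs) + 1)` with NA for missing.
#' @export
discretize_continuous <- function(values, cutoffs, min_support = -Inf) {
  if (is.unsorted(cutoffs, strictly = TRUE))
    abort("`cutoffs` must be strictly increasing")
  code <- findInterval(values, cutoffs, left.open = FALSE) + 1L
  code[!is.finite(values) | values < min_support] <- NA_integer_
  as.integer(code)
}

#' @export
autoplot.hfc_ga <- function(object, ...) {
  ggplot(object$history, aes(x = .data$generation)) +
    geom_line(aes(y = .data$best_fitness), linewidth = 0.8) +
    geom_point(aes(y = .data$best_fitness)) +
    geom_line(aes(y = .data$mean_fitness), linetype = "dashed") +
    labs(x = "generation", y = "fitness",
         title = "GA variable selection: best (solid) and mean (dashed) fitness") +
    theme_minimal()
}
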
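## Latent class analysis of categorical indicators by EM.
##
## Model: sample i belongs to latent class k with probability pi_k; given the
## class, item j takes category r with probability rho_{jrk}, independently
## across items. The complete set of item-response probabilities is stored as
## a stacked M x K matrix (M = sum of categories over items) so that the
## E-step is a single matrix product with the one-hot coded design.

RHO_FLOOR <- 1e-6

## M-step given posterior tau; returns list(pi, log_rho, rho)
lca_mstep <- function(oh, tau, R) {
  n <- nrow(oh)
  pi <- colSums(tau) / n
  cnt <- crossprod(oh, tau)                      # M x K expected counts
  item <- rep.int(seq_along(R), R)
  tot <- rowsum(cnt, item, reorder = TRUE)       # J x K per-item totals
  rho <- cnt / pmax(tot[item, , drop = FALSE], .Machine$double.xmin)
  rho <- pmax(rho, RHO_FLOOR)                    # floor then renormalize
  rho <- rho / rowsum(rho, item, reorder = TRUE)[item, , drop = FALSE]
  list(pi = pi, rho = rho, log_rho = log(rho))
}

## E-step: class log-joint, loglik, posterior
lca_estep <- function(oh, log_pi, log_rho) {
  lj <- oh %*% log_rho
  lj <- lj + rep(log_pi, each = nrow(lj))
  lse <- row_logsumexp(lj)
  tau <- exp(lj - lse)
  list(tau = tau, loglik = sum(lse))
}

## multistart EM (compiled); returns the best-likelihood start
lca_em_run <- function(oh, R, K, n_starts, max_iter, tol) {
  out <- lca_em_multistart(oh, rep.int(seq_along(R), R), length(R), K,
                           n_starts, max_iter, tol)
  out$pi <- as.numeric(out$pi)
  out
}

#' Fit a latent class model by maximum likelihood
#'
#' Runs EM from `n_starts` random posterior initializations (independent
#' Dirichlet rows) and returns the best-likelihood solution. Classes are
#' relabeled in decreasing mixing proportion so the fit is deterministic up
#' to the seed. Item-response probabilities are floored at `1e-6` and
#' renormalized, which keeps the log-likelihood finite when a category is
#' empty within a class.
#'
#' @param design An [new_design()] object of categorical indicators.
#' @param K Number of latent classes (>= 1).
#' @param n_starts Number of random EM starts.
#' @param max_iter Maximum EM iterations per start.
#' @param tol Convergence tolerance on the log-likelihood gain.
#' @param seed Optional integer seed; the fit is bit-reproducible given it.
#' @return An object of class `hfc_lca`: mixing proportions `pi`, stacked
#'   item-response matrix `rho` (rows are item/category pairs, columns are
#'   classes), `loglik`, `n_params`, `bic`, `entropy` (relative entropy of
#'   the training posterior), training `posterior`, convergence metadata and
#'   the per-iteration log-likelihood trace of the winning start.
#' @export
fit_lca <- function(design, K, n_starts = 20, max_iter = 500, tol = 1e-8,
                    seed = NULL) {
  stopifnot(inherits(design, "hfc_design"))
  K <- check_count(K, "K")
  n <- nrow(design$codes)
  R <- design$n_categories
  if (K > n_patterns(design))
    abort(sprintf("K = %d exceeds the %d distinct response patterns", K,
                  n_patterns(design)))
  oh <- design_onehot(design)

  best <- NULL
  with_seed(seed, {
    if (K == 1L) {
      tau <- matrix(1, n, 1L)
      prm <- lca_mstep(oh, tau, R)
      es <- lca_estep(oh, 0, prm$log_rho)
      best <- list(pi = 1, rho = prm$rho, loglik = es$loglik, tau = es$tau,
                   converged = TRUE, n_iterations = 1L, trace = es$loglik)
    } else {
      best <- lca_em_run(oh, R, K, n_starts, max_iter, tol)
    }
  })
  if (!best$converged)
    warn(sprintf("EM did not converge in %d iterations; best iterate returned",
                 max_iter))

  ## canonical label order: decreasing mixing proportion
  ord <- order(best$pi, decreasing = TRUE)
  pi <- as.numeric(best$pi[ord])
  rho <- best$rho[, ord, drop = FALSE]
  tau <- best$tau[, ord, drop = FALSE]
  rownames(rho) <- unlist(lapply(seq_along(R), function(j)
    paste0(design$items[j], ":", seq_len(R[j]))))
  colnames(rho) <- colnames(tau) <- paste0("class", seq_len(K))

  n_params <- (K - 1L) + K * sum(R - 1L)
  structure(list(
    K = K, pi = pi, rho = rho, item_index = rep(seq_along(R), R),
    items = design$items, n_categories = R,
    loglik = best$loglik, n_params = n_params,
    bic = -2 * best$loglik + n_params * log(n),
    entropy = relative_entropy(tau),
    posterior = tau, n = n,
    n_starts = n_starts, seed = seed,
    converged = best$converged, n_iterations = best$n_iterations,
    loglik_trace = best$trace
  ), class = "hfc_lca")
}

#' @export
print.hfc_lca <- function(x, ...) {
  cat(sprintf("<hfc_lca> K = %d on %d samples x %d items\n", x$K, x$n,
              length(x$items)))
  cat(sprintf("  loglik %.3f | BIC %.3f | entropy %.3f | %s in %d iter\n",
              x$loglik, x$bic, x$entropy,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  cat("  pi:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

#' Posterior class-membership probabilities
#'
#' Computes `tau_ik` proportional to `pi_k * prod_j rho[j, y_ij, k]` in log
#' space and normalizes each row.
#'
#' @param object A fitted `hfc_lca` or `hfc_lpa` model.
#' @param newdata An `hfc_design` (LCA) or numeric score matrix / data frame
#'   (LPA) to score; defaults to the training data posterior.
#' @param ... Unused.
#' @return An n x K matrix of membership probabilities, rows summing to 1.
#' @export
class_posterior <- function(object, newdata = NULL, ...) {
  UseMethod("class_posterior")
}

#' @rdname class_posterior
#' @export
class_posterior.hfc_lca <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$posterior)
  stopifnot(inherits(newdata, "hfc_design"))
  if (length(newdata$n_categories) != length(object$n_categories))
    abort("design items do not match the fitted model")
  bad <- which(newdata$n_categories > object$n_categories)
  if (length(bad) || any(apply(newdata$codes, 2L, max) > object$n_categories))
    abort("design contains category codes unseen by the fitted model")
  ## re-embed codes into the model's category space
  emb <- newdata
  emb$n_categories <- object$n_categories
  oh <- design_onehot(emb)
  es <- lca_estep(oh, log(object$pi), log(object$rho))
  tau <- es$tau
  colnames(tau) <- paste0("class", seq_len(object$K))
  rownames(tau) <- newdata$sample_ids
  tau
}

#' Relative entropy of a posterior membership matrix
#'
#' `1 - sum_i sum_k (-tau_ik log tau_ik) / (n log K)`, with `0 log 0 = 0`.
#' Equals 1 for perfectly crisp assignment and 0 for uniformly uncertain
#' rows. Defined as 1 when `K = 1`.
#'
#' @param tau n x K posterior matrix with rows summing to 1.
#' @param K Number of classes; defaults to `ncol(tau)`.
#' @return A single value in `[0, 1]`.
#' @export
relative_entropy <- function(tau, K = ncol(tau)) {
  tau <- as.matrix(tau)
  if (K <= 1L) return(1)
  h <- -tau * log(tau)
  h[!is.finite(h)] <- 0
  1 - sum(h) / (nrow(tau) * log(K))
}

#' Simulate a categorical design from a fitted latent class model
#'
#' Draws a class for each sample from the mixing proportions, then item
#' responses from the class's item-response probabilities. This is the
#' parametric-bootstrap generator behind [blrt()].
#'
#' @param model A fitted `hfc_lca`.
#' @param n Number of samples to draw.
#' @param seed Optional integer seed.
#' @return An `hfc_design` with an attribute `"class"` holding the latent
#'   class draws.
#' @export
simulate_lca <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "hfc_lca"))
  R <- model$n_categories
  J <- length(R)
  offs <- c(0L, cumsum(R))
  with_seed(seed, {
    cls <- sample.int(model$K, n, replace = TRUE, prob = model$pi)
    codes <- matrix(0L, n, J)
    for (j in seq_len(J)) {
      blk <- model$rho[(offs[j] + 1L):offs[j + 1L], , drop = FALSE]
      cum <- apply(blk, 2L, cumsum)              # R_j x K
      u <- runif(n)
      codes[, j] <- 1L + colSums(cum[, cls, drop = FALSE] <
                                   matrix(u, R[j], n, byrow = TRUE))
    }
    colnames(codes) <- model$items
    out <- new_design(codes, R)
    attr(out, "class_draw") <- cls
    out
  })
}

#' Bootstrap likelihood-ratio test for k versus k + 1 classes
#'
#' Fits the `k0`- and `(k0+1)`-class models to the data, then estimates the
#' null distribution of `LR = 2 (loglik_{k0+1} - loglik_{k0})` by refitting
#' both models on `B` parametric-bootstrap datasets simulated from the fitted
#' `k0`-class model. The p-value is the rank-based
#' `(1 + #\{LR_b >= LR_obs\}) / (B + 1)`.
#'
#' Bootstrap refits reuse half the number of random starts of the observed
#' fits; a replicate whose refit fails is redrawn up to 3 times and then
#' skipped with a warning (the effective B is reported).
#'
#' @param design An `hfc_design`.
#' @param k0 Null number of classes (>= 1); the alternative is `k0 + 1`.
#' @param B Number of bootstrap replicates (999 by default).
#' @param n_starts Random starts for the observed-data fits.
#' @param max_iter,tol EM controls, as in [fit_lca()].
#' @param seed Optional integer seed driving the whole test.
#' @param fit0,fit1 Optional prefitted models for `k0` and `k0 + 1` (skips
#'   the observed-data fits; used by [select_k()]).
#' @param boot_tol,boot_max_iter EM controls for the bootstrap refits.
#'   Defaults relax the observed-data tolerance to `1e-6` and cap
#'   iterations at 200: the likelihood-ratio statistic enters a rank
#'   comparison, so its last decimals are irrelevant, and the refits are
#'   the dominant cost of the test.
#' @return An object of class `hfc_blrt`: `k0`, `k1`, `lr_obs`,
#'   `lr_boot`, `B` (requested), `B_eff` (successful replicates), `p_value`.
#' @export
blrt <- function(design, k0, B = 999, n_starts = 20, max_iter = 500,
                 tol = 1e-8, seed = NULL, fit0 = NULL, fit1 = NULL,
                 boot_tol = max(tol, 1e-6),
                 boot_max_iter = min(max_iter, 200L)) {
  k0 <- check_count(k0, "k0")
  B <- check_count(B, "B")
  seeds <- split_seed(seed %||% sample.int(.Machine$integer.max, 1), B + 2L)
  if (is.null(fit0))
    fit0 <- fit_lca(design, k0, n_starts, max_iter, tol, seed = seeds[B + 1L])
  if (is.null(fit1))
    fit1 <- fit_lca(design, k0 + 1L, n_starts, max_iter, tol, seed = seeds[B + 2L])
  lr_obs <- max(0, 2 * (fit1$loglik - fit0$loglik))

  ns_boot <- max(2L, n_starts %/% 2L)
  n <- fit0$n
  lr_boot <- rep(NA_real_, B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    sub <- split_seed(seeds[b], 4L * 3L)
    for (try in seq_len(3L)) {
      off <- (try - 1L) * 4L
      res <- tryCatch({
        bd <- simulate_lca(fit0, n, seed = sub[off + 1L])
        f0 <- suppressWarnings(fit_lca(bd, k0, ns_boot, boot_max_iter,
                                       boot_tol, seed = sub[off + 2L]))
        f1 <- suppressWarnings(fit_lca(bd, k0 + 1L, ns_boot, boot_max_iter,
                                       boot_tol, seed = sub[off + 3L]))
        max(0, 2 * (f1$loglik - f0$loglik))
      }, error = function(e) NULL)
      if (!is.null(res)) break
    }
    if (is.null(res)) n_failed <- n_failed + 1L else lr_boot[b] <- res
  }
  if (n_failed > 0L)
    warn(sprintf("%d bootstrap replicate(s) failed after retries and were skipped",
                 n_failed))
  lr_boot <- lr_boot[!is.na(lr_boot)]
  B_eff <- length(lr_boot)
  structure(list(
    k0 = k0, k1 = k0 + 1L, lr_obs = lr_obs, lr_boot = lr_boot,
    B = B, B_eff = B_eff,
    p_value = (1 + sum(lr_boot >= lr_obs)) / (B_eff + 1),
    fit0 = fit0, fit1 = fit1
  ), class = "hfc_blrt")
}

#' @export
print.hfc_blrt <- function(x, ...) {
  cat(sprintf("<hfc_blrt> %d vs %d classes: LR = %.3f, p = %.4g (B = %d)\n",
              x$k0, x$k1, x$lr_obs, x$p_value, x$B_eff))
  invisible(x)
}

#' Select the number of latent classes
#'
#' Fits models with 1 to `k_max` classes, locates the BIC-minimizing class
#' count, then tests k versus k + 1 with the bootstrap likelihood-ratio test,
#' stepping up while the test rejects at `alpha` and `k < k_max`. The full
#' decision trace (per-K fit table and every BLRT performed) is returned.
#'
#' @param design An `hfc_design`.
#' @param k_max Largest class count considered.
#' @param B Bootstrap replicates per BLRT.
#' @param n_starts,max_iter,tol EM controls.
#' @param alpha BLRT step-up threshold (0.05).
#' @param seed Optional integer seed.
#' @return An object of class `hfc_kselect`: `k` (chosen), `model` (the
#'   fitted model at the chosen K), `fit_table` (per-K loglik/BIC/entropy
#'   tibble), `blrt_trace` (tibble of tests performed), `bic_k` (the BIC
#'   optimum the step-up started from).
#' @export
select_k <- function(design, k_max, B = 999, n_starts = 20, max_iter = 500,
                     tol = 1e-8, alpha = 0.05, seed = NULL) {
  k_max <- check_count(k_max, "k_max")
  seeds <- split_seed(seed %||% sample.int(.Machine$integer.max, 1),
                      2L * k_max + 2L)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max))
    fits[[k]] <- fit_lca(design, k, n_starts, max_iter, tol, seed = seeds[k])
  fit_table <- tibble(
    K = seq_len(k_max),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    entropy = vapply(fits, `[[`, numeric(1), "entropy"),
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
  k_bic <- fit_table$K[which.min(fit_table$bic)]
  k <- k_bic
  trace <- list()
  if (k_max > 1L) {
    while (k < k_max) {
      res <- blrt(design, k, B = B, n_starts = n_starts, max_iter = max_iter,
                  tol = tol, seed = seeds[k_max + k],
                  fit0 = fits[[k]], fit1 = fits[[k + 1L]])
      trace[[length(trace) + 1L]] <- tibble(
        k0 = res$k0, k1 = res$k1, lr = res$lr_obs, B_eff = res$B_eff,
        p_value = res$p_value, rejected = res$p_value <= alpha)
      if (res$p_value > alpha) break
      k <- k + 1L
    }
  }
  structure(list(
    k = k, model = fits[[k]], bic_k = k_bic,
    fit_table = fit_table,
    blrt_trace = if (length(trace)) dplyr::bind_rows(trace) else
      tibble(k0 = integer(), k1 = integer(), lr = numeric(),
             B_eff = integer(), p_value = numeric(), rejected = logical()),
    alpha = alpha, seed = seed
  ), class = "hfc_kselect")
}

#' @export
print.hfc_kselect <- function(x, ...) {
  cat(sprintf("<hfc_kselect> chosen K = %d (BIC optimum %d)\n", x$k, x$bic_k))
  print(x$fit_table)
  if (nrow(x$blrt_trace)) print(x$blrt_trace)
  invisible(x)
}

#' Assign samples to classes by maximum posterior probability
#'
#' Argmax per posterior row; ties are broken in favour of the lowest class
#' index.
#'
#' @param tau Posterior membership matrix (or a fitted model, whose training
#'   posterior is used).
#' @return A tibble with `sample_id` (when row names exist), `class` and
#'   `probability` (the winning membership probability).
#' @export
assign_classes <- function(tau) {
  if (inherits(tau, "hfc_lca") || inherits(tau, "hfc_lpa")) tau <- tau$posterior
  tau <- as.matrix(tau)
  cls <- max.col(tau, ties.method = "first")
  out <- tibble(class = cls,
                probability = tau[cbind(seq_len(nrow(tau)), cls)])
  if (!is.null(rownames(tau)))
    out <- tibble::add_column(out, sample_id = rownames(tau), .before = 1)
  out
}

#' @export
tidy.hfc_lca <- function(x, ...) {
  tibble(
    item = x$items[x$item_index],
    category = unlist(lapply(x$n_categories, seq_len)),
    tibble::as_tibble(x$rho)
  ) |>
    tidyr::pivot_longer(dplyr::starts_with("class"), names_to = "class",
                        names_prefix = "class", values_to = "rho") |>
    dplyr::mutate(class = as.integer(.data$class)) |>
    dplyr::arrange(.data$class, .data$item, .data$category)
}

#' @export
glance.hfc_lca <- function(x, ...) {
  tibble(K = x$K, n = x$n, loglik = x$loglik, n_params = x$n_params,
         bic = x$bic, entropy = x$entropy, converged = x$converged,
         n_iterations = x$n_iterations)
}
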
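## Moderated differential expression across clusters.
##
## Per-protein linear model on cluster indicators; residual variances are
## shrunk toward a common prior by empirical Bayes. The prior degrees of
## freedom d0 and prior variance s0^2 are estimated by closed-form moment
## matching on the log residual variances: with d residual df,
##   e_g = log s_g^2 - digamma(d/2) + log(d/2)
## has Var(e_g) = trigamma(d/2) + trigamma(d0/2), so d0 solves a trigamma
## inversion and s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2)). The
## moderated variance is s~^2 = (d0 s0^2 + d s_g^2) / (d0 + d) with
## d0 + d degrees of freedom.

## Newton inversion of trigamma (y > 0 -> x with trigamma(x) = y)
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-12) break
  }
  x
}

#' Empirical-Bayes moderated statistics across clusters
#'
#' One-vs-rest contrasts per cluster: the log2 fold change of cluster k is
#' the mean in k minus the mean of all remaining samples (on the scale of
#' the supplied matrix — standardized when the clustering-scale matrix is
#' passed). The overall test is a moderated F across clusters; per-contrast
#' moderated t statistics use the shrunken variance.
#'
#' @param proteins Data frame, first column sample id, remaining columns
#'   protein values.
#' @param labels Integer/factor cluster labels aligned with the rows.
#' @param shrink Apply empirical-Bayes shrinkage (default TRUE). `FALSE`
#'   sets d0 = 0, recovering ordinary per-protein statistics.
#' @return A tibble of class `hfc_de_stats`: per protein the per-cluster
#'   `lfc_k` and `t_k` columns, `max_abs_lfc`, raw variance `s2`, moderated
#'   variance `s2_tilde`, moderated `f_stat`, and `p_value` (from the
#'   moderated F). Attributes `d0`, `s0_sq`, `df_residual`, `df_total`,
#'   `cluster_means`.
#' @export
moderated_stats <- function(proteins, labels, shrink = TRUE) {
  x <- df_to_matrix(proteins)
  labels <- as.integer(factor(labels))
  if (length(labels) != nrow(x))
    abort("`labels` must align with the protein matrix rows")
  K <- max(labels)
  nk <- tabulate(labels, K)
  if (K < 2L) abort("need >= 2 clusters")
  if (any(nk < 2L)) abort("every cluster needs >= 2 samples")
  n <- nrow(x); p <- ncol(x)
  d <- n - K

  ## group means (K x p) via indicator crossproduct
  G <- matrix(0, n, K); G[cbind(seq_len(n), labels)] <- 1
  means <- crossprod(G, x) / nk
  rss <- colSums(x^2) - colSums(nk * means^2)
  s2 <- pmax(rss / d, .Machine$double.xmin)

  if (shrink) {
    e <- log(s2) - digamma(d / 2) + log(d / 2)
    ev <- var(e)
    dif <- ev - trigamma(d / 2)
    if (is.finite(dif) && dif > 0) {
      d0 <- 2 * trigamma_inverse(dif)
      s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(mean(e))
    }
  } else {
    d0 <- 0
    s0_sq <- NA_real_
  }
  s2_tilde <- if (is.infinite(d0)) rep(s0_sq, p) else if (d0 == 0) s2 else
    (d0 * s0_sq + d * s2) / (d0 + d)
  df_total <- d0 + d

  grand <- colMeans(x)
  ms_between <- colSums(nk * sweep(means, 2L, grand, "-")^2) / (K - 1)
  f_stat <- ms_between / s2_tilde
  p_value <- pf(f_stat, K - 1, df_total, lower.tail = FALSE)

  out <- tibble(protein = colnames(x))
  for (k in seq_len(K)) {
    rest <- (n * grand - nk[k] * means[k, ]) / (n - nk[k])
    lfc <- means[k, ] - rest
    se <- sqrt(s2_tilde * (1 / nk[k] + 1 / (n - nk[k])))
    out[[paste0("lfc_", k)]] <- unname(lfc)
    out[[paste0("t_", k)]] <- unname(lfc / se)
  }
  out$max_abs_lfc <- do.call(pmax, lapply(seq_len(K), function(k)
    abs(out[[paste0("lfc_", k)]])))
  out$s2 <- unname(s2)
  out$s2_tilde <- unname(s2_tilde)
  out$f_stat <- unname(f_stat)
  out$p_value <- unname(p_value)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "df_residual") <- d
  attr(out, "df_total") <- df_total
  attr(out, "cluster_means") <- means
  class(out) <- c("hfc_de_stats", class(out))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p P-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Flag differentially expressed proteins and assign them to clusters
#'
#' A protein is flagged when its BH-adjusted p-value is below `alpha` AND
#' its maximum absolute one-vs-rest log2 fold change reaches `min_lfc`
#' (defaults 0.05 and 1.0; the preset `min_lfc = 0.7` used upstream of
#' enrichment analyses is available by argument). Each flagged protein is
#' assigned to the cluster with the highest mean expression.
#'
#' @param stats Output of [moderated_stats()].
#' @param alpha Adjusted-p threshold.
#' @param min_lfc Absolute log2-fold-change threshold.
#' @return A tibble of class `hfc_de` adding `adj_p_value`, `flagged` and
#'   `assigned_cluster` (NA unless flagged).
#' @export
flag_and_assign <- function(stats, alpha = 0.05, min_lfc = 1.0) {
  stopifnot(inherits(stats, "hfc_de_stats"))
  means <- attr(stats, "cluster_means")
  out <- dplyr::mutate(
    as_tibble(stats),
    adj_p_value = bh_adjust(.data$p_value),
    flagged = .data$adj_p_value < alpha & .data$max_abs_lfc >= min_lfc,
    assigned_cluster = ifelse(.data$flagged,
                              apply(means, 2L, which.max), NA_integer_))
  attr(out, "d0") <- attr(stats, "d0")
  attr(out, "s0_sq") <- attr(stats, "s0_sq")
  attr(out, "alpha") <- alpha
  attr(out, "min_lfc") <- min_lfc
  class(out) <- c("hfc_de", class(out))
  out
}

#' One-call differential expression across clusters
#'
#' [moderated_stats()] followed by [flag_and_assign()].
#'
#' @inheritParams moderated_stats
#' @inheritParams flag_and_assign
#' @return An `hfc_de` tibble.
#' @export
de_analysis <- function(proteins, labels, alpha = 0.05, min_lfc = 1.0,
                        shrink = TRUE) {
  flag_and_assign(moderated_stats(proteins, labels, shrink = shrink),
                  alpha = alpha, min_lfc = min_lfc)
}

#' @export
autoplot.hfc_de <- function(object, ...) {
  dat <- dplyr::mutate(as_tibble(object),
                       neglog_p = -log10(pmax(.data$adj_p_value, 1e-300)))
  ggplot(dat, aes(x = .data$max_abs_lfc, y = .data$neglog_p,
                  colour = .data$flagged)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = -log10(attr(object, "alpha")),
               linetype = "dashed") +
    geom_vline(xintercept = attr(object, "min_lfc"), linetype = "dashed") +
    labs(x = "max |log2 fold change| (one-vs-rest)",
         y = "-log10 adjusted p", colour = "flagged") +
    theme_minimal()
}
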
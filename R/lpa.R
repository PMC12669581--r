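## Latent profile analysis: the Gaussian-mixture analogue of the latent
## class model, operating directly on continuous principal-component scores
## (no categorization). Sensitivity variant of the categorical engine with
## the same posterior / assignment / BIC contracts.

lpa_logdens <- function(x, mu, sigma, covariance) {
  n <- nrow(x); K <- nrow(mu); d <- ncol(x)
  ld <- matrix(0, n, K)
  if (covariance == "diagonal") {
    for (k in seq_len(K)) {
      z <- sweep(x, 2L, mu[k, ], "-")
      v <- sigma[k, ]
      ld[, k] <- -0.5 * (d * log(2 * pi) + sum(log(v)) +
                           rowSums(sweep(z^2, 2L, v, "/")))
    }
  } else {                                       # shared_full
    ch <- chol(sigma)
    logdet <- 2 * sum(log(diag(ch)))
    for (k in seq_len(K)) {
      z <- forwardsolve(t(ch), t(sweep(x, 2L, mu[k, ], "-")))
      ld[, k] <- -0.5 * (d * log(2 * pi) + logdet + colSums(z^2))
    }
  }
  ld
}

## regularize a covariance towards validity; warns when it has to act
lpa_ridge <- function(sigma, covariance) {
  if (covariance == "diagonal") {
    if (any(sigma < 1e-8)) {
      warn("near-singular class variance; ridge regularization applied")
      sigma <- pmax(sigma, 1e-8)
    }
  } else {
    ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
    if (!ok || any(diag(sigma) < 1e-8)) {
      warn("near-singular covariance; ridge regularization applied")
      sigma <- sigma + diag(1e-6 + 1e-6 * mean(diag(sigma)), ncol(sigma))
    }
  }
  sigma
}

lpa_mstep <- function(x, tau, covariance) {
  n <- nrow(x); d <- ncol(x); K <- ncol(tau)
  nk <- colSums(tau)
  pi <- nk / n
  mu <- crossprod(tau, x) / nk
  if (covariance == "diagonal") {
    sigma <- matrix(0, K, d)
    for (k in seq_len(K)) {
      z <- sweep(x, 2L, mu[k, ], "-")
      sigma[k, ] <- colSums(tau[, k] * z^2) / nk[k]
    }
  } else {
    sigma <- matrix(0, d, d)
    for (k in seq_len(K)) {
      z <- sweep(x, 2L, mu[k, ], "-")
      sigma <- sigma + crossprod(z * tau[, k], z)
    }
    sigma <- sigma / n
  }
  list(pi = pi, mu = mu, sigma = lpa_ridge(sigma, covariance))
}

lpa_em_once <- function(x, K, covariance, max_iter, tol) {
  n <- nrow(x)
  g <- matrix(rgamma(n * K, 1), n, K)
  tau <- g / rowSums(g)
  prm <- lpa_mstep(x, tau, covariance)
  ll_old <- -Inf; trace <- numeric(0); converged <- FALSE; iter <- 0L
  repeat {
    iter <- iter + 1L
    lj <- sweep(lpa_logdens(x, prm$mu, prm$sigma, covariance), 2L,
                log(prm$pi), "+")
    lse <- row_logsumexp(lj)
    tau <- exp(lj - lse)
    trace[iter] <- sum(lse)
    if (trace[iter] - ll_old < tol && iter > 1L) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ll_old <- trace[iter]
    prm <- lpa_mstep(x, tau, covariance)
  }
  c(prm, list(loglik = trace[iter], tau = tau, converged = converged,
              n_iterations = iter, trace = trace))
}

#' Fit a latent profile (Gaussian mixture) model
#'
#' EM for a finite Gaussian mixture on continuous scores, with either
#' class-specific diagonal covariances or one full covariance shared across
#' classes. Used as the sensitivity variant that avoids categorizing the
#' principal components. Near-singular covariances are ridge-regularized
#' with a warning.
#'
#' @param scores Numeric matrix or data frame of continuous scores (if a
#'   data frame whose first column is character, it is taken as sample ids).
#' @param K Number of profiles (>= 1).
#' @param covariance `"diagonal"` (default) or `"shared_full"`.
#' @param n_starts,max_iter,tol,seed EM controls as in [fit_lca()].
#' @return An object of class `hfc_lpa` with `pi`, `mu` (K x d), `sigma`,
#'   `loglik`, `n_params`, `bic`, `entropy`, training `posterior` and the
#'   winning start's log-likelihood trace.
#' @export
fit_lpa <- function(scores, K, covariance = c("diagonal", "shared_full"),
                    n_starts = 10, max_iter = 500, tol = 1e-8, seed = NULL) {
  covariance <- match.arg(covariance)
  if (is.data.frame(scores)) {
    scores <- if (is.character(scores[[1]])) df_to_matrix(scores) else
      as.matrix(scores)
  }
  K <- check_count(K, "K")
  x <- unname(as.matrix(scores)); storage.mode(x) <- "double"
  n <- nrow(x); d <- ncol(x)

  best <- NULL
  with_seed(seed, {
    if (K == 1L) {
      tau <- matrix(1, n, 1L)
      prm <- lpa_mstep(x, tau, covariance)
      ll <- sum(sweep(lpa_logdens(x, prm$mu, prm$sigma, covariance), 2L,
                      log(prm$pi), "+"))
      best <- c(prm, list(loglik = ll, tau = tau, converged = TRUE,
                          n_iterations = 1L, trace = ll))
    } else {
      for (s in seq_len(n_starts)) {
        fit <- lpa_em_once(x, K, covariance, max_iter, tol)
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
      }
    }
  })
  ord <- order(best$pi, decreasing = TRUE)
  pi <- as.numeric(best$pi[ord])
  mu <- best$mu[ord, , drop = FALSE]
  sigma <- if (covariance == "diagonal") best$sigma[ord, , drop = FALSE] else
    best$sigma
  tau <- best$tau[, ord, drop = FALSE]
  colnames(tau) <- paste0("class", seq_len(K))
  if (!is.null(rownames(scores))) rownames(tau) <- rownames(scores)

  n_params <- (K - 1L) + K * d +
    if (covariance == "diagonal") K * d else d * (d + 1L) / 2L
  structure(list(
    K = K, pi = pi, mu = mu, sigma = sigma, covariance = covariance,
    d = d, n = n, loglik = best$loglik, n_params = n_params,
    bic = -2 * best$loglik + n_params * log(n),
    entropy = relative_entropy(tau), posterior = tau,
    converged = best$converged, n_iterations = best$n_iterations,
    loglik_trace = best$trace, seed = seed
  ), class = "hfc_lpa")
}

#' @rdname class_posterior
#' @export
class_posterior.hfc_lpa <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$posterior)
  if (is.data.frame(newdata)) {
    newdata <- if (is.character(newdata[[1]])) df_to_matrix(newdata) else
      as.matrix(newdata)
  }
  x <- as.matrix(newdata)
  if (ncol(x) != object$d) abort("score dimension does not match the model")
  lj <- sweep(lpa_logdens(x, object$mu, object$sigma, object$covariance), 2L,
              log(object$pi), "+")
  tau <- exp(lj - row_logsumexp(lj))
  colnames(tau) <- paste0("class", seq_len(object$K))
  if (!is.null(rownames(x))) rownames(tau) <- rownames(x)
  tau
}

#' @export
print.hfc_lpa <- function(x, ...) {
  cat(sprintf("<hfc_lpa> K = %d (%s covariance) on %d samples x %d dims\n",
              x$K, x$covariance, x$n, x$d))
  cat(sprintf("  loglik %.3f | BIC %.3f | entropy %.3f\n", x$loglik, x$bic,
              x$entropy))
  invisible(x)
}

#' @export
glance.hfc_lpa <- function(x, ...) {
  tibble(K = x$K, covariance = x$covariance, n = x$n, loglik = x$loglik,
         n_params = x$n_params, bic = x$bic, entropy = x$entropy,
         converged = x$converged, n_iterations = x$n_iterations)
}
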
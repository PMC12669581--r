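# Shared fixtures and independent oracles, built in code at test time.

# small categorical design from explicit codes
make_design <- function(codes, R = NULL) {
  new_design(as.matrix(codes), n_categories = R)
}

# brute-force LCA log-likelihood maximization for tiny designs:
# direct optimization over unconstrained parameters via multistart optim,
# independent of the EM code path.
brute_force_lca_loglik <- function(codes, K, n_restarts = 40, seed = 99) {
  codes <- as.matrix(codes)
  J <- ncol(codes)
  R <- apply(codes, 2L, max)
  n <- nrow(codes)
  softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }
  unpack <- function(par) {
    pi <- softmax(c(0, par[seq_len(K - 1)]))
    idx <- K - 1L
    rho <- vector("list", J)
    for (j in seq_len(J)) {
      rho[[j]] <- matrix(0, R[j], K)
      for (k in seq_len(K)) {
        z <- c(0, par[idx + seq_len(R[j] - 1L)])
        idx <- idx + R[j] - 1L
        rho[[j]][, k] <- softmax(z)
      }
    }
    list(pi = pi, rho = rho)
  }
  npar <- (K - 1L) + K * sum(R - 1L)
  negll <- function(par) {
    pr <- unpack(par)
    ll <- 0
    for (i in seq_len(n)) {
      li <- 0
      for (k in seq_len(K)) {
        term <- pr$pi[k]
        for (j in seq_len(J)) term <- term * pr$rho[[j]][codes[i, j], k]
        li <- li + term
      }
      ll <- ll + log(li)
    }
    -ll
  }
  set.seed(seed)
  best <- Inf
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(
      optim(rnorm(npar, sd = 2), negll, method = "BFGS",
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value < best) best <- fit$value
  }
  -best
}

# exhaustive-pair Harrell concordance oracle
harrell_c_oracle <- function(time, event, score) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # usable when the shorter observed time is an event
    if (time[i] == time[j]) {
      if (event[i] == 1 && event[j] == 1) next  # tied event times: unusable (standard Harrell)
      next
    }
    short <- if (time[i] < time[j]) i else j
    long <- if (time[i] < time[j]) j else i
    if (event[short] != 1) next
    den <- den + 1
    if (score[short] > score[long]) num <- num + 1
    else if (score[short] == score[long]) num <- num + 0.5
  }
  num / den
}

# hand log-rank oracle (unweighted, G groups) via observed-minus-expected
logrank_oracle <- function(time, event, group) {
  group <- as.integer(factor(group))
  G <- max(group)
  tt <- sort(unique(time[event == 1]))
  O <- numeric(G); E <- numeric(G)
  V <- matrix(0, G, G)
  for (t in tt) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1 & time == t)
    for (g in seq_len(G)) {
      n_g <- sum(at_risk & group == g)
      d_g <- sum(event == 1 & time == t & group == g)
      O[g] <- O[g] + d_g
      E[g] <- E[g] + d_t * n_g / n_t
    }
    if (n_t > 1) {
      for (g in seq_len(G)) for (h in seq_len(G)) {
        n_g <- sum(at_risk & group == g)
        n_h <- sum(at_risk & group == h)
        V[g, h] <- V[g, h] +
          d_t * (n_t - d_t) / (n_t - 1) *
          (ifelse(g == h, n_g / n_t, 0) - n_g * n_h / n_t^2)
      }
    }
  }
  dif <- (O - E)[-1]
  chisq <- drop(t(dif) %*% solve(V[-1, -1, drop = FALSE]) %*% dif)
  list(chisq = chisq, df = G - 1,
       p = pchisq(chisq, G - 1, lower.tail = FALSE))
}

# brute-force Cox partial likelihood (no ties) for a single covariate
cox_oracle_beta <- function(time, event, x) {
  stopifnot(!any(duplicated(time[event == 1])))
  npl <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      rs <- time >= time[i]
      s <- s + b * x[i] - log(sum(exp(b * x[rs])))
    }
    -s
  }
  optim(0, npl, method = "Brent", lower = -20, upper = 20)$par
}

# step-by-step moderated-statistics oracle (independent arithmetic path)
moderated_oracle <- function(x, labels) {
  labels <- as.integer(factor(labels))
  K <- max(labels); n <- nrow(x); p <- ncol(x); d <- n - K
  s2 <- numeric(p); mns <- matrix(0, K, p)
  for (g in seq_len(p)) {
    rss <- 0
    for (k in seq_len(K)) {
      xi <- x[labels == k, g]
      mns[k, g] <- mean(xi)
      rss <- rss + sum((xi - mean(xi))^2)
    }
    s2[g] <- rss / d
  }
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  dif <- var(e) - trigamma(d / 2)
  if (dif > 0) {
    # invert trigamma by uniroot, independently of the Newton path
    d0 <- 2 * uniroot(function(z) trigamma(z) - dif, c(1e-6, 1e8),
                      tol = 1e-14)$root
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf; s0 <- exp(mean(e))
  }
  s2t <- if (is.infinite(d0)) rep(s0, p) else (d0 * s0 + d * s2) / (d0 + d)
  tstat <- matrix(0, p, K)
  lfc <- matrix(0, p, K)
  nk <- tabulate(labels, K)
  for (g in seq_len(p)) for (k in seq_len(K)) {
    rest <- mean(x[labels != k, g])
    lfc[g, k] <- mns[k, g] - rest
    tstat[g, k] <- lfc[g, k] / sqrt(s2t[g] * (1 / nk[k] + 1 / (n - nk[k])))
  }
  list(d0 = d0, s0_sq = s0, s2 = s2, s2_tilde = s2t, lfc = lfc, t = tstat)
}

# protein tibble from a plain matrix
as_protein_df <- function(x, ids = sprintf("S%03d", seq_len(nrow(x)))) {
  colnames(x) <- colnames(x) %||% sprintf("p%03d", seq_len(ncol(x)))
  tibble::add_column(tibble::as_tibble(x), sample_id = ids, .before = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
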
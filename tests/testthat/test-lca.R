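# Latent class engine: closed forms, brute-force oracle, EM properties,
# posterior arithmetic, entropy, simulation round trips.

test_that("one-class fit has closed-form solution", {
  set.seed(1)
  codes <- cbind(sample(1:3, 40, TRUE), sample(1:2, 40, TRUE))
  d <- make_design(codes)
  fit <- fit_lca(d, 1)
  expect_equal(fit$pi, 1)
  # rho = observed marginal frequencies (floored/renormalized negligibly)
  f1 <- tabulate(codes[, 1], 3) / 40
  f2 <- tabulate(codes[, 2], 2) / 40
  expect_equal(unname(fit$rho[1:3, 1]), f1, tolerance = 1e-5)
  expect_equal(unname(fit$rho[4:5, 1]), f2, tolerance = 1e-5)
  ll <- sum(tabulate(codes[, 1], 3) * log(f1)) +
    sum(tabulate(codes[, 2], 2) * log(f2))
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
})

test_that("two perfectly separated patterns are recovered exactly", {
  d <- make_design(rbind(c(1, 1), c(1, 1), c(2, 2), c(2, 2)))
  fit <- fit_lca(d, 2, n_starts = 10, seed = 3)
  expect_equal(fit$pi, c(0.5, 0.5), tolerance = 1e-6)
  # rho concentrated on the pattern categories
  expect_true(all(apply(fit$rho, 2, max) >= 1 - 2e-6))
  # rho flooring at 1e-6 shifts the maximum by O(eps)
  expect_equal(fit$loglik, 4 * log(0.5), tolerance = 1e-5)
})

test_that("EM matches brute-force likelihood maximization on tiny designs", {
  set.seed(7)
  cases <- list(
    rbind(c(1,1),c(1,1),c(1,2),c(2,2),c(2,2),c(2,1),c(1,1),c(2,2)),
    cbind(sample(1:2, 12, TRUE), sample(1:2, 12, TRUE)),
    cbind(sample(1:2, 10, TRUE), sample(1:3, 10, TRUE))
  )
  for (codes in cases) {
    for (K in 1:2) {
      em <- fit_lca(make_design(codes), K, n_starts = 30, seed = 11)
      bf <- brute_force_lca_loglik(codes, K)
      expect_equal(em$loglik, bf, tolerance = 1e-4)
    }
  }
})

test_that("EM log-likelihood trace is monotone over many random fits", {
  set.seed(42)
  worst <- 0
  for (r in 1:100) {
    n <- sample(30:80, 1)
    J <- sample(2:5, 1)
    codes <- matrix(sample(1:3, n * J, TRUE), n, J)
    fit <- suppressWarnings(
      fit_lca(make_design(codes), sample(2:3, 1), n_starts = 2,
              max_iter = 80, seed = r))
    worst <- min(worst, min(diff(fit$loglik_trace)))
  }
  expect_gte(worst, -1e-8)
})

test_that("parameter recovery on well-separated simulated designs", {
  K <- 3; J <- 8; R <- 3
  pi_true <- c(0.5, 0.3, 0.2)
  rho_true <- matrix(0.1 / 2, J * R, K)
  for (j in seq_len(J)) for (k in seq_len(K)) {
    peak <- (j + k) %% R + 1L     # class-specific peaked category
    rho_true[(j - 1) * R + peak, k] <- 0.9
  }
  model <- structure(list(K = K, pi = pi_true, rho = rho_true,
                          items = paste0("item", 1:J),
                          n_categories = rep(R, J)),
                     class = "hfc_lca")
  d <- simulate_lca(model, 1500, seed = 5)
  fit <- fit_lca(d, K, n_starts = 20, seed = 6)
  # align labels by matching mixing order (canonical: decreasing pi)
  expect_equal(fit$pi, pi_true, tolerance = 0.05)
  expect_lt(mean(abs(fit$rho - rho_true)), 0.05)
  truth <- attr(d, "class_draw")
  expect_gte(adjusted_rand(assign_classes(class_posterior(fit, d))$class,
                           truth), 0.9)
})

test_that("posterior matches direct arithmetic on a worked example", {
  model <- structure(list(
    K = 2, pi = c(0.6, 0.4),
    rho = rbind(c(0.8, 0.3), c(0.2, 0.7),    # item 1, categories 1:2
                c(0.9, 0.4), c(0.1, 0.6)),   # item 2, categories 1:2
    items = c("a", "b"), n_categories = c(2L, 2L)), class = "hfc_lca")
  d <- make_design(rbind(c(1, 1)), R = c(2L, 2L))
  tau <- class_posterior(model, d)
  p1 <- 0.6 * 0.8 * 0.9; p2 <- 0.4 * 0.3 * 0.4
  expect_equal(unname(tau[1, ]), c(p1, p2) / (p1 + p2), tolerance = 1e-12)
  # symmetric ambiguity gives a 50/50 posterior
  sym <- structure(list(
    K = 2, pi = c(0.5, 0.5),
    rho = rbind(c(0.8, 0.2), c(0.2, 0.8),    # item a favours class 1 at code 1
                c(0.8, 0.2), c(0.2, 0.8)),   # item b likewise
    items = c("a", "b"), n_categories = c(2L, 2L)), class = "hfc_lca")
  # pattern (1, 2) is equidistant from both classes
  tau2 <- class_posterior(sym, make_design(rbind(c(1, 2)), R = c(2L, 2L)))
  expect_equal(unname(tau2[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  # K = 1 posterior is a column of ones
  one <- fit_lca(make_design(rbind(c(1,1), c(2,2))), 1)
  expect_equal(unname(class_posterior(one)[, 1]), c(1, 1))
})

test_that("posterior rejects designs that do not match the model", {
  d <- make_design(matrix(sample(1:2, 40, TRUE), 20, 2))
  fit <- fit_lca(d, 2, n_starts = 5, seed = 1)
  bad <- make_design(rbind(c(1, 3)), R = c(2L, 3L))
  expect_error(class_posterior(fit, bad), "unseen")
})

test_that("relative entropy endpoints and worked value", {
  onehot <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(relative_entropy(onehot), 1)
  unif <- matrix(0.5, 4, 2)
  expect_equal(relative_entropy(unif), 0)
  tau <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  h <- -(0.9 * log(0.9) + 0.1 * log(0.1)) - (0.2 * log(0.2) + 0.8 * log(0.8))
  expect_equal(relative_entropy(tau), 1 - h / (2 * log(2)), tolerance = 1e-12)
  expect_equal(round(relative_entropy(tau), 4), 0.4045)
  expect_equal(relative_entropy(matrix(1, 5, 1)), 1)  # K = 1 convention
})

test_that("simulate_lca is deterministic and matches model frequencies", {
  # three items so the 2-class model is identifiable for the round trip
  model <- structure(list(
    K = 2, pi = c(0.7, 0.3),
    rho = rbind(c(0.9, 0.2), c(0.1, 0.8),
                c(0.6, 0.3), c(0.4, 0.7),
                c(0.8, 0.1), c(0.2, 0.9)),
    items = c("a", "b", "c"), n_categories = c(2L, 2L, 2L)),
    class = "hfc_lca")
  d1 <- simulate_lca(model, 500, seed = 9)
  d2 <- simulate_lca(model, 500, seed = 9)
  expect_identical(d1$codes, d2$codes)
  big <- simulate_lca(model, 20000, seed = 10)
  # empirical pattern frequencies vs model-implied probabilities (abs tol)
  pat_prob <- function(a, b, cc) sum(model$pi * model$rho[a, ] *
                                       model$rho[2 + b, ] * model$rho[4 + cc, ])
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    emp <- mean(big$codes[, 1] == a & big$codes[, 2] == b &
                  big$codes[, 3] == cc)
    expect_lt(abs(emp - pat_prob(a, b, cc)), 0.01)
  }
  # round trip: refit recovers the generating parameters
  fit <- fit_lca(big, 2, n_starts = 10, seed = 11)
  expect_equal(fit$pi, model$pi, tolerance = 0.03)
  expect_lt(max(abs(fit$rho - model$rho)), 0.03)
})

test_that("degenerate one-class model simulates a constant design", {
  model <- structure(list(
    K = 1, pi = 1, rho = matrix(c(1 - 1e-6, 1e-6), 2, 1),
    items = "a", n_categories = 2L), class = "hfc_lca")
  d <- simulate_lca(model, 200, seed = 2)
  expect_true(all(d$codes == 1L))
})

test_that("assignment breaks ties toward the lowest class index", {
  tau <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  a <- assign_classes(tau)
  expect_equal(a$class, c(1L, 2L, 1L))
  expect_equal(a$probability, c(1, 1, 0.5))
})

test_that("classes are canonically ordered by decreasing pi", {
  set.seed(3)
  model <- structure(list(
    K = 2, pi = c(0.8, 0.2),
    rho = rbind(c(0.95, 0.05), c(0.05, 0.95), c(0.9, 0.1), c(0.1, 0.9)),
    items = c("a", "b"), n_categories = c(2L, 2L)), class = "hfc_lca")
  d <- simulate_lca(model, 600, seed = 4)
  fit <- fit_lca(d, 2, n_starts = 10, seed = 5)
  expect_true(all(diff(fit$pi) <= 0))
  expect_equal(fit$bic, -2 * fit$loglik + fit$n_params * log(600),
               tolerance = 1e-8)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-10)
  # every item/class rho block is a simplex
  for (j in 1:2) for (k in 1:2)
    expect_equal(sum(fit$rho[(j - 1) * 2 + 1:2, k]), 1, tolerance = 1e-10)
})

test_that("K exceeding the number of distinct patterns errors", {
  d <- make_design(rbind(c(1, 1), c(1, 1), c(2, 2)))
  expect_error(fit_lca(d, 3), "distinct response patterns")
})

test_that("fit is reproducible given a seed", {
  codes <- matrix(sample(1:3, 120, TRUE), 40, 3)
  d <- make_design(codes)
  f1 <- fit_lca(d, 2, n_starts = 5, seed = 77)
  f2 <- fit_lca(d, 2, n_starts = 5, seed = 77)
  expect_identical(f1$pi, f2$pi)
  expect_identical(f1$rho, f2$rho)
})

test_that("tidy and glance return well-formed summaries", {
  d <- make_design(matrix(sample(1:2, 60, TRUE), 30, 2))
  fit <- fit_lca(d, 2, n_starts = 5, seed = 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2 * (2 + 2))
  expect_named(td, c("item", "category", "class", "rho"))
  gl <- glance(fit)
  expect_equal(gl$K, 2)
  expect_equal(gl$bic, fit$bic)
})
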
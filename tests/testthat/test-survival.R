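# Survival association: truncation rule, log-rank and concordance against
# exhaustive oracles, Cox against a brute-force partial-likelihood
# maximization, and recovery / coverage simulations.

test_that("follow-up truncation censors at the horizon exactly", {
  out <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    time_x = c(5.0, 2.0, 3.0), event_x = c(1L, 1L, 1L))
  tr <- truncate_followup(out, horizon = 3)
  expect_equal(tr$time_x, c(3.0, 2.0, 3.0))
  # event beyond the horizon is censored; at the horizon it is retained
  expect_equal(tr$event_x, c(0L, 1L, 1L))
  expect_error(truncate_followup(out, horizon = 0), "positive")
})

test_that("log-rank matches the observed-minus-expected oracle", {
  # two clearly separated toy groups, all events, no ties
  dat <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = 1L,
                    cluster = rep(c("A", "B"), each = 3))
  km <- km_logrank(dat, "time", "event", "cluster")
  oracle <- logrank_oracle(dat$time, dat$event, dat$cluster)
  expect_equal(km$chisq, oracle$chisq, tolerance = 1e-10)
  expect_equal(km$p_value, oracle$p, tolerance = 1e-10)
  expect_equal(km$df, 1L)

  # identical survival in both groups: chi-square 0, p 1
  same <- data.frame(time = rep(c(1, 2, 3), 2), event = 1L,
                     cluster = rep(c("A", "B"), each = 3))
  km0 <- km_logrank(same, "time", "event", "cluster")
  expect_lt(km0$chisq, 1e-10)
  expect_equal(km0$p_value, 1, tolerance = 1e-8)

  # a censored mixed fixture also matches the oracle
  set.seed(8)
  n <- 40
  dat2 <- data.frame(time = round(rexp(n, 0.3), 3),
                     event = rbinom(n, 1, 0.7),
                     cluster = sample(c("A", "B", "C"), n, TRUE))
  km2 <- km_logrank(dat2, "time", "event", "cluster")
  or2 <- logrank_oracle(dat2$time, dat2$event, dat2$cluster)
  expect_equal(km2$chisq, or2$chisq, tolerance = 1e-8)
  expect_equal(km2$df, 2L)
})

test_that("KM estimate is non-increasing and equals empirical survival without censoring", {
  dat <- data.frame(time = c(1, 2, 3, 4, 7, 9), event = 1L,
                    cluster = rep(c("A", "B"), 3))
  km <- km_logrank(dat, "time", "event", "cluster")
  for (g in unique(km$curves$group)) {
    s <- km$curves$survival[km$curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
  }
  a <- km$curves[km$curves$group == "A", ]
  expect_equal(a$survival, 1 - seq_along(a$survival) / nrow(a))
})

test_that("Cox coefficient matches brute-force partial likelihood", {
  set.seed(21)
  n <- 30
  x <- rnorm(n)
  time <- round(rexp(n, exp(0.8 * x) * 0.2), 6)  # distinct times w.p. 1
  event <- rbinom(n, 1, 0.8)
  dat <- data.frame(time = time, event = event, x = x)
  fit <- cox_fit(dat, "time", "event", covariates = "x",
                 standardize = FALSE)
  beta <- cox_oracle_beta(time, event, x)
  expect_equal(fit$terms$estimate, beta, tolerance = 1e-5)
  expect_equal(fit$terms$hr, exp(beta), tolerance = 1e-4)
  # CI construction: exp(coef +/- 1.96 se)
  expect_equal(fit$terms$conf_low,
               exp(fit$terms$estimate - qnorm(0.975) * fit$terms$std_error))
  expect_error(cox_fit(dat[dat$event == 0, ], "time", "event",
                       covariates = "x"), "no events")
})

test_that("Cox recovers simulated class hazard ratios within 15 percent", {
  cfg <- sim_config(n_samples = 1500, n_proteins = 2, n_informative = 0,
                    baseline_hazard = 0.12,
                    class_hazard_ratios = c(1, 2.3, 5.8),
                    censor_rate = 0.4, admin_horizon = 3, seed = 314)
  labels <- with(cfg, {set.seed(99); sample.int(3, 1500, TRUE, mixing)})
  out <- sample_survival(labels, cfg, seed = 271)
  dat <- data.frame(time = out$time_major_cv, event = out$event_major_cv,
                    cluster = factor(labels))
  fit <- cox_fit(dat, "time", "event", cluster = "cluster", reference = "1")
  est <- unname(fit$terms$estimate)
  expect_equal(est[1], log(2.3), tolerance = 0.15)
  expect_equal(est[2], log(5.8), tolerance = 0.15)
  # c-statistic of the model's linear predictor is discriminative
  expect_gt(fit$c_statistic, 0.6)
})

test_that("null Cox covers HR = 1 at approximately the nominal rate", {
  set.seed(55)
  cover <- logical(200)
  for (r in seq_len(200)) {
    n <- 120
    time <- rexp(n, 0.3)
    event <- rbinom(n, 1, 0.7)
    x <- rbinom(n, 1, 0.5)          # label with no effect
    fit <- cox_fit(data.frame(time = time, event = event, x = x),
                   "time", "event", covariates = "x", standardize = FALSE)
    cover[r] <- fit$terms$conf_low <= 1 && 1 <= fit$terms$conf_high
  }
  # 95% nominal; binomial 99.9% band around 0.95 for 200 draws
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("concordance matches the exhaustive pair oracle", {
  # 5-sample fixture with one censored time, distinct times
  time <- c(1, 2, 3, 4, 5)
  event <- c(1, 1, 0, 1, 1)
  score <- c(5, 4, 1, 2, 3)
  expect_equal(concordance_index(time, event, score),
               harrell_c_oracle(time, event, score))
  # perfect ordering: higher score fails earlier, no censoring
  expect_equal(concordance_index(1:6, rep(1, 6), 6:1), 1)
  # tied scores count one half
  expect_equal(concordance_index(c(1, 2), c(1, 1), c(3, 3)), 0.5)
  # random fixture
  set.seed(31)
  tt <- sample(seq(0.1, 40, by = 0.1), 25)
  ev <- rbinom(25, 1, 0.6)
  sc <- rnorm(25)
  expect_equal(concordance_index(tt, ev, sc), harrell_c_oracle(tt, ev, sc),
               tolerance = 1e-12)
})

test_that("concordance is invariant under monotone score transforms and ~0.5 under null", {
  set.seed(17)
  tt <- rexp(300, 0.2); ev <- rbinom(300, 1, 0.7); sc <- rnorm(300)
  c1 <- concordance_index(tt, ev, sc)
  c2 <- concordance_index(tt, ev, exp(3 * sc) + 5)
  expect_equal(c1, c2, tolerance = 1e-12)
  set.seed(18)
  tt <- rexp(2000, 0.2); ev <- rep(1, 2000); sc <- rnorm(2000)
  expect_equal(concordance_index(tt, ev, sc), 0.5, tolerance = 0.02)
})

test_that("run_association produces per-endpoint HRs against the low-risk reference", {
  cfg <- sim_config(n_samples = 700, n_proteins = 2, n_informative = 0,
                    class_hazard_ratios = c(1, 2.3, 5.8), seed = 11)
  set.seed(12)
  labels <- sample.int(3, 700, TRUE, cfg$mixing)
  out <- sample_survival(labels, cfg, seed = 13)
  out <- tibble::add_column(out, sample_id = sprintf("S%03d", 1:700),
                            .before = 1)
  asg <- tibble::tibble(sample_id = out$sample_id, class = labels)
  assoc <- run_association(asg, out)
  expect_equal(assoc$reference, "1")  # lowest-hazard class
  expect_setequal(unique(assoc$results$endpoint),
                  c("major_cv", "hf_hosp", "cv_death", "all_cause_death"))
  mc <- assoc$results[assoc$results$endpoint == "major_cv", ]
  expect_equal(nrow(mc), 2)  # two non-reference clusters
  expect_true(all(mc$conf_low <= mc$hr & mc$hr <= mc$conf_high))
  expect_true(all(mc$hr > 1))
  expect_error(run_association(dplyr::mutate(asg, class = 1L), out),
               "single class")
})

test_that("log-rank chi-square is invariant under group relabeling", {
  set.seed(23)
  dat <- data.frame(time = rexp(60, 0.3), event = rbinom(60, 1, 0.8),
                    cluster = sample(1:3, 60, TRUE))
  km1 <- km_logrank(dat, "time", "event", "cluster")
  dat$cluster <- c(3, 1, 2)[dat$cluster]
  km2 <- km_logrank(dat, "time", "event", "cluster")
  expect_equal(km1$chisq, km2$chisq, tolerance = 1e-10)
})
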
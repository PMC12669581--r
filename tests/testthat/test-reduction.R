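# Standardization, PCA, projection, categorization and scheme machinery.

test_that("standardization gives exact z-scores with sample SD", {
  df <- as_protein_df(cbind(a = c(1, 2, 3), b = c(10, 20, 60)))
  std <- standardize_proteins(df)
  expect_equal(std$data$a, c(-1, 0, 1))
  z <- df_to_std <- as.matrix(std$data[, -1])
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)
  # idempotence: standardizing a standardized matrix changes nothing
  std2 <- standardize_proteins(std$data)
  expect_equal(as.matrix(std2$data[, -1]), as.matrix(std$data[, -1]),
               tolerance = 1e-12)
  # constant column errors with the offending id
  bad <- as_protein_df(cbind(a = c(1, 2, 3), flat = c(2, 2, 2)))
  expect_error(standardize_proteins(bad), "flat")
})

test_that("rank-1 data loads on a single component", {
  df <- as_protein_df(cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8)))
  pca <- fit_pca(standardize_proteins(df), 1)
  expect_equal(pca$explained_variance[1], 1, tolerance = 1e-10)
})

test_that("reconstruction from all components reproduces the matrix", {
  set.seed(14)
  x <- matrix(rnorm(20 * 6), 20, 6)
  std <- standardize_proteins(as_protein_df(x))
  pca <- fit_pca(std, 6)
  scores <- as.matrix(pca$scores[, -1])
  rec <- scores %*% t(pca$rotation)
  expect_equal(unname(rec), unname(as.matrix(std$data[, -1])),
               tolerance = 1e-8)
  # explained variances non-increasing, loadings orthonormal
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  expect_equal(unname(crossprod(pca$rotation)), diag(6), tolerance = 1e-8)
  # sign convention: the largest-magnitude loading of each component > 0
  for (c in 1:6) {
    v <- pca$rotation[, c]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_error(fit_pca(std, 21), "exceeds")
})

test_that("strong factors dominate the scree", {
  cfg <- sim_config(n_samples = 300, n_proteins = 60, n_informative = 0,
                    n_factors = 3, factor_strength = 0.6, seed = 15)
  ch <- generate_cohort(cfg)
  pca <- fit_pca(standardize_proteins(ch$proteins), 10)
  ev <- pca$explained_variance
  expect_gt(min(ev[1:3]) / max(ev[4:10]), 2)
})

test_that("projection round-trips on training data and reports shared fraction", {
  set.seed(16)
  x <- matrix(rnorm(30 * 12), 30, 12)
  df <- as_protein_df(x)
  std <- standardize_proteins(df)
  pca <- fit_pca(std, 4)
  proj <- project_scores(pca, df)
  expect_equal(as.matrix(proj[, -1]), as.matrix(pca$scores[, -1]),
               tolerance = 1e-10)
  expect_equal(attr(proj, "shared_fraction"), 1)
  # dropping a protein still projects through the intersection
  dropped <- df[, -2]
  proj2 <- project_scores(pca, dropped)
  expect_equal(attr(proj2, "shared_fraction"), 11 / 12)
  # empty intersection and low overlap error
  renamed <- df
  names(renamed)[-1] <- paste0("other", 1:12)
  expect_error(project_scores(pca, renamed), "no proteins shared")
  expect_error(project_scores(pca, df[, 1:7], min_shared = 0.8), "below floor")
})

test_that("dropout projection stays close to the full projection", {
  cfg <- sim_config(n_samples = 300, n_proteins = 150, n_informative = 40,
                    seed = 17)
  ch <- generate_cohort(cfg)
  std <- standardize_proteins(ch$proteins)
  pca <- fit_pca(std, 5)
  set.seed(18)
  keep <- c(1, 1 + sort(sample(150, 135)))   # drop 10% of proteins
  proj <- project_scores(pca, ch$proteins[, keep])
  full <- as.matrix(pca$scores[, -1])
  part <- as.matrix(proj[, -1])
  for (c in 1:5) expect_gt(cor(full[, c], part[, c]), 0.95)
})

test_that("schemes define the documented percentile grids", {
  q <- categorization_scheme("quartiles")
  expect_equal(q$percentiles, c(25, 50, 75)); expect_equal(q$n_categories, 4L)
  d <- categorization_scheme("deciles")
  expect_equal(d$percentiles, seq(10, 90, 10)); expect_equal(d$n_categories, 10L)
  expect_equal(categorization_scheme("p10_90")$n_categories, 3L)
  expect_equal(categorization_scheme("p20_80")$n_categories, 3L)
  expect_error(categorization_scheme("tertiles"))
})

test_that("categorization matches hand-computed fixtures", {
  scores <- matrix(1:8, ncol = 1, dimnames = list(NULL, "PC1"))
  d <- categorize_scores(scores, categorization_scheme("quartiles"))
  expect_equal(d$codes[, 1], c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_equal(d$n_categories, 4L)
  # p10_90 on 10 distinct values: sizes 1 / 8 / 1 under linear interpolation
  s10 <- matrix(1:10, ncol = 1, dimnames = list(NULL, "PC1"))
  d10 <- categorize_scores(s10, categorization_scheme("p10_90"))
  expect_equal(as.integer(table(d10$codes)), c(1L, 8L, 1L))
  # quantile convention: cuts are the type-7 linear-interpolation quantiles
  sch <- fit_cutpoints(s10, categorization_scheme("p10_90"))
  expect_equal(sch$cutpoints[, "PC1"],
               quantile(1:10, c(0.1, 0.9), type = 7, names = FALSE))
  # deciles give ten categories on every item
  dd <- categorize_scores(cbind(PC1 = rnorm(50), PC2 = rnorm(50)),
                          categorization_scheme("deciles"))
  expect_equal(dd$n_categories, c(10L, 10L))
})

test_that("boundary values fall in the upper bin and frozen cutpoints are exact", {
  sch <- categorization_scheme("quartiles")
  sch$cutpoints <- matrix(c(2, 4, 6), 3, dimnames = list(NULL, "PC1"))
  d <- categorize_scores(matrix(c(1.9, 2, 4, 6, 7), ncol = 1,
                                dimnames = list(NULL, "PC1")), sch)
  expect_equal(d$codes[, 1], c(1L, 2L, 3L, 4L, 4L))
  # re-categorizing training data with its own frozen cutpoints is stable
  set.seed(19)
  tr <- matrix(rnorm(100), ncol = 2, dimnames = list(NULL, c("PC1", "PC2")))
  fitted <- fit_cutpoints(tr, categorization_scheme("deciles"))
  expect_identical(categorize_scores(tr, fitted)$codes,
                   categorize_scores(tr, fitted)$codes)
  d1 <- categorize_scores(tr, fitted)
  d2 <- categorize_scores(tr, categorization_scheme("deciles"))
  expect_identical(d1$codes, d2$codes)
})

test_that("tied cutpoints warn but retain bins", {
  x <- matrix(c(rep(1, 30), 2, 3), ncol = 1, dimnames = list(NULL, "PC1"))
  expect_warning(fit_cutpoints(x, categorization_scheme("deciles")), "empty")
})

test_that("scheme selection returns the highest-entropy scheme", {
  cfg <- sim_config(n_samples = 350, n_proteins = 100, n_informative = 30,
                    seed = 20)
  ch <- generate_cohort(cfg)
  pca <- fit_pca(standardize_proteins(ch$proteins), 10)
  # non-converging coarse schemes are excluded with a warning by design
  sel <- suppressWarnings(select_scheme(pca$scores, K = 3, n_starts = 8,
                                        seed = 21))
  ok <- sel$table[sel$table$converged, ]
  expect_equal(sel$best$name, ok$scheme[which.max(ok$entropy)])
  expect_false(is.null(sel$best$cutpoints))
  # crisp 3-class structure yields a high-entropy winner
  expect_gt(max(ok$entropy), 0.8)
  # single scheme passes through unchanged
  one <- select_scheme(pca$scores, schemes = "quartiles", K = 3)
  expect_equal(one$best$name, "quartiles")
})
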
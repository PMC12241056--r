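test_that("BIC trace matches the hand formula on a small fixture", {
  set.seed(12)
  n <- 12
  S <- matrix(rnorm(n * 3), n, 3)
  S <- scale(S, scale = FALSE)
  y <- 20 + 2 * S[, 1] - 1 * S[, 2] + rnorm(n)
  sel <- bic_select(S, y, k_max = 3)
  for (k in 1:3) {
    fit <- lm(y ~ S[, 1:k, drop = FALSE])  # independent OLS
    rss <- sum(residuals(fit)^2)
    expect_equal(unname(sel$bic[k]), n * log(rss / n) + (k + 1) * log(n),
                 tolerance = 1e-10)
  }
  expect_equal(sel$k, unname(which.min(sel$bic)))
})

test_that("BIC selects k = 1 when the outcome is the first score column", {
  set.seed(13)
  n <- 40
  S <- scale(matrix(rnorm(n * 5), n, 5), scale = FALSE)
  y <- 5 + 3 * S[, 1]  # exact fit at k = 1
  expect_equal(bic_select(S, y, k_max = 5)$k, 1)
})

test_that("BIC rejects constant outcomes and oversized k_max", {
  S <- scale(matrix(rnorm(60), 20, 3), scale = FALSE)
  expect_error(bic_select(S, rep(2, 20)), "constant")
  expect_error(bic_select(S, rnorm(20), k_max = 4), "exceeds")
})

test_that("in-sample RSS of the BIC trace is non-increasing in k", {
  coh <- tiny_cohort(n = 60, p = 12, seed = 41, metrics = "AD", true_k = 3)
  ctr <- log_double_center(coh$metrics$AD)
  dec <- ssm_decompose(ctr$centered)
  sel <- bic_select(dec$scores, coh$covariates$vo2max, k_max = 8)
  expect_true(all(diff(sel$rss) <= 1e-10))
})

test_that("k = 1 pattern reduces to the first component and beta = |r|", {
  coh <- tiny_cohort(n = 80, p = 10, seed = 42, metrics = "RD")
  fit <- ssm_fit(coh$metrics$RD, coh$covariates$vo2max, k = 1)
  dec <- fit$decomposition
  # w is v1 scaled by b1; expression is z(score 1) up to sign
  expect_gt(abs(cosine_similarity(fit$combined_loadings, dec$loadings[, 1])),
            1 - 1e-10)
  expect_equal(abs(cor(fit$expression, dec$scores[, 1])), 1, tolerance = 1e-10)
  r <- cor(dec$scores[, 1], coh$covariates$vo2max)
  expect_equal(fit$fit$standardized_beta, abs(r), tolerance = 1e-10)
})

test_that("fit statistics satisfy the single-predictor identities", {
  for (seed in c(1, 7)) {
    coh <- tiny_cohort(n = 50, p = 8, seed = seed, metrics = "MD")
    fit <- ssm_fit(coh$metrics$MD, coh$covariates$vo2max)
    n <- fit$n; b <- fit$fit$standardized_beta
    expect_equal(fit$fit$adjusted_r_squared,
                 1 - (1 - b^2) * (n - 1) / (n - 2), tolerance = 1e-10)
    # expression is z-scored and positively oriented
    expect_equal(mean(fit$expression), 0, tolerance = 1e-10)
    expect_equal(sd(fit$expression), 1, tolerance = 1e-10)
    expect_gte(cor(fit$expression, coh$covariates$vo2max), 0)
    # combined loadings are the weighted component loadings
    k <- fit$k
    expect_equal(fit$combined_loadings,
                 drop(fit$decomposition$loadings[, 1:k, drop = FALSE] %*%
                        fit$combination_weights),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("a noiseless rank-1 cohort with VO2max affine in expression fits
           perfectly", {
  coh <- rank1_cohort(n = 50, p = 9, seed = 43)
  # rebuild VO2max as an exact affine function of the planted expression
  vo2 <- 24 + 3 * coh$expression_true[, 1]
  fit <- ssm_fit(coh$metrics$FA, vo2, k = 1)
  expect_equal(fit$fit$standardized_beta, 1, tolerance = 1e-6)
  expect_equal(fit$fit$adjusted_r_squared, 1, tolerance = 1e-6)
})

test_that("forward scoring of the training data reproduces the expression", {
  coh <- tiny_cohort(n = 60, p = 10, seed = 44, metrics = "FA")
  fit <- ssm_fit(coh$metrics$FA, coh$covariates$vo2max)
  expect_equal(predict(fit, coh$metrics$FA), fit$expression,
               tolerance = 1e-10)
  # and global row rescaling of new data does not move scores
  expect_equal(predict(fit, coh$metrics$FA * exp(rnorm(60))),
               fit$expression, tolerance = 1e-8)
})

test_that("k exceeding the available components is rejected", {
  coh <- tiny_cohort(n = 20, p = 5, seed = 45, metrics = "AD")
  expect_error(ssm_fit(coh$metrics$AD, coh$covariates$vo2max, k = 10), "rank")
})

test_that("TIV-adjusted fit: independent TIV leaves the association intact", {
  coh <- tiny_cohort(n = 2000, p = 10, seed = 46, metrics = "RD")
  fit <- ssm_fit(coh$metrics$RD, coh$covariates$vo2max)
  tv <- tiv_adjusted_fit(fit, coh$covariates$vo2max, coh$covariates$tiv)
  # tiv has no configured effect: adjusted-R2 change ~ unadjusted adjusted-R2
  expect_lt(abs(tv$adjusted_r2_change - fit$fit$adjusted_r_squared), 0.02)
  expect_lt(abs(tv$beta - fit$fit$standardized_beta), 0.05)
})

test_that("TIV-adjusted fit: null expression gives a null partial beta", {
  set.seed(47)
  n <- 500
  vo2 <- rnorm(n, 24, 5)
  expr <- rnorm(n)          # orthogonal to vo2 in population
  tiv <- rnorm(n, 1.4e6, 1e5)
  tv <- tiv_adjusted_fit(expr, vo2, tiv)
  expect_lt(abs(tv$beta), 0.1)
  expect_lte(tv$adjusted_r2_change, 0.02)
})

test_that("TIV-adjusted fit: VO2max = TIV leaves nothing for expression", {
  set.seed(48)
  n <- 60
  tiv <- rnorm(n, 1.4e6, 1e5)
  expr <- rnorm(n)
  tv <- suppressWarnings(tiv_adjusted_fit(expr, tiv, tiv))
  expect_equal(tv$beta, 0, tolerance = 1e-6)
  expect_equal(tv$adjusted_r2_change, 0, tolerance = 1e-6)
})

test_that("collinear TIV and expression trigger a degeneracy warning", {
  set.seed(49)
  expr <- rnorm(50)
  expect_warning(tiv_adjusted_fit(expr, rnorm(50), expr), "collinear")
})
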
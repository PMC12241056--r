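test_that("identical seeds give byte-identical cohorts", {
  a <- simulate_cohort(30, 8, ground_truth(8, seed = 42))
  b <- simulate_cohort(30, 8, ground_truth(8, seed = 42))
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- simulate_cohort(30, 8, ground_truth(8, seed = 43))
  expect_false(identical(a$metrics$FA, c2$metrics$FA))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99); before <- .Random.seed
  invisible(simulate_cohort(20, 5, ground_truth(5, seed = 1)))
  expect_identical(before, .Random.seed)
})

test_that("noiseless rank-1 construction: centered log matrix is rank 1", {
  coh <- rank1_cohort(n = 40, p = 8, seed = 3)
  ctr <- log_double_center(coh$metrics$FA)
  d <- svd(ctr$centered)$d
  expect_lt(d[2] / d[1], 1e-6)
  # and the surviving direction is the centered planted loading
  v <- centered_truth_loading(coh)
  v1 <- svd(ctr$centered)$v[, 1]
  expect_gt(abs(cosine_similarity(v1, v)), 1 - 1e-8)
})

test_that("null signal strength leaves expression uncorrelated with VO2max", {
  gt <- ground_truth(10, signal_strength = 0, seed = 5)
  rs <- vapply(1:200, function(s) {
    coh <- simulate_cohort(500, 10, gt, metrics = "FA", seed = s)
    cor(coh$expression_true[, 1], coh$covariates$vo2max)
  }, numeric(1))
  expect_gte(mean(abs(rs) < 0.2), 0.95)
})

test_that("simulated covariates recover their configured moments at n = 1000", {
  gt <- ground_truth(6, seed = 11)
  coh <- simulate_cohort(1000, 6, gt, metrics = "FA", seed = 2024)
  cv <- coh$covariates
  n <- nrow(cv)
  prev <- gt$prevalence

  # VO2max marginal moments (population mean 24.43, SD 5.40)
  expect_lt(abs(mean(cv$vo2max) - 24.43), 3 * 5.40 / sqrt(n))
  expect_lt(abs(sd(cv$vo2max) - 5.40), 3 * 5.40 / sqrt(2 * n))

  # binary prevalences within 3 SE of configured targets
  for (spec in list(c("sex", 1 - prev$female),
                    c("apoe_e4", prev$apoe_e4),
                    c("cardiac_arrest", prev$risk_factors[["cardiac_arrest"]]),
                    c("hypertension", prev$risk_factors[["hypertension"]]),
                    c("smoking", prev$risk_factors[["smoking"]]))) {
    p0 <- as.numeric(spec[2])
    se <- sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(mean(cv[[spec[1]]]) - p0), 3 * se)
  }
  # derived high-risk level matches its independence-implied prevalence
  p_high <- prob_high_vascular_risk(prev$risk_factors)
  expect_lt(abs(mean(cv$vascular_risk_level) - p_high),
            3 * sqrt(p_high * (1 - p_high) / n))
  # age uniform on 50-88
  expect_lt(abs(mean(cv$age) - 69), 3 * (38 / sqrt(12)) / sqrt(n))
  expect_true(all(cv$age >= 50 & cv$age <= 88))
  # wmh_log normal with configured meanlog/sdlog
  expect_lt(abs(mean(cv$wmh_log) - prev$wmh_meanlog),
            3 * prev$wmh_sdlog / sqrt(n))
  expect_equal(cv$wmh_log, log(cv$wmh_ml), tolerance = 1e-12)
})

test_that("vascular risk level is 1 exactly when >= 2 indicators are positive", {
  cv <- simulate_cohort(400, 5, ground_truth(5, seed = 9))$covariates
  rf <- cv[, c("cardiac_arrest", "hypertension", "hyperlipidemia",
               "diabetes", "smoking")]
  expect_identical(cv$vascular_risk_level, as.integer(rowSums(rf) >= 2))
})

test_that("expected correlation between planted expression and VO2max holds", {
  gt <- ground_truth(8, signal_strength = 0.7, seed = 4)
  rs <- vapply(1:100, function(s) {
    coh <- simulate_cohort(800, 8, gt, metrics = "FA", seed = s)
    cor(coh$expression_true[, 1], coh$covariates$vo2max)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.7), 0.02)
})

test_that("ground truth validates its invariants", {
  expect_equal(sum(ground_truth(20, seed = 1)$planted_loadings^2), 1,
               tolerance = 1e-12)
  expect_error(ground_truth(5, baseline_profile = list(FA = c(1, 1, -1, 1, 1))),
               "positive")
  expect_error(ground_truth(5, prevalence = list(apoe_e4 = 1.4)), "\\[0, 1\\]")
  expect_error(ground_truth(5, covariate_effects = c(age = -0.9, wmh_log = -0.9)),
               "exceeds 1")
  expect_error(simulate_cohort(5, 8, ground_truth(8)), "n_participants")
})

test_that("inject_outliers displaces exactly the requested cells", {
  coh <- tiny_cohort(n = 30, p = 6, seed = 7, metrics = c("AD", "FA"))
  expect_identical(inject_outliers(coh, data.frame()), coh)

  spec <- data.frame(participant = c(3, 10), tract = c(2, 5),
                     metric = c("AD", "FA"), offset = c(1.5, -0.1))
  out <- inject_outliers(coh, spec)
  expect_equal(out$metrics$AD[3, 2], coh$metrics$AD[3, 2] + 1.5)
  expect_equal(out$metrics$FA["P010", 5], coh$metrics$FA["P010", 5] - 0.1)
  # name-based indexing resolves to the same cell
  by_name <- inject_outliers(coh, data.frame(
    participant = "P003", tract = colnames(coh$metrics$AD)[2],
    metric = "AD", offset = 1.5))
  expect_equal(by_name$metrics$AD, out$metrics$AD + 0)
  expect_equal(by_name$metrics$AD[3, 2], out$metrics$AD[3, 2])
  # everything else untouched, truth unchanged
  out$metrics$AD[3, 2] <- coh$metrics$AD[3, 2]
  out$metrics$FA[10, 5] <- coh$metrics$FA[10, 5]
  expect_identical(out$metrics, coh$metrics)
  expect_identical(out$truth, coh$truth)

  expect_error(inject_outliers(coh, data.frame(participant = 99, tract = 1,
                                               metric = "AD", offset = 1)),
               "out of range")
  expect_error(inject_outliers(coh, data.frame(participant = 1, tract = 1,
                                               metric = "MD", offset = 1)),
               "unknown metric")
})
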
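# planted-outlier fixtures exercising the two exclusion rules: rule 3
# (>= 2 metrics extreme on one tract) and rule 4 (one metric extreme on
# >= 2 tracts). Fixtures use Gaussian tract variation so the planted
# displacements are the only extreme values.

iqr_of <- function(M, j) diff(quantile(M[, j], c(0.25, 0.75), names = FALSE))

test_that("clean data produces no flags or exclusions", {
  coh <- gaussian_cohort(n = 80, p = 8, seed = 21)
  qc <- qc_flag_extremes(coh$metrics)
  # isolated sample-tail flags can occur; exclusions must not
  expect_lte(nrow(qc$flagged_cells), 2)
  expect_equal(nrow(qc$excluded), 0)
  expect_equal(qc$retained_n, 80)
  expect_identical(qc$retained_ids, rownames(coh$metrics$AD))
})

test_that("zero-IQR tracts produce no flags", {
  M <- matrix(5, 20, 3, dimnames = list(sprintf("P%02d", 1:20), c("a", "b", "c")))
  M[, 2] <- 7
  qc <- qc_flag_extremes(list(AD = M))
  expect_equal(nrow(qc$flagged_cells), 0)
})

test_that("a single displaced cell is flagged but does not exclude", {
  coh <- gaussian_cohort(n = 80, p = 8, seed = 22)
  off <- 10 * iqr_of(coh$metrics$AD, 3)
  out <- inject_outliers(coh, data.frame(participant = 5, tract = 3,
                                         metric = "AD", offset = off))
  qc <- qc_flag_extremes(out$metrics)
  fl <- qc$flagged_cells
  expect_equal(nrow(fl), 1)
  expect_identical(fl$participant, "P005")
  expect_identical(fl$metric, "AD")
  expect_identical(fl$tract, colnames(coh$metrics$AD)[3])
  expect_equal(nrow(qc$excluded), 0)
})

test_that("two metrics displaced on one tract excludes under rule 3", {
  coh <- gaussian_cohort(n = 80, p = 8, seed = 23)
  spec <- data.frame(participant = c(7, 7), tract = c(4, 4),
                     metric = c("AD", "RD"),
                     offset = c(10 * iqr_of(coh$metrics$AD, 4),
                                10 * iqr_of(coh$metrics$RD, 4)))
  qc <- qc_flag_extremes(inject_outliers(coh, spec)$metrics)
  expect_identical(qc$excluded$participant, "P007")
  expect_identical(qc$excluded$rule, "3")
  expect_equal(qc$retained_n, 79)
})

test_that("one metric displaced on two tracts excludes under rule 4; a single
           displaced tract does not", {
  coh <- gaussian_cohort(n = 80, p = 8, seed = 24)
  spec2 <- data.frame(participant = c(9, 9), tract = c(2, 6),
                      metric = "FA",
                      offset = c(10 * iqr_of(coh$metrics$FA, 2),
                                 10 * iqr_of(coh$metrics$FA, 6)))
  qc2 <- qc_flag_extremes(inject_outliers(coh, spec2)$metrics)
  expect_identical(qc2$excluded$participant, "P009")
  expect_identical(qc2$excluded$rule, "4")

  spec1 <- spec2[1, ]
  qc1 <- qc_flag_extremes(inject_outliers(coh, spec1)$metrics)
  expect_false("P009" %in% qc1$excluded$participant)
  expect_equal(qc1$retained_n, 80)
})

test_that("a participant extreme under both rules is reported as such", {
  coh <- gaussian_cohort(n = 60, p = 6, seed = 27)
  spec <- data.frame(participant = 4, tract = c(1, 1, 3),
                     metric = c("AD", "MD", "MD"),
                     offset = c(10 * iqr_of(coh$metrics$AD, 1),
                                10 * iqr_of(coh$metrics$MD, 1),
                                10 * iqr_of(coh$metrics$MD, 3)))
  qc <- qc_flag_extremes(inject_outliers(coh, spec)$metrics)
  expect_identical(qc$excluded$participant, "P004")
  expect_identical(qc$excluded$rule, "3+4")
})

test_that("flag bounds follow the linear-interpolation quantile definition", {
  # heavier-tailed simulated data: recompute the full flag set directly
  coh <- tiny_cohort(n = 50, p = 5, seed = 25, metrics = "MD")
  M <- coh$metrics$MD
  qc <- qc_flag_extremes(list(MD = M))
  expected <- do.call(rbind, lapply(seq_len(ncol(M)), function(j) {
    q <- quantile(M[, j], c(0.25, 0.75), names = FALSE)
    bad <- which(M[, j] < q[1] - 3 * diff(q) | M[, j] > q[2] + 3 * diff(q))
    if (!length(bad)) return(NULL)
    data.frame(participant = rownames(M)[bad], tract = colnames(M)[j])
  }))
  got <- qc$flagged_cells[, c("participant", "tract")]
  if (is.null(expected)) {
    expect_equal(nrow(got), 0)
  } else {
    expect_setequal(paste(got$participant, got$tract),
                    paste(expected$participant, expected$tract))
  }
})

test_that("mismatched metric indices are rejected and exclusions compose", {
  coh <- gaussian_cohort(n = 40, p = 6, seed = 26, metrics = c("AD", "RD"))
  bad <- coh$metrics
  rownames(bad$RD)[1] <- "ZZZ"
  expect_error(qc_flag_extremes(bad), "identical participant and tract labels")

  # qc_apply drops excluded rows from matrices and covariates alike
  off_a <- 10 * iqr_of(coh$metrics$AD, 1)
  off_r <- 10 * iqr_of(coh$metrics$RD, 1)
  spec <- data.frame(participant = c(2, 2), tract = c(1, 1),
                     metric = c("AD", "RD"), offset = c(off_a, off_r))
  out <- inject_outliers(coh, spec)
  qc <- qc_flag_extremes(out$metrics)
  filt <- qc_apply(qc, out$metrics, coh$covariates)
  expect_equal(nrow(filt$metrics$AD), 39)
  expect_false("P002" %in% filt$covariates$participant_id)
  expect_identical(rownames(filt$metrics$AD), filt$covariates$participant_id)
})
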
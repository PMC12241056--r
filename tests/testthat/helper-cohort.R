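# small simulated cohorts for unit tests
tiny_cohort <- function(n = 60, p = 10, seed = 1, metrics = "FA", ...) {
  simulate_cohort(n, p, ground_truth(p, seed = seed, ...), metrics = metrics)
}

# near-noiseless rank-1 cohort: the limit where exact algebraic identities hold
rank1_cohort <- function(n = 40, p = 8, seed = 1, metrics = "FA",
                         noise_sd = 1e-9, subject_scale_sd = 0) {
  simulate_cohort(n, p,
                  ground_truth(p, true_k = 1, noise_sd = noise_sd,
                               subject_scale_sd = subject_scale_sd,
                               seed = seed),
                  metrics = metrics)
}

# hand-constructed cohort with Gaussian (light-tailed) metric variation:
# 3-IQR fences are ~4.7 SD events, so planted displacements are the only
# extremes — isolates the QC rules from distributional tails
gaussian_cohort <- function(n = 80, p = 8, seed = 1,
                            metrics = c("AD", "RD", "MD", "FA"), cv = 0.05) {
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(n))
  tracts <- tracula_tract_labels(p)
  base <- list(AD = 1.2e-3, RD = 5.5e-4, MD = 7.5e-4, FA = 0.45)
  mats <- lapply(metrics, function(m) {
    M <- matrix(rnorm(n * p, base[[m]], cv * base[[m]]), n, p,
                dimnames = list(ids, tracts))
    attr(M, "metric") <- m
    M
  })
  names(mats) <- metrics
  structure(list(metrics = mats,
                 covariates = data.frame(participant_id = ids,
                                         stringsAsFactors = FALSE),
                 truth = NULL),
            class = "ssm_cohort")
}

# the planted loading vector as seen after double-centering: loadings are
# identified only in the space orthogonal to the all-ones tract vector
centered_truth_loading <- function(cohort) {
  v <- cohort$truth$planted_loadings
  v - mean(v)
}

# independent brute-force PCA oracle: eigendecomposition of the residual
# covariance matrix
eigen_oracle <- function(C) {
  n <- nrow(C)
  ev <- eigen(crossprod(C) / (n - 1), symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-10
  list(values = ev$values[keep],
       vectors = ev$vectors[, keep, drop = FALSE])
}

# explicit Benjamini-Hochberg step-up construction: min over tails of
# p_(j) * m / j, capped at 1
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (r in m:1) {
    prev <- min(prev, p[o[r]] * m / r)
    adj[o[r]] <- min(prev, 1)
  }
  adj
}
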
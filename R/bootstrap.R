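#' Bootstrap reliability of combined pattern loadings
#'
#' Resamples participants with replacement and, for each resample, reruns
#' the full pattern derivation — log transform, double-centering, PCA, and
#' combination of the leading components — with the number of components `k`
#' FROZEN at the full-sample BIC selection. Freezing `k` makes the bootstrap
#' a reliability estimate of the observed pattern's tract loadings; re-
#' selecting `k` per replicate would mix model-selection variance into the
#' loading intervals.
#'
#' PCA loadings are identified only up to sign, so each replicate's combined
#' loading vector is aligned to the full-sample point estimate: when its
#' correlation with the point estimate is negative the whole vector is
#' negated. (Procrustes alignment of the component subspace is a possible
#' alternative; simple vector alignment is used because the object of
#' interest is the single combined pattern.) Per-tract 95% intervals are the
#' 2.5th and 97.5th percentiles of the aligned replicate loadings
#' (percentile bootstrap; bias-corrected accelerated intervals are available
#' via `type = "bca"`). Replicates whose decomposition has rank below `k`
#' are discarded and counted.
#'
#' @param object An [ssm_fit()] (preferred: carries the log matrix, `k`, and
#'   the point estimate), or a strictly positive metric matrix.
#' @param vo2max Required when `object` is a matrix.
#' @param k Required when `object` is a matrix; frozen component count.
#' @param n_iterations Number of bootstrap resamples (>= 100; the analysis
#'   default is 10,000).
#' @param seed Integer seed; identical seeds give bit-identical intervals.
#' @param level Confidence level (default 0.95).
#' @param type `"percentile"` (default) or `"bca"`.
#' @param store_replicates Keep the aligned replicate loading matrix.
#' @return Object of class `ssm_boot`: `point_estimate` (the full-sample
#'   combined loadings, raw scale), `ci_lower`, `ci_upper`, `significant`
#'   (interval excludes zero), `n_degenerate`, `n_iterations`, `level`,
#'   `seed`, `type`, and optionally `replicates`.
#' @export
#' @examples
#' coh <- simulate_cohort(60, 10, ground_truth(10, seed = 4))
#' fit <- ssm_fit(coh$metrics$FA, coh$covariates$vo2max)
#' bt <- ssm_bootstrap(fit, n_iterations = 200, seed = 11)
#' bt
ssm_bootstrap <- function(object, vo2max = NULL, k = NULL,
                          n_iterations = 10000L, seed = NULL,
                          level = 0.95, type = c("percentile", "bca"),
                          store_replicates = FALSE) {
  type <- match.arg(type)
  if (inherits(object, "ssm_fit")) {
    L <- object$log_matrix
    vo2max <- object$vo2max
    k <- object$k
    point <- object$combined_loadings
  } else {
    if (is.null(vo2max) || is.null(k))
      stop("vo2max and k are required when object is a matrix")
    fit <- ssm_fit(object, vo2max, k = k)
    L <- fit$log_matrix
    point <- fit$combined_loadings
  }
  n <- nrow(L); p <- ncol(L)
  if (n_iterations < 100L) stop("n_iterations must be >= 100")
  if (n < k + 3L) stop("need at least k + 3 participants to bootstrap")
  stopifnot(level > 0, level < 1)

  old_seed <- .hold_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  if (!is.null(seed)) set.seed(seed)

  W <- matrix(NA_real_, p, n_iterations)
  n_degenerate <- 0L
  rank_tol <- 1e-10
  for (b in seq_len(n_iterations)) {
    idx <- sample.int(n, n, replace = TRUE)
    wb <- .boot_loading(L[idx, , drop = FALSE], vo2max[idx], k, rank_tol)
    if (is.null(wb)) { n_degenerate <- n_degenerate + 1L; next }
    # sign alignment to the full-sample point estimate
    if (cor(wb, point) < 0) wb <- -wb
    W[, b] <- wb
  }
  ok <- !is.na(W[1L, ])
  if (!any(ok)) stop("all bootstrap replicates were degenerate (rank < k)")
  if (n_degenerate / n_iterations > 0.01)
    warning(sprintf("%d of %d bootstrap replicates degenerate (> 1%%)",
                    n_degenerate, n_iterations))
  W <- W[, ok, drop = FALSE]

  alpha <- (1 - level) / 2
  if (type == "percentile") {
    qs <- apply(W, 1L, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
    lo <- qs[1L, ]; hi <- qs[2L, ]
  } else {
    jack <- .jackknife_loadings(L, vo2max, k, point, rank_tol)
    lo <- hi <- numeric(p)
    for (j in seq_len(p)) {
      ci <- .bca_interval(W[j, ], point[j], jack[j, ], alpha)
      lo[j] <- ci[1L]; hi[j] <- ci[2L]
    }
  }
  names(lo) <- names(hi) <- names(point)
  structure(list(
    point_estimate = point, ci_lower = lo, ci_upper = hi,
    significant = lo > 0 | hi < 0,
    n_degenerate = n_degenerate, n_iterations = n_iterations,
    level = level, seed = seed, type = type, k = k, n = n,
    resampling_unit = "participant",
    replicates = if (store_replicates) W else NULL
  ), class = "ssm_boot")
}

# one replicate: double-center the resampled log matrix, take the top-k SVD
# components, combine with OLS weights. Score columns are exactly orthogonal
# with zero mean, so the coefficients are scalar projections. Returns NULL
# when the resample has rank < k.
.boot_loading <- function(Lb, yb, k, tol) {
  n <- nrow(Lb)
  Cb <- Lb - rowMeans(Lb) - rep(colMeans(Lb) - mean(Lb), each = n)
  sv <- svd(Cb, nu = 0L, nv = k)
  if (sv$d[k] <= sv$d[1L] * tol || sv$d[1L] == 0) return(NULL)
  V <- sv$v
  S <- Cb %*% V
  b <- crossprod(S, yb - mean(yb)) / colSums(S^2)
  w <- as.vector(V %*% b)
  e <- as.vector(S %*% b)
  if (cor(e, yb) < 0) w <- -w
  w
}

.jackknife_loadings <- function(L, y, k, point, tol) {
  n <- nrow(L)
  out <- matrix(NA_real_, ncol(L), n)
  for (i in seq_len(n)) {
    wi <- .boot_loading(L[-i, , drop = FALSE], y[-i], k, tol)
    if (is.null(wi)) next
    if (cor(wi, point) < 0) wi <- -wi
    out[, i] <- wi
  }
  out
}

# BCa interval for one tract from its replicate draws, point estimate, and
# jackknife values
.bca_interval <- function(w, theta, jack, alpha) {
  jack <- jack[!is.na(jack)]
  z0 <- qnorm(mean(w < theta))
  d <- mean(jack) - jack
  a <- sum(d^3) / (6 * sum(d^2)^1.5)
  if (!is.finite(z0) || !is.finite(a)) {
    return(quantile(w, c(alpha, 1 - alpha), names = FALSE))
  }
  zl <- qnorm(alpha); zu <- qnorm(1 - alpha)
  al <- pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  au <- pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  quantile(w, c(al, au), names = FALSE)
}

#' @export
print.ssm_boot <- function(x, ...) {
  cat("SSM bootstrap reliability (", x$type, " CIs, level ", x$level, ")\n",
      sep = "")
  cat("  ", x$n_iterations, "iterations,", x$n, "participants, k =",
      x$k, "\n")
  if (x$n_degenerate)
    cat("  degenerate replicates discarded:", x$n_degenerate, "\n")
  cat("  significant tracts:", sum(x$significant), "of",
      length(x$significant), "\n")
  invisible(x)
}

#' Convert bootstrap reliability to a per-tract table
#'
#' @param x An `ssm_boot`.
#' @param ... Unused.
#' @return Data frame: tract, loading, ci_lower, ci_upper, significant.
#' @export
as.data.frame.ssm_boot <- function(x, ...) {
  data.frame(tract = names(x$point_estimate),
             loading = unname(x$point_estimate),
             ci_lower = unname(x$ci_lower),
             ci_upper = unname(x$ci_upper),
             significant = unname(x$significant),
             stringsAsFactors = FALSE)
}

#' Loading bar chart with bootstrap confidence whiskers
#'
#' Mirrors the standard SSM pattern figure: blue bars are the point
#' estimates of the combined tract loadings, red whiskers the bootstrap
#' confidence intervals, and asterisks mark tracts whose interval excludes
#' zero.
#'
#' @param x An `ssm_boot`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.ssm_boot <- function(x, ...) {
  w <- x$point_estimate
  op <- par(mar = c(8, 4, 2, 1)); on.exit(par(op))
  ylim <- range(0, x$ci_lower, x$ci_upper, w) * 1.15
  bp <- barplot(w, names.arg = names(w), las = 2, cex.names = 0.6,
                col = "steelblue", ylim = ylim,
                ylab = "combined pattern loading", ...)
  abline(h = 0)
  segments(bp, x$ci_lower, bp, x$ci_upper, col = "red", lwd = 1.5)
  if (any(x$significant)) {
    ystar <- ifelse(w[x$significant] >= 0,
                    x$ci_upper[x$significant], x$ci_lower[x$significant])
    text(bp[x$significant], ystar, "*", pos = ifelse(ystar >= 0, 3, 1),
         cex = 1.2, offset = 0.2)
  }
  invisible(x)
}
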
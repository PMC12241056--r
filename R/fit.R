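#' BIC selection of nested leading components
#'
#' For each candidate `k` in `1..k_max`, fits ordinary least squares of the
#' fitness covariate on the first `k` subject-score columns (with intercept)
#' and computes the Gaussian-likelihood form of the Bayesian Information
#' Criterion,
#' \deqn{BIC(k) = n \log(RSS_k / n) + (k + 1) \log n,}
#' counting the intercept among the `k + 1` parameters. The candidate sets
#' are nested leading components — `{1}`, `{1,2}`, ... — not arbitrary
#' subsets. Ties are broken toward smaller `k`.
#'
#' @param scores Participants-by-components score matrix (columns ordered by
#'   decreasing eigenvalue).
#' @param vo2max Fitness covariate (ml/kg/min), aligned to score rows.
#' @param k_max Largest candidate `k`; must not exceed the number of
#'   components, and `n > k_max + 2` is required.
#' @return List with `k` (the argmin) and `bic` (the full trace, named by k).
#' @export
bic_select <- function(scores, vo2max, k_max = min(15L, ncol(scores))) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stopifnot(length(vo2max) == n)
  if (k_max > ncol(scores))
    stop("k_max exceeds the number of available components")
  if (n <= k_max + 2) stop("need n > k_max + 2 observations")
  if (sd(vo2max) == 0) stop("vo2max is constant: no variance to model")
  yc <- vo2max - mean(vo2max)
  bic <- numeric(k_max)
  rss <- numeric(k_max)
  for (k in seq_len(k_max)) {
    fit <- lm.fit(cbind(1, scores[, seq_len(k), drop = FALSE]), vo2max)
    rss[k] <- sum(fit$residuals^2)
    bic[k] <- n * log(rss[k] / n) + (k + 1) * log(n)
  }
  names(bic) <- seq_len(k_max)
  list(k = as.integer(which.min(bic)), bic = bic, rss = rss)
}

#' Fit a Scaled Subprofile Model covariance pattern to tract metrics
#'
#' The package's core model fit. The participant-by-tract metric matrix is
#' natural-log transformed and double-centered ([log_double_center()]),
#' decomposed into principal components ([ssm_decompose()]), and the number
#' `k` of leading components is chosen by BIC ([bic_select()]) so that their
#' linear combination best predicts the fitness covariate. The combined
#' pattern has per-tract loadings `w = sum_c b_c v_c` (the `v_c` weighted by
#' their OLS coefficients `b_c` on VO2max) and per-participant expression
#' `e_i = sum_c b_c s_ic`, z-scored and oriented so that expression
#' correlates positively with VO2max.
#'
#' For a single combined predictor, the standardized beta of VO2max on
#' expression equals their Pearson correlation, and the adjusted R-squared is
#' `1 - (1 - beta^2) (n - 1) / (n - 2)`.
#'
#' @param x Strictly positive participant-by-tract matrix (rows named by
#'   participant, columns by tract), typically one diffusion metric after QC.
#' @param vo2max Fitness covariate (ml/kg/min). Either a numeric vector
#'   aligned to the rows of `x`, or named, in which case it is matched to the
#'   row names of `x`.
#' @param k_max Largest candidate component count; defaults to
#'   `min(15, rank)`.
#' @param k Fix the number of components instead of selecting by BIC
#'   (used by the bootstrap, where `k` is frozen at the full-sample choice).
#' @param metric Optional metric name (AD, RD, MD, FA, ...) for labelling.
#' @return An object of class `ssm_fit` with components including
#'   `decomposition` (the full `ssm_decomposition`), `k`, `bic` (trace),
#'   `combination_weights`, `combined_loadings` (raw scale),
#'   `combined_loadings_unit` (unit norm, the plotted scale), `expression`
#'   (z-scored, positively oriented), and `fit` (standardized beta, R2,
#'   adjusted R2, p value). Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`.
#' @seealso [ssm_bootstrap()], [tiv_adjusted_fit()], [tract_univariate()]
#' @export
#' @examples
#' coh <- simulate_cohort(60, 12, ground_truth(12, seed = 2))
#' fit <- ssm_fit(coh$metrics$RD, coh$covariates$vo2max)
#' fit
#' abs(cosine_similarity(coef(fit), coh$truth$planted_loadings))
ssm_fit <- function(x, vo2max, k_max = NULL, k = NULL, metric = NULL) {
  if (!is.null(names(vo2max)) && !is.null(rownames(x))) {
    if (!all(rownames(x) %in% names(vo2max)))
      stop("vo2max is missing participants: ",
           paste(setdiff(rownames(x), names(vo2max)), collapse = ", "))
    vo2max <- unname(vo2max[rownames(x)])
  }
  n <- nrow(x)
  if (length(vo2max) != n)
    stop("vo2max length does not match the number of participants")
  if (anyNA(x) || anyNA(vo2max)) stop("missing values are not allowed")

  ctr <- log_double_center(x)
  dec <- ssm_decompose(ctr$centered)
  if (dec$rank == 0L) stop("centered matrix has rank zero: no covariance structure")

  if (is.null(k)) {
    if (is.null(k_max)) k_max <- min(15L, dec$rank)
    k_max <- min(k_max, dec$rank)
    sel <- bic_select(dec$scores, vo2max, k_max)
    k <- sel$k
    bic <- sel$bic
  } else {
    if (k < 1L || k > dec$rank) stop("k must lie in 1..rank (", dec$rank, ")")
    bic <- NULL
  }

  cp <- .combine_pattern(dec, k, vo2max)
  fitstats <- .simple_fit_stats(cp$expression_z, vo2max)

  structure(list(
    call = match.call(),
    metric = metric %||% attr(x, "metric"),
    n = n, p = ncol(x),
    participant_ids = rownames(x), tract_labels = colnames(x),
    log_matrix = log(x),
    centering = ctr[c("row_means", "column_means", "grand_mean")],
    decomposition = dec,
    k = k, bic = bic,
    combination_weights = cp$b,
    combined_loadings = cp$w,
    combined_loadings_unit = cp$w / sqrt(sum(cp$w^2)),
    expression = cp$expression_z,
    expression_raw = cp$expression_raw,
    expression_center = cp$center, expression_scale = cp$scale,
    vo2max = vo2max,
    fit = fitstats
  ), class = "ssm_fit")
}

# combined pattern for a fixed k: OLS coefficients of vo2max on score
# columns 1..k, loadings and expressions combined with those weights, sign
# oriented toward positive correlation with vo2max
.combine_pattern <- function(dec, k, vo2max) {
  if (k > dec$rank) stop("k exceeds the available components")
  S <- dec$scores[, seq_len(k), drop = FALSE]
  fit <- lm.fit(cbind(`(Intercept)` = 1, S), vo2max)
  b <- fit$coefficients[-1L]
  w <- as.vector(dec$loadings[, seq_len(k), drop = FALSE] %*% b)
  e <- as.vector(S %*% b)
  if (cor(e, vo2max) < 0) { w <- -w; e <- -e; b <- -b }
  ctr <- mean(e); scl <- sd(e)
  if (scl == 0) stop("combined expression is constant; cannot standardize")
  names(w) <- rownames(dec$loadings)
  z <- (e - ctr) / scl
  names(z) <- rownames(dec$scores)
  list(b = b, w = w, expression_raw = e, expression_z = z,
       center = ctr, scale = scl)
}

.simple_fit_stats <- function(z, y) {
  n <- length(y)
  r <- cor(z, y)
  r2 <- r^2
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  tval <- r * sqrt((n - 2) / max(1 - r2, .Machine$double.eps))
  p <- 2 * pt(abs(tval), n - 2, lower.tail = FALSE)
  list(standardized_beta = r, r_squared = r2, adjusted_r_squared = adj,
       p_value = p, n = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cosine similarity of two vectors
#'
#' Convenience measure of pattern recovery: the cosine of the angle between
#' an estimated loading vector and a reference (e.g., planted) vector. PCA
#' loadings are identified only up to sign, so `abs()` of the result is the
#' usual recovery score.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' @export
print.ssm_fit <- function(x, digits = 3, ...) {
  cat("SSM covariance pattern fit",
      if (!is.null(x$metric)) paste0("(", x$metric, ")"), "\n")
  cat("  ", x$n, "participants x", x$p, "tracts;",
      x$decomposition$rank, "components\n")
  cat("  BIC-selected k =", x$k, "\n")
  cat(sprintf("  expression ~ VO2max: beta = %.*f, adj. R2 = %.*f, p = %.3g\n",
              digits, x$fit$standardized_beta,
              digits, x$fit$adjusted_r_squared, x$fit$p_value))
  invisible(x)
}

#' @export
coef.ssm_fit <- function(object,
                         type = c("loadings", "unit", "weights"), ...) {
  type <- match.arg(type)
  switch(type,
         loadings = object$combined_loadings,
         unit = object$combined_loadings_unit,
         weights = object$combination_weights)
}

#' @export
residuals.ssm_fit <- function(object, ...) {
  object$vo2max - fitted(object)
}

#' @export
fitted.ssm_fit <- function(object, ...) {
  # fitted VO2max from the simple regression on z-scored expression
  b <- object$fit$standardized_beta * sd(object$vo2max)
  mean(object$vo2max) + b * object$expression
}

#' Score new participants on a fitted pattern
#'
#' Forward application of a frozen pattern: each new participant's log
#' profile is centered by its own mean and by the training group mean profile
#' (`column_means - grand_mean`), projected onto the stored component
#' loadings, combined with the stored weights, and standardized with the
#' training expression center and scale. This utility is exposed for
#' prospective scoring; it is not a cross-validated estimate.
#'
#' @param object An `ssm_fit`.
#' @param newdata Strictly positive matrix with the same tract columns as the
#'   training data (matched by column name when present).
#' @param ... Unused.
#' @return Numeric vector of expression scores on the training z scale.
#' @export
predict.ssm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$expression)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && !is.null(object$tract_labels)) {
    if (!setequal(colnames(newdata), object$tract_labels))
      stop("newdata tracts do not match the training tracts")
    newdata <- newdata[, object$tract_labels, drop = FALSE]
  }
  if (ncol(newdata) != object$p) stop("newdata must have ", object$p, " tracts")
  if (any(newdata <= 0)) stop("newdata must be strictly positive")
  L <- log(newdata)
  C <- L - rowMeans(L) -
    rep(object$centering$column_means - object$centering$grand_mean,
        each = nrow(L))
  k <- object$k
  S <- C %*% object$decomposition$loadings[, seq_len(k), drop = FALSE]
  e <- as.vector(S %*% object$combination_weights)
  setNames((e - object$expression_center) / object$expression_scale,
           rownames(newdata))
}

#' @export
summary.ssm_fit <- function(object, ...) {
  ev <- object$decomposition$eigenvalues
  structure(list(
    metric = object$metric, n = object$n, p = object$p,
    k = object$k, bic = object$bic, fit = object$fit,
    var_explained = ev[seq_len(object$k)] / sum(ev),
    combination_weights = object$combination_weights,
    top_loadings = sort(abs(object$combined_loadings_unit),
                        decreasing = TRUE)[1:min(8, object$p)]
  ), class = "summary.ssm_fit")
}

#' @export
print.summary.ssm_fit <- function(x, digits = 3, ...) {
  cat("SSM covariance pattern fit",
      if (!is.null(x$metric)) paste0("(", x$metric, ")"), "\n\n")
  cat(x$n, "participants x", x$p, "tracts\n")
  if (!is.null(x$bic)) {
    cat("BIC trace (k = 1..", length(x$bic), "):\n", sep = "")
    print(round(x$bic, 1))
  }
  cat("\nSelected k =", x$k, "| variance explained by selected components:",
      sprintf("%.1f%%", 100 * sum(x$var_explained)), "\n")
  cat(sprintf(
    "\nExpression ~ VO2max: beta = %.*f, R2 = %.*f, adj. R2 = %.*f, p = %.3g\n",
    digits, x$fit$standardized_beta, digits, x$fit$r_squared,
    digits, x$fit$adjusted_r_squared, x$fit$p_value))
  cat("\nLargest |unit loadings|:\n")
  print(round(x$top_loadings, digits))
  invisible(x)
}

#' Plot method for SSM fits
#'
#' `which = "bic"` draws the BIC trace over candidate component counts;
#' `which = "loadings"` a bar chart of combined unit-scale loadings;
#' `which = "expression"` the expression-versus-VO2max scatter with the
#' fitted line.
#'
#' @param x An `ssm_fit`.
#' @param which One of `"bic"`, `"loadings"`, `"expression"`.
#' @param ... Passed to the underlying base graphics call.
#' @export
plot.ssm_fit <- function(x, which = c("bic", "loadings", "expression"), ...) {
  which <- match.arg(which)
  if (which == "bic") {
    if (is.null(x$bic)) stop("fit has no BIC trace (k was fixed)")
    plot(as.integer(names(x$bic)), x$bic, type = "b", pch = 19,
         xlab = "components k", ylab = "BIC", ...)
    abline(v = x$k, lty = 2)
  } else if (which == "loadings") {
    w <- x$combined_loadings_unit
    op <- par(mar = c(8, 4, 2, 1)); on.exit(par(op))
    bp <- barplot(w, names.arg = names(w), las = 2, cex.names = 0.6,
                  ylab = "combined loading (unit scale)", ...)
    abline(h = 0)
  } else {
    plot(x$expression, x$vo2max, pch = 19, cex = 0.7,
         xlab = "pattern expression (z)", ylab = "VO2max (ml/kg/min)", ...)
    abline(lm(x$vo2max ~ x$expression), lwd = 2)
  }
  invisible(x)
}
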
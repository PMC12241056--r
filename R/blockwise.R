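#' Default block structure for covariate regressions
#'
#' The hierarchical block order used for pattern-expression models: head
#' size first (TIV), then demographics (age, sex), then vascular and genetic
#' risk (high vascular risk level, APOE e4 carriage), then lesion load
#' (log-transformed WMH volume). Each block adds its predictors to all
#' previous ones. Alternative sets — e.g. the five individual vascular risk
#' indicators in place of the derived level — can be passed to
#' [blockwise_regression()] for sensitivity analyses.
#'
#' @return Named list of character vectors (predictors added per block).
#' @export
default_blocks <- function() {
  list(block1 = "tiv",
       block2 = c("age", "sex"),
       block3 = c("vascular_risk_level", "apoe_e4"),
       block4 = "wmh_log")
}

#' Block-wise hierarchical regression of pattern expression on covariates
#'
#' Fits a sequence of nested ordinary least squares models of the pattern
#' expression score on cumulative predictor blocks and reports, per block,
#' each predictor's standardized beta (from the fit with z-scored outcome
#' and predictors — binary predictors are z-scored like continuous ones, the
#' SPSS convention), the unstandardized coefficient with its standard error
#' and p value, the adjusted R-squared, and the model F statistic with its p
#' value. Rows with a missing value in any predictor of the largest block
#' are dropped from every block, so R-squared changes compare like with
#' like.
#'
#' @param expression Outcome vector (pattern expression), or an `ssm_fit`.
#' @param covariates Data frame containing every predictor named in
#'   `blocks`, aligned to `expression`.
#' @param blocks Named list of character vectors: predictors *added* at each
#'   block (cumulative design). Default [default_blocks()].
#' @return Object of class `ssm_blockwise`: list with `blocks` (per block:
#'   `coefficients` data frame, `r_squared`, `adjusted_r_squared`,
#'   `f_statistic`, `f_p_value`, `df`, `perfect_fit`), `n` (complete cases
#'   used), `block_predictors`.
#' @export
#' @examples
#' coh <- simulate_cohort(120, 10, ground_truth(10, seed = 8))
#' fit <- ssm_fit(coh$metrics$RD, coh$covariates$vo2max)
#' bw <- blockwise_regression(fit$expression, coh$covariates)
#' bw
blockwise_regression <- function(expression, covariates,
                                 blocks = default_blocks()) {
  if (inherits(expression, "ssm_fit")) expression <- expression$expression
  stopifnot(is.data.frame(covariates), length(blocks) >= 1L)
  if (length(expression) != nrow(covariates))
    stop("expression and covariates have different lengths")
  all_preds <- unique(unlist(blocks))
  missing_cols <- setdiff(all_preds, names(covariates))
  if (length(missing_cols))
    stop("covariates lack column(s): ", paste(missing_cols, collapse = ", "))

  dat <- data.frame(.y = as.numeric(expression),
                    covariates[, all_preds, drop = FALSE])
  cc <- complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  n <- nrow(dat)
  if (n < length(all_preds) + 2L)
    stop("too few complete cases (", n, ") for ", length(all_preds),
         " predictors")

  cum <- character(0)
  res <- vector("list", length(blocks))
  names(res) <- names(blocks) %||% paste0("block", seq_along(blocks))
  cum_sets <- vector("list", length(blocks))
  for (bl in seq_along(blocks)) {
    cum <- c(cum, blocks[[bl]])
    cum_sets[[bl]] <- cum
    X <- as.matrix(dat[, cum, drop = FALSE])
    qrX <- qr(cbind(1, X))
    if (qrX$rank < ncol(X) + 1L) {
      aliased <- cum[qrX$pivot[-seq_len(qrX$rank)] - 1L]
      stop("rank-deficient design in ", names(res)[bl],
           "; collinear column(s): ", paste(aliased, collapse = ", "))
    }
    fml <- stats::reformulate(cum, response = ".y")
    fit <- lm(fml, data = dat)
    sm <- summary(fit)
    # standardized betas: z-score outcome and every predictor
    zdat <- as.data.frame(lapply(dat[, c(".y", cum), drop = FALSE],
                                 function(v) as.vector(scale(v))))
    zfit <- lm(fml, data = zdat)
    ctab <- data.frame(
      predictor = cum,
      beta = unname(coef(zfit)[cum]),
      b = unname(coef(fit)[cum]),
      se = sm$coefficients[cum, "Std. Error"],
      p = sm$coefficients[cum, "Pr(>|t|)"],
      stringsAsFactors = FALSE)
    rownames(ctab) <- NULL
    r2 <- sm$r.squared
    perfect <- (1 - r2) < 1e-12
    df_model <- length(cum)
    df_resid <- n - df_model - 1L
    f <- if (perfect) Inf else (r2 / df_model) / ((1 - r2) / df_resid)
    fp <- if (perfect) 0 else pf(f, df_model, df_resid, lower.tail = FALSE)
    res[[bl]] <- list(coefficients = ctab,
                      r_squared = r2,
                      adjusted_r_squared = sm$adj.r.squared,
                      f_statistic = f, f_p_value = fp,
                      df = c(df_model, df_resid),
                      perfect_fit = perfect)
  }
  structure(list(blocks = res, n = n, block_predictors = cum_sets),
            class = "ssm_blockwise")
}

#' @export
print.ssm_blockwise <- function(x, digits = 3, ...) {
  cat("Block-wise regression of pattern expression (n =", x$n, ")\n")
  for (bl in seq_along(x$blocks)) {
    b <- x$blocks[[bl]]
    cat(sprintf("\n%s: adj. R2 = %.*f, F(%d, %d) = %.2f, p = %.3g%s\n",
                names(x$blocks)[bl], digits, b$adjusted_r_squared,
                b$df[1], b$df[2], b$f_statistic, b$f_p_value,
                if (b$perfect_fit) "  [perfect fit]" else ""))
    tab <- b$coefficients
    tab$beta <- round(tab$beta, digits)
    tab$b <- signif(tab$b, digits)
    tab$se <- signif(tab$se, digits)
    tab$p <- signif(tab$p, 3)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Flatten a block-wise result to one data frame
#'
#' @param x An `ssm_blockwise`.
#' @param ... Unused.
#' @return Data frame with one row per (block, predictor), plus block-level
#'   fit columns.
#' @export
as.data.frame.ssm_blockwise <- function(x, ...) {
  rows <- lapply(seq_along(x$blocks), function(bl) {
    b <- x$blocks[[bl]]
    cbind(block = names(x$blocks)[bl], b$coefficients,
          adjusted_r_squared = b$adjusted_r_squared,
          f_statistic = b$f_statistic, f_p_value = b$f_p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
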
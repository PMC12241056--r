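#' Univariate per-tract regressions against fitness with FDR correction
#'
#' For each tract in the tested subset, fits a simple ordinary least squares
#' regression of the (by default log-transformed) tract metric on VO2max and
#' reports the standardized beta, the unstandardized slope with its
#' t-distribution confidence interval, the raw p value, and the
#' Benjamini-Hochberg FDR-adjusted p value. The FDR family is the tested
#' subset — typically the tracts found significant in the bootstrap of the
#' SSM pattern — not the full tract set; pass all tract labels to treat
#' every tract as the family.
#'
#' @param x Strictly positive participant-by-tract metric matrix.
#' @param vo2max Fitness covariate aligned to the rows of `x`.
#' @param tracts Character vector of tract labels to test (the FDR family).
#'   Defaults to all columns.
#' @param log_scale Regress the natural log of the metric (default TRUE, for
#'   consistency with the SSM preprocessing) or the raw metric.
#' @param conf_level Level of the slope confidence interval.
#' @return Data frame of class `ssm_univariate`: `tract`, `beta`
#'   (standardized), `slope`, `se`, `ci_lower`, `ci_upper`, `p`, `p_fdr`,
#'   with attribute `metric` when `x` carries one.
#' @export
#' @examples
#' coh <- simulate_cohort(80, 10, ground_truth(10, seed = 6))
#' head(tract_univariate(coh$metrics$AD, coh$covariates$vo2max))
tract_univariate <- function(x, vo2max, tracts = colnames(x),
                             log_scale = TRUE, conf_level = 0.95) {
  stopifnot(is.matrix(x), nrow(x) == length(vo2max))
  if (length(tracts) == 0L) stop("empty tract subset")
  if (!all(tracts %in% colnames(x)))
    stop("unknown tract(s): ",
         paste(setdiff(tracts, colnames(x)), collapse = ", "))
  Y <- x[, tracts, drop = FALSE]
  if (log_scale) {
    if (any(Y <= 0)) stop("non-positive values: log scale undefined")
    Y <- log(Y)
  }
  n <- nrow(Y)
  out <- lapply(seq_along(tracts), function(j) {
    fit <- lm(Y[, j] ~ vo2max)
    sm <- summary(fit)$coefficients
    ci <- confint(fit, "vo2max", level = conf_level)
    data.frame(
      tract = tracts[j],
      beta = unname(coef(fit)[2L] * sd(vo2max) / sd(Y[, j])),
      slope = unname(coef(fit)[2L]),
      se = sm["vo2max", "Std. Error"],
      ci_lower = ci[1L], ci_upper = ci[2L],
      p = sm["vo2max", "Pr(>|t|)"],
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$p_fdr <- p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  attr(res, "metric") <- attr(x, "metric")
  attr(res, "log_scale") <- log_scale
  class(res) <- c("ssm_univariate", "data.frame")
  res
}
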
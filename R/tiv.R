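#' TIV-adjusted association of pattern expression with fitness
#'
#' Tests whether pattern expression predicts VO2max beyond head size: block 1
#' regresses VO2max on total intracranial volume (TIV) alone; block 2 adds
#' the expression score. Reported are the standardized beta of expression in
#' block 2 (from the fit with z-scored outcome and predictors) and the
#' change in adjusted R-squared between blocks.
#'
#' @param expression Pattern expression scores, or an [ssm_fit()] object.
#' @param vo2max Fitness covariate, aligned to participants.
#' @param tiv Total intracranial volume, aligned to participants.
#' @return List with `beta` (standardized, expression in block 2), `p_value`,
#'   `adjusted_r2_block1`, `adjusted_r2_block2`, `adjusted_r2_change`, and
#'   `degenerate` (TRUE when TIV and expression are collinear beyond
#'   tolerance, in which case the partial beta is unstable).
#' @export
#' @examples
#' coh <- simulate_cohort(80, 12, ground_truth(12, seed = 5))
#' fit <- ssm_fit(coh$metrics$MD, coh$covariates$vo2max)
#' tiv_adjusted_fit(fit, coh$covariates$vo2max, coh$covariates$tiv)
tiv_adjusted_fit <- function(expression, vo2max, tiv) {
  if (inherits(expression, "ssm_fit")) expression <- expression$expression
  n <- length(vo2max)
  stopifnot(length(expression) == n, length(tiv) == n)

  degenerate <- FALSE
  if (sd(tiv) == 0 || abs(cor(tiv, expression)) > 1 - 1e-10) {
    degenerate <- TRUE
    warning("TIV and expression are collinear beyond tolerance; ",
            "partial coefficients are unstable")
  }

  m1 <- lm(vo2max ~ tiv)
  m2 <- lm(vo2max ~ tiv + expression)
  adj1 <- summary(m1)$adj.r.squared
  sm2 <- summary(m2)
  adj2 <- sm2$adj.r.squared

  zfit <- lm(scale(vo2max) ~ scale(tiv) + scale(expression))
  beta <- unname(coef(zfit)[3L])
  p <- if ("expression" %in% rownames(sm2$coefficients))
    sm2$coefficients["expression", "Pr(>|t|)"] else NA_real_

  list(beta = beta, p_value = p,
       adjusted_r2_block1 = adj1, adjusted_r2_block2 = adj2,
       adjusted_r2_change = adj2 - adj1,
       degenerate = degenerate)
}
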
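#' Ground truth for a simulated cohort
#'
#' Collects every parameter that determines the data-generating process of
#' [simulate_cohort()]: the planted regional covariance pattern, how strongly
#' its subject expression drives the fitness covariate, the magnitude of the
#' global per-subject scaling factor and of tract-level noise, the baseline
#' regional profile of each diffusion metric, and the standardized effects of
#' demographic and health covariates on pattern expression.
#'
#' The generative model, on the natural-log scale of one metric, is
#' \deqn{\log M_{ij} = \log b_j + g_i + \sum_c s_{ic} v_c[j] + \epsilon_{ij}}
#' with `b` the baseline profile, `g_i ~ N(0, subject_scale_sd)` a global
#' subject factor (the multiplicative scaling the SSM's double-centering is
#' designed to remove), `v_1` the planted loading vector (`v_2..v_k` drawn
#' orthonormal to it), `s_ic` subject expressions with unit population SD, and
#' `eps ~ N(0, noise_sd)` tract-level noise. VO2max is generated as
#' `signal_strength * u + sqrt(1 - signal_strength^2) * N(0,1)`, where `u` is
#' the `component_weights`-combination of the expressions, then affinely
#' scaled to population mean 24.43 and SD 5.40 ml/kg/min; its expected
#' correlation with `u` is therefore exactly `signal_strength`.
#'
#' Covariate effects are standardized: expression of the planted pattern is
#' built as `sum(effect_c * z(covariate_c)) + residual`, with the residual SD
#' chosen so the expression has unit population variance. Effects must satisfy
#' `sum(effect^2) <= 1`.
#'
#' Default covariate distributions emulate a community cohort of cognitively
#' unimpaired older adults: age uniform on 50–88 years; 78/167 female; five
#' vascular risk indicators (cardiac arrest 5/167, hypertension 55/167,
#' hyperlipidemia 73/167, diabetes 8/167, smoking history 66/167) drawn
#' independently, with high vascular risk derived as two or more positives;
#' APOE e4 carriage 49/167; white matter hyperintensity (WMH) volume
#' log-normal; total intracranial volume (TIV) normal with a male offset.
#'
#' @param n_tracts Number of tract regions.
#' @param true_k Number of planted signal components.
#' @param signal_strength Expected correlation between the combined component
#'   expression and simulated VO2max, in `[-1, 1]`.
#' @param noise_sd SD of tract-level noise on the log scale. The per-cell SD
#'   of the planted signal term `s_i v_j` is `sqrt(mean(v_j^2)) = 1/sqrt(p)`
#'   (unit-SD expressions, unit-norm loadings), and the default `NULL` sets
#'   `noise_sd` to half that — the strongest noise level at which the
#'   planted pattern is still reliably observable downstream.
#' @param subject_scale_sd SD (log scale) of the per-subject global factor.
#' @param planted_loadings Unit-norm numeric vector of length `n_tracts`; if
#'   `NULL`, a reproducible vector is drawn from `seed` and normalized.
#' @param component_weights Weights combining the `true_k` standardized
#'   component expressions into the VO2max driver; defaults to equal weights
#'   `1/sqrt(true_k)`. Must have unit Euclidean norm.
#' @param component_variance_decay Ratio of successive planted component
#'   expression variances (component `c` has variance `decay^(c-1)`; the
#'   planted pattern itself always has unit variance). A decaying spectrum
#'   makes the component order identifiable; an exactly degenerate spectrum
#'   would leave the sample principal components an arbitrary rotation of
#'   the planted ones.
#' @param baseline_profile Named list of per-tract baseline profiles, one per
#'   metric, strictly positive; `NULL` for built-in defaults in native units
#'   (diffusivities in mm^2/s, FA dimensionless).
#' @param covariate_effects Named numeric vector of standardized effects on
#'   pattern expression; recognised names are `age`, `sex`, `tiv`,
#'   `vascular_risk_level`, `apoe_e4`, `wmh_log`.
#' @param prevalence Named list overriding covariate distribution parameters:
#'   `female`, `apoe_e4`, `risk_factors` (length-5 vector), `age_range`,
#'   `wmh_meanlog`, `wmh_sdlog`, `tiv_mean`, `tiv_male_offset`, `tiv_sd`,
#'   `vo2max_mean`, `vo2max_sd`.
#' @param residual_cor Exchangeable correlation of tract-level noise within a
#'   subject (default 0: independent noise).
#' @param seed Integer seed recorded in the truth object and used as the
#'   default seed of [simulate_cohort()].
#' @return An object of class `ssm_ground_truth`.
#' @seealso [simulate_cohort()]
#' @export
ground_truth <- function(n_tracts = 42L,
                         true_k = 1L,
                         signal_strength = 0.7,
                         noise_sd = NULL,
                         subject_scale_sd = 0.1,
                         planted_loadings = NULL,
                         component_weights = NULL,
                         component_variance_decay = 0.7,
                         baseline_profile = NULL,
                         covariate_effects = c(age = -0.5, sex = 0.15,
                                               tiv = 0,
                                               vascular_risk_level = -0.15,
                                               apoe_e4 = 0, wmh_log = -0.25),
                         prevalence = list(),
                         residual_cor = 0,
                         seed = 1L) {
  if (is.null(noise_sd)) noise_sd <- 0.5 / sqrt(n_tracts)
  stopifnot(n_tracts >= 3L, true_k >= 1L, noise_sd > 0,
            subject_scale_sd >= 0, abs(signal_strength) <= 1,
            residual_cor >= 0, residual_cor < 1)
  if (is.null(planted_loadings)) {
    old_seed <- .hold_rng()
    set.seed(seed)
    v <- rnorm(n_tracts)
    .restore_rng(old_seed)
    planted_loadings <- v / sqrt(sum(v^2))
  }
  if (length(planted_loadings) != n_tracts)
    stop("planted_loadings must have length n_tracts")
  nrm <- sqrt(sum(planted_loadings^2))
  if (abs(nrm - 1) > 1e-12) planted_loadings <- planted_loadings / nrm
  if (is.null(component_weights))
    component_weights <- rep(1 / sqrt(true_k), true_k)
  if (length(component_weights) != true_k)
    stop("component_weights must have length true_k")
  if (abs(sum(component_weights^2) - 1) > 1e-8)
    stop("component_weights must have unit Euclidean norm")
  stopifnot(component_variance_decay > 0, component_variance_decay <= 1)

  prev <- modifyList(list(
    female = 78 / 167,
    apoe_e4 = 49 / 167,
    risk_factors = c(cardiac_arrest = 5 / 167, hypertension = 55 / 167,
                     hyperlipidemia = 73 / 167, diabetes = 8 / 167,
                     smoking = 66 / 167),
    age_range = c(50, 88),
    wmh_meanlog = 1.0, wmh_sdlog = 0.9,
    tiv_mean = 1.38e6, tiv_male_offset = 1.3e5, tiv_sd = 1.1e5,
    vo2max_mean = 24.43, vo2max_sd = 5.40
  ), prevalence)
  probs <- c(prev$female, prev$apoe_e4, prev$risk_factors)
  if (any(probs < 0 | probs > 1))
    stop("covariate prevalences must lie in [0, 1]")

  if (is.null(baseline_profile))
    baseline_profile <- .default_baselines(n_tracts)
  if (any(unlist(baseline_profile) <= 0))
    stop("baseline_profile must be strictly positive (log transform undefined)")

  eff <- c(age = 0, sex = 0, tiv = 0, vascular_risk_level = 0,
           apoe_e4 = 0, wmh_log = 0)
  if (length(covariate_effects)) {
    if (is.null(names(covariate_effects)) ||
        !all(names(covariate_effects) %in% names(eff)))
      stop("covariate_effects names must be among: ",
           paste(names(eff), collapse = ", "))
    eff[names(covariate_effects)] <- covariate_effects
  }
  if (sum(eff^2) > 1)
    stop("sum of squared covariate effects exceeds 1; ",
         "expression variance cannot be normalized")

  structure(list(
    n_tracts = as.integer(n_tracts),
    true_k = as.integer(true_k),
    signal_strength = signal_strength,
    noise_sd = noise_sd,
    subject_scale_sd = subject_scale_sd,
    planted_loadings = planted_loadings,
    component_weights = component_weights,
    component_variance_decay = component_variance_decay,
    baseline_profile = baseline_profile,
    covariate_effects = eff,
    prevalence = prev,
    residual_cor = residual_cor,
    seed = as.integer(seed)
  ), class = "ssm_ground_truth")
}

# smooth, strictly positive baseline regional profiles in native units;
# +/-20% sinusoidal variation across tracts stands in for real regional means
.default_baselines <- function(p) {
  shape <- 1 + 0.2 * sin(2 * pi * seq_len(p) / p)
  list(AD = 1.2e-3 * shape, RD = 5.5e-4 * shape,
       MD = 7.5e-4 * shape, FA = pmin(0.45 * shape, 0.85))
}

#' Probability of high vascular risk under independent indicators
#'
#' Exact probability that two or more of the binary risk indicators are
#' positive, given their marginal prevalences, assuming independence. This is
#' the population prevalence of the derived `vascular_risk_level` covariate.
#'
#' @param prevalences Numeric vector of indicator prevalences in `[0, 1]`.
#' @return A probability.
#' @export
prob_high_vascular_risk <- function(prevalences) {
  stopifnot(all(prevalences >= 0 & prevalences <= 1))
  p0 <- prod(1 - prevalences)
  # P(exactly 1): sum over indicators of the odds-weighted none-probability
  p1 <- p0 * sum(ifelse(prevalences == 1, Inf,
                        prevalences / (1 - prevalences)))
  if (any(prevalences == 1)) {
    # degenerate indicators: recompute by enumeration
    k <- length(prevalences)
    states <- expand.grid(rep(list(0:1), k))
    pr <- apply(states, 1, function(s)
      prod(ifelse(s == 1, prevalences, 1 - prevalences)))
    return(sum(pr[rowSums(states) >= 2]))
  }
  max(0, 1 - p0 - p1)
}

#' Simulate a cohort with a planted regional covariance pattern
#'
#' Generates participant-by-tract metric matrices (one per requested diffusion
#' metric) plus a participant covariate table, following the generative model
#' documented in [ground_truth()]. All structure relevant to downstream
#' recovery testing — the planted loading vector, the realized subject
#' expressions, the VO2max driver — is retained in the returned object.
#'
#' @param n_participants Number of participants (>= 10).
#' @param n_tracts Number of tract regions (>= 3); must match the truth object.
#' @param truth A [ground_truth()] object.
#' @param metrics Character vector of metric names to generate; each gets its
#'   own independent noise realization of the same planted structure.
#' @param seed Integer seed; defaults to `truth$seed`. Identical seeds yield
#'   byte-identical cohorts.
#' @return An object of class `ssm_cohort`: a list with elements
#'   \describe{
#'     \item{metrics}{named list of participant-by-tract matrices with
#'       participant IDs as row names and tract labels as column names;}
#'     \item{covariates}{data frame with one row per participant:
#'       `participant_id`, `vo2max`, `age`, `sex` (male = 1), `tiv`, five
#'       binary risk indicators, derived `vascular_risk_level` (1 iff >= 2
#'       indicators positive), `apoe_e4`, `wmh_ml` and `wmh_log`;}
#'     \item{expression_true}{n-by-`true_k` matrix of realized component
#'       expressions (column 1 is the planted pattern's expression);}
#'     \item{loadings_true}{`n_tracts`-by-`true_k` matrix of planted loading
#'       vectors (column 1 equals `truth$planted_loadings`);}
#'     \item{truth}{the `ssm_ground_truth` object.}
#'   }
#' @export
#' @examples
#' coh <- simulate_cohort(40, 12, ground_truth(12, seed = 7))
#' dim(coh$metrics$FA)
#' cor(coh$expression_true[, 1], coh$covariates$vo2max)
simulate_cohort <- function(n_participants = 167L,
                            n_tracts = 42L,
                            truth = ground_truth(n_tracts),
                            metrics = c("AD", "RD", "MD", "FA"),
                            seed = truth$seed) {
  stopifnot(inherits(truth, "ssm_ground_truth"))
  if (n_participants < 10L) stop("n_participants must be >= 10")
  if (n_tracts < 3L) stop("n_tracts must be >= 3")
  if (truth$n_tracts != n_tracts)
    stop("truth was built for ", truth$n_tracts, " tracts, not ", n_tracts)
  if (!all(metrics %in% names(truth$baseline_profile)))
    stop("no baseline profile for metric(s): ",
         paste(setdiff(metrics, names(truth$baseline_profile)), collapse = ", "))

  n <- as.integer(n_participants)
  p <- as.integer(n_tracts)
  k <- truth$true_k
  prev <- truth$prevalence
  eff <- truth$covariate_effects

  old_seed <- .hold_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)

  ids <- sprintf("P%03d", seq_len(n))

  ## covariates -------------------------------------------------------------
  age <- runif(n, prev$age_range[1], prev$age_range[2])
  sex <- rbinom(n, 1L, 1 - prev$female)          # male = 1
  rf <- vapply(prev$risk_factors, function(pr) rbinom(n, 1L, pr),
               integer(n))
  colnames(rf) <- names(prev$risk_factors)
  vrl <- as.integer(rowSums(rf) >= 2L)
  apoe <- rbinom(n, 1L, prev$apoe_e4)
  wmh_log <- rnorm(n, prev$wmh_meanlog, prev$wmh_sdlog)
  wmh_ml <- exp(wmh_log)
  tiv <- prev$tiv_mean + prev$tiv_male_offset * sex + rnorm(n, 0, prev$tiv_sd)

  ## planted expressions ----------------------------------------------------
  # population z-scores, so that configured effects are exact standardized
  # coefficients at the population level
  z_age <- (age - mean(prev$age_range)) / (diff(prev$age_range) / sqrt(12))
  z_sex <- .z_bin(sex, 1 - prev$female)
  p_high <- prob_high_vascular_risk(prev$risk_factors)
  z_vrl <- .z_bin(vrl, p_high)
  z_apoe <- .z_bin(apoe, prev$apoe_e4)
  z_wmh <- (wmh_log - prev$wmh_meanlog) / prev$wmh_sdlog
  tiv_pop_sd <- sqrt(prev$tiv_male_offset^2 * prev$female * (1 - prev$female) +
                     prev$tiv_sd^2)
  tiv_pop_mean <- prev$tiv_mean + prev$tiv_male_offset * (1 - prev$female)
  z_tiv <- (tiv - tiv_pop_mean) / tiv_pop_sd

  lin <- eff["age"] * z_age + eff["sex"] * z_sex + eff["tiv"] * z_tiv +
    eff["vascular_risk_level"] * z_vrl + eff["apoe_e4"] * z_apoe +
    eff["wmh_log"] * z_wmh
  resid_sd <- sqrt(1 - sum(eff^2))
  s <- matrix(rnorm(n * k), n, k)
  s[, 1] <- lin + resid_sd * s[, 1]
  comp_sd <- sqrt(truth$component_variance_decay^(seq_len(k) - 1))
  if (k > 1L) s[, -1L] <- sweep(s[, -1L, drop = FALSE], 2, comp_sd[-1L], "*")

  ## VO2max: driven by the equally-standardized component expressions -------
  u <- as.vector(sweep(s, 2, comp_sd, "/") %*% truth$component_weights)
  ss <- truth$signal_strength
  vo2max <- prev$vo2max_mean +
    prev$vo2max_sd * (ss * u + sqrt(1 - ss^2) * rnorm(n))

  ## loading vectors: v1 planted; v2..vk Gram-Schmidt on Gaussian draws ------
  V <- matrix(0, p, k)
  V[, 1] <- truth$planted_loadings
  if (k > 1L) {
    for (c in 2:k) {
      v <- rnorm(p)
      for (d in 1:(c - 1)) v <- v - sum(v * V[, d]) * V[, d]
      V[, c] <- v / sqrt(sum(v^2))
    }
  }

  ## metric matrices ---------------------------------------------------------
  g <- rnorm(n, 0, truth$subject_scale_sd)
  signal <- s %*% t(V)
  labels <- tracula_tract_labels(p)
  rho <- truth$residual_cor
  mats <- lapply(metrics, function(m) {
    eps <- matrix(rnorm(n * p, 0, truth$noise_sd), n, p)
    if (rho > 0) {
      shared <- rnorm(n, 0, truth$noise_sd)
      eps <- sqrt(rho) * shared + sqrt(1 - rho) * eps
    }
    logm <- rep(log(truth$baseline_profile[[m]]), each = n) + g + signal + eps
    M <- exp(logm)
    dimnames(M) <- list(ids, labels)
    attr(M, "metric") <- m
    M
  })
  names(mats) <- metrics

  covariates <- data.frame(
    participant_id = ids, vo2max = vo2max, age = age, sex = sex, tiv = tiv,
    rf, vascular_risk_level = vrl, apoe_e4 = apoe,
    wmh_ml = wmh_ml, wmh_log = wmh_log,
    stringsAsFactors = FALSE
  )

  dimnames(V) <- list(labels, paste0("C", seq_len(k)))
  dimnames(s) <- list(ids, paste0("C", seq_len(k)))
  structure(list(metrics = mats, covariates = covariates,
                 expression_true = s, loadings_true = V, truth = truth),
            class = "ssm_cohort")
}

.z_bin <- function(x, p) {
  if (p <= 0 || p >= 1) return(x * 0)
  (x - p) / sqrt(p * (1 - p))
}

.hold_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.ssm_cohort <- function(x, ...) {
  n <- nrow(x$covariates)
  cat("Simulated SSM cohort:", n, "participants,",
      x$truth$n_tracts, "tracts\n")
  cat("  metrics:", paste(names(x$metrics), collapse = ", "), "\n")
  cat("  planted components:", x$truth$true_k,
      " signal strength:", x$truth$signal_strength, "\n")
  cat(sprintf("  VO2max: mean %.2f, sd %.2f ml/kg/min\n",
              mean(x$covariates$vo2max), sd(x$covariates$vo2max)))
  invisible(x)
}

#' Displace individual cells of a simulated cohort
#'
#' Returns a copy of the cohort with selected metric values displaced by a
#' fixed offset — used to plant outliers for exercising the IQR-based quality
#' control rules. The ground truth is unchanged.
#'
#' @param cohort An `ssm_cohort`.
#' @param spec Data frame with columns `participant`, `tract`, `metric`,
#'   `offset`. Participant and tract may be given as integer indices or as
#'   row/column names.
#' @return A modified copy of `cohort`.
#' @export
inject_outliers <- function(cohort, spec) {
  stopifnot(inherits(cohort, "ssm_cohort"), is.data.frame(spec))
  if (nrow(spec) == 0L) return(cohort)
  need <- c("participant", "tract", "metric", "offset")
  if (!all(need %in% names(spec)))
    stop("spec must have columns: ", paste(need, collapse = ", "))
  for (r in seq_len(nrow(spec))) {
    m <- as.character(spec$metric[r])
    if (!m %in% names(cohort$metrics))
      stop("unknown metric: ", m)
    M <- cohort$metrics[[m]]
    i <- .resolve_index(spec$participant[r], rownames(M), "participant")
    j <- .resolve_index(spec$tract[r], colnames(M), "tract")
    M[i, j] <- M[i, j] + spec$offset[r]
    cohort$metrics[[m]] <- M
  }
  cohort
}

.resolve_index <- function(x, nms, what) {
  if (is.numeric(x)) {
    i <- as.integer(x)
    if (i < 1L || i > length(nms))
      stop(what, " index out of range: ", i)
  } else {
    i <- match(as.character(x), nms)
    if (is.na(i)) stop("unknown ", what, ": ", x)
  }
  i
}
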
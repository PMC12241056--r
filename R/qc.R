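#' IQR-based quality control of tract metric values
#'
#' Flags extreme tract values and derives participant exclusions. A cell is
#' flagged when its value lies below `Q1 - 3 IQR` or above `Q3 + 3 IQR` of
#' that tract's cross-participant distribution for that metric. A participant
#' is excluded when
#' \itemize{
#'   \item (rule 3) two or more of the metrics are flagged on the same tract, or
#'   \item (rule 4) any single metric is flagged on two or more tracts.
#' }
#'
#' Quartiles use the linear-interpolation definition (`stats::quantile`
#' type 7); flags at the exact margin can differ under other quantile
#' definitions. When a tract's IQR is zero the bounds collapse to the
#' quartiles themselves and only values strictly outside them are flagged, so
#' a constant tract produces no flags.
#'
#' @param metrics Named list of participant-by-tract matrices (one per
#'   diffusion metric) sharing identical row and column names, or a single
#'   matrix.
#' @param scope Distribution over which quartiles are computed:
#'   `"per_tract"` (default: across participants within each tract) or
#'   `"per_metric"` (pooled across all tracts of a metric).
#' @return An object of class `ssm_qc`: list with `flagged_cells` (data frame
#'   of participant, tract, metric, value, lower, upper), `excluded` (data
#'   frame of participant and triggering rule), `retained_ids`, `retained_n`.
#' @export
#' @examples
#' coh <- simulate_cohort(40, 8, ground_truth(8, seed = 3))
#' qc_flag_extremes(coh$metrics)
qc_flag_extremes <- function(metrics, scope = c("per_tract", "per_metric")) {
  scope <- match.arg(scope)
  if (is.matrix(metrics)) metrics <- list(metric = metrics)
  stopifnot(is.list(metrics), length(metrics) >= 1L)
  ref <- metrics[[1L]]
  for (m in metrics) {
    if (!identical(dimnames(m), dimnames(ref)))
      stop("metric matrices must share identical participant and tract labels")
  }
  ids <- rownames(ref)
  tracts <- colnames(ref)

  flags <- list()
  for (mn in names(metrics)) {
    M <- metrics[[mn]]
    if (scope == "per_tract") {
      q <- apply(M, 2, quantile, probs = c(0.25, 0.75), names = FALSE)
      lo <- q[1, ] - 3 * (q[2, ] - q[1, ])
      hi <- q[2, ] + 3 * (q[2, ] - q[1, ])
      bad <- which(sweep(M, 2, lo, "<") | sweep(M, 2, hi, ">"), arr.ind = TRUE)
      if (nrow(bad)) {
        flags[[mn]] <- data.frame(
          participant = ids[bad[, 1]], tract = tracts[bad[, 2]], metric = mn,
          value = M[bad], lower = lo[bad[, 2]], upper = hi[bad[, 2]],
          stringsAsFactors = FALSE)
      }
    } else {
      q <- quantile(M, probs = c(0.25, 0.75), names = FALSE)
      lo <- q[1] - 3 * (q[2] - q[1]); hi <- q[2] + 3 * (q[2] - q[1])
      bad <- which(M < lo | M > hi, arr.ind = TRUE)
      if (nrow(bad)) {
        flags[[mn]] <- data.frame(
          participant = ids[bad[, 1]], tract = tracts[bad[, 2]], metric = mn,
          value = M[bad], lower = lo, upper = hi, stringsAsFactors = FALSE)
      }
    }
  }
  flagged <- if (length(flags)) do.call(rbind, unname(flags)) else
    data.frame(participant = character(), tract = character(),
               metric = character(), value = numeric(),
               lower = numeric(), upper = numeric(), stringsAsFactors = FALSE)
  rownames(flagged) <- NULL

  excl <- data.frame(participant = character(), rule = character(),
                     stringsAsFactors = FALSE)
  if (nrow(flagged)) {
    # rule 3: >=2 metrics flagged on one (participant, tract)
    pt <- unique(flagged[, c("participant", "tract", "metric")])
    cnt3 <- stats::aggregate(metric ~ participant + tract, data = pt, FUN = length)
    r3 <- unique(cnt3$participant[cnt3$metric >= 2L])
    # rule 4: one metric flagged on >=2 tracts for a participant
    pm <- unique(flagged[, c("participant", "metric", "tract")])
    cnt4 <- stats::aggregate(tract ~ participant + metric, data = pm, FUN = length)
    r4 <- unique(cnt4$participant[cnt4$tract >= 2L])
    all_excl <- union(r3, r4)
    if (length(all_excl)) {
      rule <- ifelse(all_excl %in% r3 & all_excl %in% r4, "3+4",
                     ifelse(all_excl %in% r3, "3", "4"))
      excl <- data.frame(participant = all_excl, rule = rule,
                         stringsAsFactors = FALSE)
      excl <- excl[order(match(excl$participant, ids)), , drop = FALSE]
      rownames(excl) <- NULL
    }
  }
  retained <- setdiff(ids, excl$participant)
  structure(list(flagged_cells = flagged, excluded = excl,
                 retained_ids = retained, retained_n = length(retained),
                 scope = scope, n_input = length(ids)),
            class = "ssm_qc")
}

#' @export
print.ssm_qc <- function(x, ...) {
  cat("SSM quality control (3 IQR,", x$scope, "quartiles)\n")
  cat("  flagged cells:", nrow(x$flagged_cells), "\n")
  cat("  excluded participants:", nrow(x$excluded), "of", x$n_input, "\n")
  if (nrow(x$excluded)) {
    for (r in seq_len(nrow(x$excluded)))
      cat("    ", x$excluded$participant[r], " (rule ", x$excluded$rule[r],
          ")\n", sep = "")
  }
  cat("  retained:", x$retained_n, "\n")
  invisible(x)
}

#' Apply QC exclusions to cohort tables
#'
#' Drops excluded participants from every metric matrix and the covariate
#' table, keeping row order.
#'
#' @param qc An `ssm_qc` report.
#' @param metrics Named list of metric matrices.
#' @param covariates Optional covariate data frame with `participant_id`.
#' @return List with filtered `metrics` and (if given) `covariates`.
#' @export
qc_apply <- function(qc, metrics, covariates = NULL) {
  stopifnot(inherits(qc, "ssm_qc"))
  keep <- qc$retained_ids
  metrics <- lapply(metrics, function(M) M[keep, , drop = FALSE])
  if (!is.null(covariates))
    covariates <- covariates[match(keep, covariates$participant_id), ,
                             drop = FALSE]
  list(metrics = metrics, covariates = covariates)
}
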
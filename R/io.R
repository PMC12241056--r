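#' Read a participant-by-tract metric table
#'
#' Expects delimited text with a header row of tract labels and the
#' participant identifier in the first column. The delimiter is sniffed from
#' the header (comma or tab) unless given.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` to sniff.
#' @param metric Optional metric name to attach as an attribute.
#' @return Numeric matrix with participant row names and tract column names.
#' @export
read_metric_matrix <- function(path, sep = NULL, metric = NULL) {
  if (is.null(sep)) sep <- .sniff_sep(path)
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate participant IDs in ", path)
  M <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(M)) stop("non-numeric metric values in ", path)
  rownames(M) <- ids
  attr(M, "metric") <- metric
  M
}

#' Write a participant-by-tract metric table
#'
#' @param x Matrix with participant row names and tract column names.
#' @param path File path.
#' @param sep Field separator (default comma).
#' @export
write_metric_matrix <- function(x, path, sep = ",") {
  df <- data.frame(participant_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read a participant covariate table
#'
#' Delimited text with a header row; must contain a `participant_id` column.
#' When `wmh_ml` is present and `wmh_log` is not, the log-transformed column
#' is derived (`wmh_log = log(wmh_ml)`, defined only for positive volumes).
#' When the five risk indicator columns are present and
#' `vascular_risk_level` is not, the high-risk level (two or more positive
#' indicators) is derived.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` to sniff.
#' @return Data frame, one row per participant.
#' @export
read_covariate_table <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- .sniff_sep(path)
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(df))
    stop("covariate table lacks a participant_id column")
  df$participant_id <- as.character(df$participant_id)
  if (anyDuplicated(df$participant_id))
    stop("duplicate participant IDs in ", path)
  if ("wmh_ml" %in% names(df) && !"wmh_log" %in% names(df)) {
    if (any(df$wmh_ml <= 0, na.rm = TRUE))
      stop("wmh_ml must be positive to derive wmh_log")
    df$wmh_log <- log(df$wmh_ml)
  }
  rf <- c("cardiac_arrest", "hypertension", "hyperlipidemia", "diabetes",
          "smoking")
  if (all(rf %in% names(df)) && !"vascular_risk_level" %in% names(df))
    df$vascular_risk_level <- as.integer(rowSums(df[, rf]) >= 2L)
  df
}

#' @rdname read_covariate_table
#' @param x Covariate data frame.
#' @export
write_covariate_table <- function(x, path, sep = ",") {
  write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
}

.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Write a simulated cohort to delimited text
#'
#' Writes one metric table per metric (`<metric>.csv`), the covariate table
#' (`covariates.csv`), and the ground truth as a YAML sidecar
#' (`ground_truth.yaml`) so planted parameters travel with the data.
#'
#' @param cohort An `ssm_cohort`.
#' @param dir Output directory (created if needed).
#' @param sep Field separator.
#' @return Invisibly, the named vector of written file paths.
#' @export
write_cohort <- function(cohort, dir, sep = ",") {
  stopifnot(inherits(cohort, "ssm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (m in names(cohort$metrics)) {
    p <- file.path(dir, paste0(m, ".csv"))
    write_metric_matrix(cohort$metrics[[m]], p, sep)
    paths[m] <- p
  }
  pcov <- file.path(dir, "covariates.csv")
  write_covariate_table(cohort$covariates, pcov, sep)
  paths["covariates"] <- pcov
  truth <- cohort$truth
  sidecar <- list(
    n_tracts = truth$n_tracts, true_k = truth$true_k,
    signal_strength = truth$signal_strength, noise_sd = truth$noise_sd,
    subject_scale_sd = truth$subject_scale_sd,
    planted_loadings = as.numeric(truth$planted_loadings),
    component_weights = as.numeric(truth$component_weights),
    covariate_effects = as.list(truth$covariate_effects),
    residual_cor = truth$residual_cor, seed = truth$seed
  )
  ptruth <- file.path(dir, "ground_truth.yaml")
  yaml::write_yaml(sidecar, ptruth, precision = 15L)
  paths["ground_truth"] <- ptruth
  invisible(paths)
}
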
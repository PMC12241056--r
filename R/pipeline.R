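#' Run the full SSM analysis pipeline
#'
#' Orchestrates, for each diffusion metric table: IQR quality control
#' (shared across metrics), log transform and double-centering, PCA, BIC
#' component selection, combined pattern construction, the TIV-adjusted
#' fit, bootstrap loading reliability, FDR-corrected univariate regressions
#' of the bootstrap-significant tracts, and the block-wise covariate
#' regression of pattern expression. Writes delimited per-metric reports
#' and a JSON manifest recording the configuration, seed, library versions
#' and output checksums, so a run is auditable and reproducible.
#'
#' All randomness flows from the single root `seed`, split deterministically
#' per metric and stage, so each stage is independently reproducible.
#'
#' @param config A named list, or the path to a YAML file, with fields:
#'   \describe{
#'     \item{metric_files}{named list/vector of metric table paths (names are
#'       the metric labels, e.g. AD, RD, MD, FA);}
#'     \item{covariate_file}{path to the covariate table (must contain
#'       `participant_id`, `vo2max`, `tiv`, and the block predictors);}
#'     \item{output_dir}{directory for reports (created if needed);}
#'     \item{k_max}{candidate component limit (default 15);}
#'     \item{n_iterations}{bootstrap iterations (default 10000, minimum 100);}
#'     \item{ci_level}{bootstrap confidence level in (0,1), default 0.95;}
#'     \item{fdr_q}{FDR threshold in (0,1) used to mark univariate
#'       significance in reports, default 0.05;}
#'     \item{seed}{root integer seed (default 1);}
#'     \item{blocks}{block definitions as in [blockwise_regression()];}
#'     \item{qc}{apply [qc_flag_extremes()] exclusions (default TRUE);}
#'     \item{qc_scope}{quartile scope, `"per_tract"` (default) or
#'       `"per_metric"`;}
#'     \item{ci_type}{bootstrap interval type, `"percentile"` (default) or
#'       `"bca"`;}
#'     \item{univariate_log}{univariate regressions on the log metric
#'       (default TRUE);}
#'     \item{figures}{also write loading bar charts as PNG (default FALSE);}
#'     \item{sep}{field separator of the input tables (`NULL` to sniff).}
#'   }
#' @return Invisibly, a named list per metric with elements `fit`
#'   (`ssm_fit`), `tiv`, `bootstrap` (`ssm_boot`), `univariate`,
#'   `blockwise`, plus `qc` (`ssm_qc`) and `manifest`.
#' @export
run_ssm_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- modifyList(list(
    k_max = 15L, n_iterations = 10000L, ci_level = 0.95, fdr_q = 0.05,
    seed = 1L, blocks = default_blocks(), qc = TRUE,
    qc_scope = "per_tract", ci_type = "percentile",
    univariate_log = TRUE, figures = FALSE, sep = NULL
  ), config)
  for (f in c("metric_files", "covariate_file", "output_dir"))
    if (is.null(cfg[[f]])) stop("config field missing: ", f)
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1) stop("ci_level must be in (0,1)")
  if (cfg$fdr_q <= 0 || cfg$fdr_q >= 1) stop("fdr_q must be in (0,1)")
  if (cfg$n_iterations < 100L) stop("n_iterations must be >= 100")
  if (is.list(cfg$blocks)) cfg$blocks <- lapply(cfg$blocks, as.character)

  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logmsg <- function(...) message("[ssmfit] ", ...)

  ## load and align ----------------------------------------------------------
  metric_files <- unlist(cfg$metric_files)
  metrics <- lapply(names(metric_files), function(m)
    read_metric_matrix(metric_files[[m]], sep = cfg$sep, metric = m))
  names(metrics) <- names(metric_files)
  covariates <- read_covariate_table(cfg$covariate_file, sep = cfg$sep)

  ids <- rownames(metrics[[1L]])
  for (m in names(metrics)) {
    if (!identical(rownames(metrics[[m]]), ids))
      stop("participant IDs of metric ", m,
           " do not match metric ", names(metrics)[1L])
  }
  orphans_m <- setdiff(ids, covariates$participant_id)
  orphans_c <- setdiff(covariates$participant_id, ids)
  if (length(orphans_m))
    stop("participants missing from the covariate table: ",
         paste(orphans_m, collapse = ", "))
  if (length(orphans_c))
    stop("participants in the covariate table without metric data: ",
         paste(orphans_c, collapse = ", "))
  covariates <- covariates[match(ids, covariates$participant_id), ,
                           drop = FALSE]
  logmsg("loaded ", length(ids), " participants x ",
         ncol(metrics[[1L]]), " tracts, ", length(metrics), " metric(s)")

  ## QC ----------------------------------------------------------------------
  qc <- qc_flag_extremes(metrics, scope = cfg$qc_scope)
  if (isTRUE(cfg$qc)) {
    filtered <- qc_apply(qc, metrics, covariates)
    metrics <- filtered$metrics
    covariates <- filtered$covariates
    logmsg("QC: ", nrow(qc$flagged_cells), " flagged cells, ",
           nrow(qc$excluded), " participants excluded, ",
           qc$retained_n, " retained")
  }
  .write_qc_report(qc, file.path(out_dir, "qc_report"))

  ## per-metric analysis -----------------------------------------------------
  vo2 <- covariates$vo2max
  results <- list()
  written <- character(0)
  for (mi in seq_along(metrics)) {
    m <- names(metrics)[mi]
    logmsg("metric ", m, ": fitting SSM pattern")
    fit <- ssm_fit(metrics[[m]], vo2, k_max = cfg$k_max, metric = m)
    tiv_fit <- tiv_adjusted_fit(fit, vo2, covariates$tiv)
    boot_seed <- cfg$seed + 1000L * mi + 1L
    logmsg("metric ", m, ": bootstrap (", cfg$n_iterations,
           " iterations, seed ", boot_seed, ")")
    boot <- ssm_bootstrap(fit, n_iterations = cfg$n_iterations,
                          seed = boot_seed, level = cfg$ci_level,
                          type = cfg$ci_type)
    sig_tracts <- names(boot$significant)[boot$significant]
    uni <- if (length(sig_tracts)) {
      tract_univariate(metrics[[m]], vo2, tracts = sig_tracts,
                       log_scale = cfg$univariate_log,
                       conf_level = cfg$ci_level)
    } else NULL
    bw <- blockwise_regression(fit$expression, covariates,
                               blocks = cfg$blocks)

    written <- c(written,
                 .write_metric_report(m, fit, tiv_fit, boot, uni, bw,
                                      cfg, out_dir))
    if (isTRUE(cfg$figures)) {
      fig <- file.path(out_dir, paste0(m, "_loadings.png"))
      png(fig, width = 1400, height = 700, res = 120)
      plot(boot, main = paste("CRF-related", m, "pattern"))
      dev.off()
    }
    results[[m]] <- list(fit = fit, tiv = tiv_fit, bootstrap = boot,
                         univariate = uni, blockwise = bw)
  }

  ## manifest ----------------------------------------------------------------
  qc_files <- file.path(out_dir, paste0("qc_report",
                                        c("_flags.csv", "_exclusions.csv")))
  all_files <- c(qc_files[file.exists(qc_files)], written)
  manifest <- list(
    package = "ssmfit",
    version = as.character(packageVersion("ssmfit")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "blocks")],
    blocks = cfg$blocks,
    n_input = qc$n_input, n_retained = qc$retained_n,
    checksums = as.list(md5sum(all_files)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  logmsg("wrote ", length(all_files) + 1L, " files to ", out_dir)

  invisible(c(results, list(qc = qc, manifest = manifest)))
}

.write_qc_report <- function(qc, stem) {
  write.table(qc$flagged_cells, paste0(stem, "_flags.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  write.table(qc$excluded, paste0(stem, "_exclusions.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
}

.write_metric_report <- function(m, fit, tiv_fit, boot, uni, bw, cfg,
                                 out_dir) {
  paths <- character(0)
  ld <- data.frame(tract = names(fit$combined_loadings),
                   loading = unname(fit$combined_loadings),
                   unit_loading = unname(fit$combined_loadings_unit),
                   ci_lower = unname(boot$ci_lower),
                   ci_upper = unname(boot$ci_upper),
                   significant = unname(boot$significant),
                   stringsAsFactors = FALSE)
  p <- file.path(out_dir, paste0(m, "_loadings.csv"))
  write.table(ld, p, sep = ",", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  expr <- data.frame(participant_id = names(fit$expression),
                     expression = unname(fit$expression),
                     vo2max = fit$vo2max, stringsAsFactors = FALSE)
  p <- file.path(out_dir, paste0(m, "_expression.csv"))
  write.table(expr, p, sep = ",", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  if (!is.null(uni)) {
    u <- as.data.frame(uni)
    u$significant_fdr <- u$p_fdr < cfg$fdr_q
    p <- file.path(out_dir, paste0(m, "_univariate.csv"))
    write.table(u, p, sep = ",", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }

  p <- file.path(out_dir, paste0(m, "_blockwise.csv"))
  write.table(as.data.frame(bw), p, sep = ",", row.names = FALSE,
              quote = FALSE)
  paths <- c(paths, p)

  fitsum <- list(
    metric = m, n = fit$n, n_tracts = fit$p,
    k = fit$k,
    bic_trace = as.numeric(fit$bic),
    standardized_beta = fit$fit$standardized_beta,
    r_squared = fit$fit$r_squared,
    adjusted_r_squared = fit$fit$adjusted_r_squared,
    p_value = fit$fit$p_value,
    tiv_adjusted = list(beta = tiv_fit$beta, p_value = tiv_fit$p_value,
                        adjusted_r2_change = tiv_fit$adjusted_r2_change),
    bootstrap = list(n_iterations = boot$n_iterations, level = boot$level,
                     type = boot$type, seed = boot$seed,
                     resampling_unit = boot$resampling_unit,
                     n_degenerate = boot$n_degenerate,
                     n_significant_tracts = sum(boot$significant))
  )
  p <- file.path(out_dir, paste0(m, "_fit.yaml"))
  yaml::write_yaml(fitsum, p, precision = 15L)
  c(paths, p)
}
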
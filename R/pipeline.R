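#' Pipeline run configuration
#'
#' Bundles every stage's settings with the master seed; the configuration
#' is serialized verbatim into the run manifest so a run can be reproduced
#' bit-for-bit.
#'
#' @param cohort a [cohort_config()].
#' @param outcome an [outcome_params()].
#' @param k GMM mixture order for voxel QC (default 4).
#' @param presence_ratio lower-tail presence cutoff (default 0.5).
#' @param exclusion_threshold parcel bad-voxel cutoff (default 0.5, strict).
#' @param low_hz,high_hz band-pass edges (defaults 0.008, 0.1 Hz).
#' @param gamma Louvain resolution (default 1).
#' @param min_nodes minimum valid parcels for a network summary (default 3).
#' @param alpha significance threshold (default 0.01).
#' @param collinearity_threshold screening cutoff (default 0.3).
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), outcome = outcome_params(),
                       k = 4L, presence_ratio = 0.5, exclusion_threshold = 0.5,
                       low_hz = 0.008, high_hz = 0.1, gamma = 1,
                       min_nodes = 3L, alpha = 0.01,
                       collinearity_threshold = 0.3) {
  structure(list(cohort = cohort, outcome = outcome, k = as.integer(k),
                 presence_ratio = presence_ratio,
                 exclusion_threshold = exclusion_threshold,
                 low_hz = low_hz, high_hz = high_hz, gamma = gamma,
                 min_nodes = as.integer(min_nodes), alpha = alpha,
                 collinearity_threshold = collinearity_threshold),
            class = "run_config")
}

#' Compute one subject's feature row from voxel data
#'
#' Runs QC (GMM + lower-tail + parcel rule), temporal cleaning, Pearson
#' connectivity, positive-part graph, PC/MDZ against the template
#' partition restricted to the subject's valid parcels, Louvain + AMI, and
#' the inter-hemispheric medians, then assembles the feature row.
#'
#' @param subject a `subject_voxels` object.
#' @param parcel_table parcel metadata.
#' @param config a [run_config()].
#' @param covariates one-row data.frame appended to the feature row.
#' @param louvain_seed seed for the Louvain node ordering.
#' @return one-row feature data.frame (see [assemble_features()]).
#' @export
compute_subject_features <- function(subject, parcel_table, config,
                                     covariates = NULL, louvain_seed = 1L) {
  qc_out <- voxel_qc(subject, parcel_table, k = config$k,
                     presence_ratio = config$presence_ratio,
                     exclusion_threshold = config$exclusion_threshold,
                     tr_seconds = config$cohort$tr_seconds)
  pts <- clean_timeseries(qc_out$parcel_ts, config$low_hz, config$high_hz)
  cm <- pearson_connectivity(pts)
  W <- positive_part(cm)
  template <- parcel_table$network_label[cm$valid]
  pc <- participation_coefficient(W, template)
  mdz <- module_degree_zscore(W, template)
  lv <- louvain(W, gamma = config$gamma, seed = louvain_seed)
  dmn_label <- match("DMN", yeo7_networks)
  assemble_features(
    qc = qc_out$qc, pc = pc, mdz = mdz,
    network_label = template,
    louvain_partition = lv$partition, template_partition = template,
    interhemi_global = interhemispheric_median(cm),
    interhemi_dmn = interhemispheric_median(cm, network_filter = dmn_label),
    covariates = covariates,
    n_networks = config$cohort$n_networks, min_nodes = config$min_nodes)
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> voxel QC -> connectivity -> graph metrics -> summaries ->
#' prognostic models. Subjects are materialized one at a time. When the
#' outcome model ties the outcome to a connectivity feature, outcomes are
#' drawn after feature assembly via [simulate_outcomes()]; otherwise they
#' were drawn at cohort generation. If `out_dir` is given, the feature
#' table, report tables and a manifest are written there (see
#' [write_report()]).
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @param quiet suppress per-stage messages.
#' @return list of class `pipeline_run`: `features`, `battery`
#'   (a `model_battery`), `group_comparisons`, `config`, `cohort_truth`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(config$cohort, config$outcome)
  n <- config$cohort$n_subjects
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    subj <- generate_subject(cohort, i)
    row <- withCallingHandlers(
      compute_subject_features(subj, cohort$parcel_table, config,
                               covariates = cohort$covariates[i, , drop = FALSE],
                               louvain_seed = cohort$subject_seeds[i] %% 1000000L + 1L),
      warning = function(w) {
        if (!quiet) message("subject ", i, ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (!quiet)
      message(sprintf("subject %d: %.1f%% voxels excluded, %d/%d parcels valid",
                      i, row$excluded_voxel_pct, row$n_valid_parcels,
                      config$cohort$n_parcels))
    rows[[i]] <- row
  }
  features <- if (n > 0L) do.call(rbind, rows) else empty_features(config)
  if (n > 0L && !identical(config$outcome$feature_name, "none")) {
    features$outcome <- simulate_outcomes(features, config$outcome,
                                          cohort$outcome_seed)
  }
  battery <- NULL
  group_cmp <- NULL
  if (n > 0L && length(unique(stats::na.omit(features$outcome))) == 2L) {
    battery <- fit_model_battery(features, alpha = config$alpha,
                                 collinearity_threshold = config$collinearity_threshold)
    cmp_vars <- c(grep("^(pc|mdz)_median_", names(features), value = TRUE),
                  "ami", "excluded_voxel_pct", "age",
                  "propofol", "midazolam", "opioid", "clonidine")
    group_cmp <- group_compare(features, cmp_vars,
                               categorical = c("propofol", "midazolam",
                                               "opioid", "clonidine"))
  }
  run <- structure(list(features = features, battery = battery,
                        group_comparisons = group_cmp, config = config,
                        cohort_truth = cohort$truth),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_report(run, out_dir)
  run
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))
}

#' Write the run's tables, report and manifest
#'
#' Emits `features.csv` (full precision), `group_comparisons.csv`,
#' `model_performance.csv` (model, Pseudo-R2, AUROC, AIC),
#' `model_coefficients.csv` (predictor, coefficient, p, adjusted p),
#' a fixed-precision human-readable `report.txt`, and `manifest.json`
#' holding the serialized configuration. All floats in the report tables
#' are written at fixed precision so reruns diff cleanly.
#'
#' @param run a [run_pipeline()] result.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(run, out_dir) {
  stopifnot(inherits(run, "pipeline_run"))
  if (is.null(run$features)) stop("incomplete run: no feature table", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  perf <- if (!is.null(run$battery) && !is.null(run$battery$performance))
    run$battery$performance else
    data.frame(model = character(0), pseudo_r2 = numeric(0),
               auroc = numeric(0), aic_value = numeric(0),
               lrt_p = numeric(0), n_used = integer(0),
               converged = logical(0))
  perf_out <- data.frame(model = perf$model,
                         pseudo_r2 = fmt_num(perf$pseudo_r2, 4),
                         auroc = fmt_num(perf$auroc, 4),
                         aic = fmt_num(perf$aic_value, 2),
                         lrt_p = fmt_num(perf$lrt_p, 4),
                         n_used = perf$n_used,
                         stringsAsFactors = FALSE)
  utils::write.csv(perf_out, file.path(out_dir, "model_performance.csv"),
                   row.names = FALSE)
  cf <- if (!is.null(run$battery) && !is.null(run$battery$coefficients))
    run$battery$coefficients else
    data.frame(model = character(0), predictor = character(0),
               coefficient = numeric(0), wald_p = numeric(0),
               adj_p = numeric(0))
  cf_out <- data.frame(model = cf$model, predictor = cf$predictor,
                       coefficient = fmt_num(cf$coefficient, 4),
                       p = fmt_num(cf$wald_p, 4),
                       adj_p = fmt_num(cf$adj_p, 4),
                       stringsAsFactors = FALSE)
  utils::write.csv(cf_out, file.path(out_dir, "model_coefficients.csv"),
                   row.names = FALSE)
  gc_ <- if (!is.null(run$group_comparisons)) run$group_comparisons else
    data.frame(variable = character(0), test = character(0),
               statistic = numeric(0), p = numeric(0),
               median_favorable = numeric(0), median_unfavorable = numeric(0))
  gc_out <- data.frame(variable = gc_$variable, test = gc_$test,
                       statistic = fmt_num(gc_$statistic, 4),
                       p = fmt_num(gc_$p, 4),
                       median_favorable = fmt_num(gc_$median_favorable, 4),
                       median_unfavorable = fmt_num(gc_$median_unfavorable, 4),
                       stringsAsFactors = FALSE)
  utils::write.csv(gc_out, file.path(out_dir, "group_comparisons.csv"),
                   row.names = FALSE)
  manifest <- list(package = "tbinet",
                   version = as.character(utils::packageVersion("tbinet")),
                   config = unclass_recursive(run$config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  lines <- c("Synthetic TBI cohort network-prognostics run",
             "============================================",
             "",
             sprintf("Subjects: %d  Parcels: %d  Timepoints: %d",
                     run$config$cohort$n_subjects, run$config$cohort$n_parcels,
                     run$config$cohort$n_timepoints),
             sprintf("Unfavorable outcomes: %d / %d",
                     sum(run$features$outcome == 1, na.rm = TRUE),
                     nrow(run$features)),
             sprintf("Median excluded voxels: %s%%",
                     fmt_num(stats::median(run$features$excluded_voxel_pct), 2)),
             sprintf("Median AMI vs template: %s",
                     fmt_num(stats::median(run$features$ami), 3)),
             "",
             "Model performance (Pseudo-R2 / AUROC / AIC):")
  if (nrow(perf_out)) {
    lines <- c(lines, sprintf("  %-42s %6s %6s %8s", "model", "R2", "AUROC", "AIC"),
               sprintf("  %-42s %6s %6s %8s", perf_out$model, perf_out$pseudo_r2,
                       perf_out$auroc, perf_out$aic))
  } else lines <- c(lines, "  (no models fitted: single-class outcome)")
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

# canonical zero-row feature table so an empty cohort still yields a
# report with headers
empty_features <- function(config) {
  nets <- if (config$cohort$n_networks == 7L) yeo7_networks else
    paste0("Net", seq_len(config$cohort$n_networks))
  cols <- c(as.vector(outer(c("pc_median", "pc_max", "pc_sd",
                              "mdz_median", "mdz_max", "mdz_sd"),
                            nets, paste, sep = "_")),
            "ami", "excluded_voxel_pct", "n_valid_parcels",
            "interhemi_global", "interhemi_dmn",
            "subject", "age", names(config$cohort$sedative_rates),
            "tai", "age_std", "outcome")
  df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  df
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else unclass(x)
}
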
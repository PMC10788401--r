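#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis — cohort sizes, seeds,
#' analysis window, thresholds, evaluation mode — into one serializable
#' object so that a run is reproducible bit-for-bit from (config, seed).
#'
#' @param n_stable,n_recanalized cohort sizes (defaults 57 and 9).
#' @param seed master seed; per-stage seeds derive from it.
#' @param window analysis window for feature extraction
#'   (`"second-cycle"` or `"full"`).
#' @param n_spatial_samples spatial samples per region.
#' @param effects an [effect_spec()].
#' @param waveform a [waveform_spec()].
#' @param alpha significance threshold (default 0.05).
#' @param vif_threshold VIF exclusion threshold (default 10).
#' @param eval `"resubstitution"` or `"cv"`.
#' @param n_boot bootstrap resamples for confidence intervals.
#' @param conf confidence level for bootstrap intervals.
#' @param cohort_dir optional directory of an existing serialized
#'   cohort to load instead of generating one.
#' @param out_dir output directory for the report bundle (`NULL`: no
#'   files written).
#' @return list of class `recan_config`.
#' @export
pipeline_config <- function(n_stable = 57, n_recanalized = 9, seed = 1,
                            window = "second-cycle",
                            n_spatial_samples = 200,
                            effects = default_effects(),
                            waveform = waveform_spec(),
                            alpha = 0.05, vif_threshold = 10,
                            eval = "resubstitution", n_boot = 2000,
                            conf = 0.95, cohort_dir = NULL,
                            out_dir = NULL) {
  structure(list(n_stable = n_stable, n_recanalized = n_recanalized,
                 seed = seed, window = window,
                 n_spatial_samples = n_spatial_samples, effects = effects,
                 waveform = waveform, alpha = alpha,
                 vif_threshold = vif_threshold, eval = eval,
                 n_boot = n_boot, conf = conf, cohort_dir = cohort_dir,
                 out_dir = out_dir),
            class = "recan_config")
}

write_table <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes cohort generation (or loading) -> feature extraction ->
#' group-difference screening -> univariate-predictor analysis ->
#' multivariate logistic modelling, and (when `out_dir` is set) writes
#' the report bundle: the feature table, clinical and feature
#' comparison tables, per-feature predictor performance, within-
#' parameter AUROC comparisons, model coefficient and performance
#' tables, ROC coordinates for the best univariate predictor and the
#' model, a JSON model card sufficient to score new patients, and a log
#' of the defaults exercised. A modelling-stage failure (for instance a
#' single-patient minority class) is reported with the earlier tables
#' already written.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with `cohort`, `features`, `group_stats`,
#'   `up`, `model`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "recan_config"))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    sprintf("seed: %d", config$seed),
    sprintf("window: %s", config$window),
    "percentile convention: linear interpolation (type 7)",
    "std convention: sample SD (n-1)",
    "chi-square: Yates continuity correction on 2x2 tables",
    "Levene center: mean",
    "cutoff criterion: Youden's J, ties toward higher specificity",
    "AUROC comparison: DeLong paired test",
    sprintf("evaluation: %s", config$eval))

  cohort <- if (!is.null(config$cohort_dir)) read_cohort(config$cohort_dir)
  else generate_cohort(config$n_stable, config$n_recanalized,
                       effects = config$effects, waveform = config$waveform,
                       n_spatial_samples = config$n_spatial_samples,
                       seed = config$seed)

  features <- extract_feature_table(cohort, window = config$window)
  write_table(features, out, "features.csv")

  # Each downstream stage is fenced: a failure (for instance too few
  # recanalized patients for the predictive stages) is reported with its
  # stage name while the tables already produced stay on disk.
  fail <- function(stage, e, partial) {
    log_lines <- c(log_lines, sprintf("%s stage FAILED: %s", stage,
                                      conditionMessage(e)))
    if (!is.null(out)) writeLines(log_lines, file.path(out, "log.txt"))
    warning(sprintf("%s stage failed (%s); earlier tables retained",
                    stage, conditionMessage(e)), call. = FALSE)
    invisible(c(partial, list(log = log_lines)))
  }

  gs <- tryCatch(compare_groups(features), error = function(e) e)
  if (inherits(gs, "error"))
    return(fail("group-statistics", gs,
                list(cohort = cohort, features = features,
                     group_stats = NULL, up = NULL, model = NULL)))
  write_table(gs, out, "group_comparison.csv")

  up <- tryCatch(
    evaluate_predictors(features,
                        feature_cols = c(hemodynamic_feature_names(),
                                         intersect(names(features),
                                                   morph_ratio_names)),
                        n_boot = 0, seed = config$seed),
    error = function(e) e)
  if (inherits(up, "error"))
    return(fail("univariate-predictor", up,
                list(cohort = cohort, features = features, group_stats = gs,
                     up = NULL, model = NULL)))
  write_table(up$performance, out, "up_performance.csv")
  write_table(up$comparisons, out, "auroc_comparisons.csv")

  model <- tryCatch(
    recan_lr(features, alpha = config$alpha,
             vif_threshold = config$vif_threshold, eval = config$eval,
             n_boot = config$n_boot, conf = config$conf,
             seed = config$seed),
    error = function(e) e)
  if (inherits(model, "error"))
    return(fail("modelling", model,
                list(cohort = cohort, features = features, group_stats = gs,
                     up = up, model = NULL)))

  write_table(model$coefficients, out, "model_coefficients.csv")
  if (!is.null(model$performance)) {
    best <- up$performance[1, ]
    tab6 <- rbind(
      data.frame(model = paste0("UP (", best$feature, ")"),
                 auroc = best$auroc, auprc = best$auprc,
                 cutoff = best$cutoff, sensitivity = best$sensitivity,
                 specificity = best$specificity),
      model$performance[c("model", "auroc", "auprc", "cutoff",
                          "sensitivity", "specificity")])
    write_table(tab6, out, "model_performance.csv")
    if (!is.null(out)) {
      write_table(roc_curve(features[[up$performance$feature[1]]],
                            features$label), out, "roc_best_up.csv")
      write_table(roc_curve(model$probs, model$labels_balanced), out,
                  "roc_lr.csv")
    }
  }
  if (!is.null(out)) {
    card <- list(selected = model$selected,
                 coefficients = model$coefficients,
                 scaling = list(center = as.list(model$scaling$center[model$selected]),
                                scale = as.list(model$scaling$scale[model$selected])),
                 cutoff = model$performance$cutoff,
                 config = list(alpha = config$alpha,
                               vif_threshold = config$vif_threshold,
                               eval = config$eval, seed = config$seed,
                               window = config$window))
    jsonlite::write_json(card, file.path(out, "model_card.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out, "log.txt"))
  }
  invisible(list(cohort = cohort, features = features, group_stats = gs,
                 up = up, model = model, log = log_lines))
}
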
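#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance
#' `P(score_pos > score_neg) + 0.5 * P(tie)` via midranks. The raw
#' feature orientation is kept: values below 0.5 are reported as-is,
#' never flipped.
#'
#' @param scores numeric per-patient values.
#' @param labels outcome labels; the positive class is `positive`.
#' @param positive positive-class label (default `"recanalized"`).
#' @return the AUROC.
#' @export
auroc <- function(scores, labels, positive = "recanalized") {
  y <- as_positive(labels, positive)
  m <- sum(y); n <- sum(!y)
  if (m == 0L || n == 0L) stop_recan("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - m * (m + 1) / 2) / (m * n)
}

#' ROC curve coordinates
#'
#' Sweeps the rule `score >= threshold` from strictest to loosest;
#' the curve runs from (FPR, TPR) = (0, 0) to (1, 1) with both rates
#' nondecreasing.
#'
#' @inheritParams auroc
#' @return data frame with `threshold`, `fpr`, `tpr`, `sensitivity`,
#'   `specificity`.
#' @export
roc_curve <- function(scores, labels, positive = "recanalized") {
  y <- as_positive(labels, positive)
  if (!any(y) || all(y)) stop_recan("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tp <- vapply(thr, function(t) sum(y & scores >= t), 0L)
  fp <- vapply(thr, function(t) sum(!y & scores >= t), 0L)
  tpr <- tp / sum(y); fpr <- fp / sum(!y)
  data.frame(threshold = thr, fpr = fpr, tpr = tpr,
             sensitivity = tpr, specificity = 1 - fpr)
}

#' Precision-recall curve coordinates
#'
#' @inheritParams auroc
#' @return data frame with `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(scores, labels, positive = "recanalized") {
  y <- as_positive(labels, positive)
  if (!any(y) || all(y)) stop_recan("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(y & scores >= t), 0L)
  fp <- vapply(thr, function(t) sum(!y & scores >= t), 0L)
  data.frame(threshold = thr, recall = tp / sum(y),
             precision = tp / (tp + fp))
}

#' Area under the precision-recall curve
#'
#' Area under the step curve (no interpolation between operating
#' points): `sum over thresholds of (recall_i - recall_{i-1}) *
#' precision_i`, with the positive class being recanalized.
#'
#' @inheritParams auroc
#' @return the AUPRC.
#' @export
auprc <- function(scores, labels, positive = "recanalized") {
  pc <- pr_curve(scores, labels, positive)
  sum(diff(c(0, pc$recall)) * pc$precision)
}

#' Optimal cut-off by Youden's J
#'
#' Chooses the threshold maximizing `J = sensitivity + specificity - 1`
#' under the rule `score >= cutoff` -> predict recanalized; ties are
#' broken toward higher specificity (the larger threshold).
#'
#' @inheritParams auroc
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
optimal_cutoff <- function(scores, labels, positive = "recanalized") {
  rc <- roc_curve(scores, labels, positive)
  j <- rc$sensitivity + rc$specificity - 1
  best <- which(j == max(j))
  pick <- best[which.max(rc$specificity[best])]
  list(cutoff = rc$threshold[pick], sensitivity = rc$sensitivity[pick],
       specificity = rc$specificity[pick], youden = j[pick])
}

#' Stratified bootstrap confidence interval for a ranking metric
#'
#' Percentile interval from resampling patients within each outcome
#' class (so every resample retains both classes). Deterministic given
#' `seed`.
#'
#' @inheritParams auroc
#' @param metric `"auroc"` or `"auprc"`, or a function
#'   `f(scores, labels)`.
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param conf confidence level (default 0.95; use 0.90 for a 5th-95th
#'   percentile interval).
#' @param seed integer seed.
#' @return list with `estimate`, `lower`, `upper`, `conf`, `n_boot`.
#' @export
bootstrap_ci <- function(metric, scores, labels, n_boot = 2000,
                         conf = 0.95, seed = 1, positive = "recanalized") {
  if (n_boot < 100) stop_recan("n_boot must be >= 100")
  fn <- if (is.function(metric)) metric else
    switch(match.arg(metric, c("auroc", "auprc")),
           auroc = function(s, l) auroc(s, l, positive),
           auprc = function(s, l) auprc(s, l, positive))
  y <- as_positive(labels, positive)
  ip <- which(y); im <- which(!y)
  set.seed(seed)
  stats_b <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(ip, length(ip), replace = TRUE),
             sample(im, length(im), replace = TRUE))
    fn(scores[idx], y[idx])
  }, 0)
  a <- (1 - conf) / 2
  qs <- stats::quantile(stats_b, c(a, 1 - a), names = FALSE, type = 7)
  list(estimate = fn(scores, y), lower = qs[1], upper = qs[2],
       conf = conf, n_boot = n_boot)
}

# DeLong structural components for one predictor: V10 over positives,
# V01 over negatives.
delong_components <- function(scores, y) {
  x <- scores[y]; z <- scores[!y]
  psi <- outer(x, z, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong paired test for two AUROCs
#'
#' Two-sided test of equal AUROC for two predictors scored on the same
#' patients, using DeLong's jackknife structural components.
#'
#' @param scores1,scores2 per-patient scores for the two predictors
#'   (same patients, same order).
#' @inheritParams auroc
#' @return list with `auroc1`, `auroc2`, `statistic` (z), `p_value`.
#' @export
compare_aurocs <- function(scores1, scores2, labels,
                           positive = "recanalized") {
  if (length(scores1) != length(scores2) ||
      length(scores1) != length(labels))
    stop_recan("predictors must be paired on the same patients")
  y <- as_positive(labels, positive)
  if (!any(y) || all(y)) stop_recan("both classes must be present")
  c1 <- delong_components(scores1, y)
  c2 <- delong_components(scores2, y)
  m <- sum(y); n <- sum(!y)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- c1$auc - c2$auc
  if (v <= .Machine$double.eps) {
    p <- if (abs(d) < sqrt(.Machine$double.eps)) 1 else 0
    return(list(auroc1 = c1$auc, auroc2 = c2$auc, statistic = 0,
                p_value = p))
  }
  z <- d / sqrt(v)
  list(auroc1 = c1$auc, auroc2 = c2$auc, statistic = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

feature_family <- function(name) {
  ifelse(startsWith(name, "FR_"), "FR", sub("^([^_]+)_.*$", "\\1", name))
}

#' Evaluate every feature as a univariate predictor
#'
#' Computes AUROC, AUPRC and the Youden operating point for each
#' feature (optionally with stratified-bootstrap CIs), ranks features by
#' AUROC, and runs DeLong paired AUROC comparisons between the 14
#' spatiotemporal features within each hemodynamic parameter (and among
#' the seven FR features). Per-feature failures are recorded, not
#' propagated.
#'
#' @param features feature table (data frame) including `label_col`.
#' @param label_col outcome column name.
#' @param feature_cols columns to evaluate; defaults to the table's
#'   `feature_cols` attribute, else all numeric columns.
#' @param positive positive-class label.
#' @param n_boot bootstrap resamples for CIs; 0 (default) skips CIs.
#' @param conf confidence level for CIs.
#' @param seed integer seed for the bootstrap.
#' @param comparisons run the within-parameter pairwise AUROC tests.
#' @return list of class `recan_up`: `performance` (ranked data frame)
#'   and `comparisons` (data frame, possibly empty).
#' @export
evaluate_predictors <- function(features, label_col = "label",
                                feature_cols = NULL,
                                positive = "recanalized",
                                n_boot = 0, conf = 0.95, seed = 1,
                                comparisons = TRUE) {
  if (is.null(feature_cols))
    feature_cols <- attr(features, "feature_cols") %||%
      setdiff(names(features)[vapply(features, is.numeric, TRUE)], label_col)
  labels <- features[[label_col]]
  y <- as_positive(labels, positive)
  if (sum(y) < 2L || sum(!y) < 2L)
    stop_recan("need at least 2 patients per class")

  rows <- lapply(feature_cols, function(nm) {
    s <- features[[nm]]
    res <- tryCatch({
      cut <- optimal_cutoff(s, y)
      r <- data.frame(feature = nm, auroc = auroc(s, y),
                      auprc = auprc(s, y), cutoff = cut$cutoff,
                      sensitivity = cut$sensitivity,
                      specificity = cut$specificity,
                      stringsAsFactors = FALSE)
      if (n_boot > 0) {
        ci_roc <- bootstrap_ci("auroc", s, y, n_boot, conf, seed)
        ci_prc <- bootstrap_ci("auprc", s, y, n_boot, conf, seed)
        r$auroc_lower <- ci_roc$lower; r$auroc_upper <- ci_roc$upper
        r$auprc_lower <- ci_prc$lower; r$auprc_upper <- ci_prc$upper
      }
      r$error <- NA_character_
      r
    }, error = function(e) {
      data.frame(feature = nm, auroc = NA_real_, auprc = NA_real_,
                 cutoff = NA_real_, sensitivity = NA_real_,
                 specificity = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  perf <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(c("feature", "auroc", "auprc", "cutoff", "sensitivity",
                "specificity", "auroc_lower", "auroc_upper", "auprc_lower",
                "auprc_upper", "error"), names(r))] <- NA_real_
    r
  }))
  perf <- perf[order(-perf$auroc), , drop = FALSE]
  perf$rank <- seq_len(nrow(perf))

  comp <- data.frame(feature1 = character(), auroc1 = numeric(),
                     feature2 = character(), auroc2 = numeric(),
                     p_value = numeric(), stringsAsFactors = FALSE)
  if (comparisons) {
    hemo <- intersect(feature_cols, hemodynamic_feature_names())
    fams <- split(hemo, feature_family(hemo))
    for (members in fams) {
      if (length(members) < 2L) next
      pairs <- utils::combn(members, 2)
      for (k in seq_len(ncol(pairs))) {
        f1 <- pairs[1, k]; f2 <- pairs[2, k]
        d <- tryCatch(compare_aurocs(features[[f1]], features[[f2]], y),
                      error = function(e) NULL)
        if (is.null(d)) next
        comp <- rbind(comp, data.frame(
          feature1 = f1, auroc1 = d$auroc1, feature2 = f2,
          auroc2 = d$auroc2, p_value = d$p_value,
          stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(performance = perf, comparisons = comp),
            class = "recan_up")
}

#' @export
print.recan_up <- function(x, n = 10, ...) {
  cat(sprintf("<recan_up> %d features evaluated; top %d by AUROC:\n",
              nrow(x$performance), min(n, nrow(x$performance))))
  print(utils::head(x$performance[, c("rank", "feature", "auroc", "auprc",
                                      "sensitivity", "specificity")], n),
        row.names = FALSE, digits = 3)
  if (nrow(x$comparisons)) {
    sig <- sum(x$comparisons$p_value < 0.05, na.rm = TRUE)
    cat(sprintf("%d within-parameter AUROC pairs, %d with p < 0.05\n",
                nrow(x$comparisons), sig))
  }
  invisible(x)
}
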
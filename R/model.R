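#' Standardize feature columns
#'
#' Centers each column to mean 0 and scales to sample SD 1, keeping the
#' scaling parameters for the inverse transform (and for scoring new
#' patients on the training scale).
#'
#' @param x numeric data frame or matrix of features.
#' @return standardized data frame with attributes `center` and `scale`.
#' @export
standardize_features <- function(x) {
  x <- as.data.frame(x)
  ctr <- vapply(x, mean, 0)
  scl <- vapply(x, stats::sd, 0)
  zero <- names(scl)[scl == 0]
  if (length(zero))
    stop_recan("zero-variance feature(s): %s", paste(zero, collapse = ", "))
  out <- as.data.frame(Map(function(v, m, s) (v - m) / s, x, ctr, scl))
  names(out) <- names(x)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Invert [standardize_features()]
#'
#' @param x standardized data frame carrying `center`/`scale`
#'   attributes, or a new data frame plus explicit parameters.
#' @param center,scale scaling parameters (default: taken from `x`).
#' @return data frame on the original scale.
#' @export
unstandardize_features <- function(x, center = attr(x, "center"),
                                   scale = attr(x, "scale")) {
  out <- as.data.frame(Map(function(v, m, s) v * s + m,
                           as.data.frame(x), center[names(x)],
                           scale[names(x)]))
  names(out) <- names(x)
  out
}

# Wald p-values from a glm fit, excluding the intercept.
wald_p <- function(fit) {
  cf <- summary(fit)$coefficients
  p <- cf[, "Pr(>|z|)"]
  p[names(p) != "(Intercept)"]
}

glm_separated <- function(fit, coef_limit = 15) {
  probs <- fitted(fit)
  any(abs(stats::coef(fit)[-1]) > coef_limit, na.rm = TRUE) ||
    all(probs > 1 - 1e-8 | probs < 1e-8)
}

#' Univariate logistic-regression screen
#'
#' Fits one single-covariate logistic regression per feature and keeps
#' those with a Wald p-value below `alpha`. Features showing complete
#' separation are flagged and excluded (their Wald p-value is
#' meaningless), with a warning.
#'
#' @param x numeric data frame of (standardized) features.
#' @param labels outcome labels; positive class `positive`.
#' @param alpha retention threshold (default 0.05).
#' @param positive positive-class label.
#' @return data frame: `feature`, `coefficient`, `p_value`, `separated`,
#'   `retained`.
#' @export
univariate_lr_screen <- function(x, labels, alpha = 0.05,
                                 positive = "recanalized") {
  y <- as_positive(labels, positive)
  if (!any(y) || all(y)) stop_recan("both classes must be present")
  rows <- lapply(names(x), function(nm) {
    d <- data.frame(y = y, v = x[[nm]])
    fit <- suppressWarnings(stats::glm(y ~ v, family = stats::binomial(),
                                       data = d))
    sep <- glm_separated(fit)
    p <- if (sep) NA_real_ else unname(wald_p(fit))
    data.frame(feature = nm, coefficient = unname(stats::coef(fit)["v"]),
               p_value = p, separated = sep,
               retained = isTRUE(p < alpha), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$separated))
    warning(sprintf("excluded %d feature(s) with complete separation: %s",
                    sum(out$separated),
                    paste(out$feature[out$separated], collapse = ", ")),
            call. = FALSE)
  out
}

#' Iterative variance-inflation-factor filter
#'
#' Computes `VIF_j = 1 / (1 - R^2_j)` for each feature regressed on the
#' other surviving features and repeatedly removes the feature with the
#' largest VIF until all VIFs are at or below `threshold`. Exact
#' collinearity (R^2 of 1) yields an infinite VIF and is removed first.
#'
#' @param x numeric data frame of candidate features (>= 2 columns).
#' @param threshold VIF exclusion threshold (default 10).
#' @return list with `report` (data frame: `feature`, `vif`, `excluded`,
#'   `iteration`) and `selected` (surviving feature names).
#' @export
vif_filter <- function(x, threshold = 10) {
  x <- as.data.frame(x)
  if (ncol(x) < 2L) stop_recan("VIF needs at least 2 features")
  # VIF_j = 1/(1 - R^2_j) equals the j-th diagonal of the inverse
  # correlation matrix; fall back to per-feature regressions when the
  # matrix is (near-)singular, where Inf marks exact collinearity.
  vif_of <- function(d) {
    R <- stats::cor(d)
    inv <- tryCatch(solve(R), error = function(e) NULL)
    if (!is.null(inv) && all(diag(inv) >= 1 - 1e-8))
      return(stats::setNames(pmax(diag(inv), 1), names(d)))
    vapply(names(d), function(nm) {
      fit <- stats::lm(d[[nm]] ~ ., data = d[setdiff(names(d), nm)])
      r2 <- suppressWarnings(summary(fit))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
  }
  report <- data.frame(feature = character(), vif = numeric(),
                       excluded = logical(), iteration = integer(),
                       stringsAsFactors = FALSE)
  keep <- names(x)
  iter <- 0L
  repeat {
    if (length(keep) < 2L) break
    v <- vif_of(x[keep])
    if (max(v) <= threshold) break
    iter <- iter + 1L
    worst <- names(v)[which.max(v)]
    report <- rbind(report, data.frame(feature = worst, vif = unname(v[worst]),
                                       excluded = TRUE, iteration = iter,
                                       stringsAsFactors = FALSE))
    keep <- setdiff(keep, worst)
  }
  final_v <- if (length(keep) >= 2L) vif_of(x[keep]) else
    stats::setNames(rep(1, length(keep)), keep)
  report <- rbind(report, data.frame(feature = keep,
                                     vif = unname(final_v[keep]),
                                     excluded = FALSE, iteration = NA_integer_,
                                     stringsAsFactors = FALSE))
  list(report = report, selected = keep)
}

#' SMOTE oversampling of the minority class
#'
#' Synthetic minority oversampling: each synthetic patient lies on the
#' segment between a minority-class patient and one of its `k` nearest
#' minority neighbors (Euclidean distance in feature space), at a
#' uniform random position along the segment. The original patients are
#' preserved, and the output classes have equal counts. Deterministic
#' given `seed`.
#'
#' @param x numeric data frame of features.
#' @param labels outcome labels.
#' @param k_neighbors number of nearest neighbors (default 5); reduced
#'   with a warning when the minority class is too small.
#' @param seed integer seed.
#' @param positive positive-class (minority) label.
#' @return list with `x` (balanced features), `labels`, `synthetic`
#'   (logical marker for generated rows).
#' @export
smote_oversample <- function(x, labels, k_neighbors = 5, seed = 1,
                             positive = "recanalized") {
  x <- as.data.frame(x)
  y <- as_positive(labels, positive)
  n_min <- sum(y); n_maj <- sum(!y)
  if (n_min == n_maj) {
    return(list(x = x, labels = labels,
                synthetic = rep(FALSE, nrow(x))))
  }
  minority_pos <- n_min < n_maj
  idx_min <- which(y == minority_pos)
  n_syn <- abs(n_maj - n_min)
  k <- k_neighbors
  if (length(idx_min) <= k) {
    k <- length(idx_min) - 1L
    warning(sprintf("minority class too small for k = %d; using k = %d",
                    k_neighbors, k), call. = FALSE)
  }
  if (k < 1L) stop_recan("minority class needs at least 2 members")
  xm <- as.matrix(x[idx_min, , drop = FALSE])
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  set.seed(seed)
  base <- rep_len(seq_along(idx_min), n_syn)
  pick <- nn[cbind(base, sample.int(k, n_syn, replace = TRUE))]
  lambda <- stats::runif(n_syn)
  syn <- xm[base, , drop = FALSE] +
    lambda * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  syn <- as.data.frame(syn)
  names(syn) <- names(x)
  lab_min <- if (minority_pos) positive else
    setdiff(unique(as.character(labels)), positive)[1]
  out_labels <- c(as.character(labels), rep(lab_min, n_syn))
  list(x = rbind(x, syn), labels = out_labels,
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_syn)))
}

#' Backward stepwise logistic regression by Wald p-values
#'
#' Fits the full multivariate logistic model, then iteratively drops the
#' feature with the largest Wald p-value at or above `alpha` and refits,
#' until every remaining feature has p below `alpha`. An empty
#' (intercept-only) model is a valid outcome.
#'
#' @param x numeric data frame of candidate features.
#' @param labels outcome labels (possibly SMOTE-balanced).
#' @param alpha stay-in threshold (default 0.05).
#' @param positive positive-class label.
#' @return list with `fit` (the final `glm`), `selected` (feature
#'   names), `trace` (data frame of drops).
#' @export
stepwise_lr <- function(x, labels, alpha = 0.05, positive = "recanalized") {
  y <- as_positive(labels, positive)
  keep <- names(x)
  trace <- data.frame(step = integer(), dropped = character(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    d <- data.frame(y = y, x[keep], check.names = FALSE)
    fit <- suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                                       data = d))
    if (!length(keep)) break
    # Aliased or NA-p terms count as worst (Inf) so they are dropped first.
    p_full <- stats::setNames(rep(Inf, length(keep)), keep)
    p <- wald_p(fit)
    p <- p[!is.na(p)]
    p_full[intersect(names(p), keep)] <- p[intersect(names(p), keep)]
    if (max(p_full) < alpha) break
    worst <- names(p_full)[which.max(p_full)]
    pw <- if (is.finite(p_full[worst])) unname(p_full[worst]) else NA_real_
    step_i <- step_i + 1L
    trace <- rbind(trace, data.frame(step = step_i, dropped = worst,
                                     p_value = pw, stringsAsFactors = FALSE))
    keep <- setdiff(keep, worst)
  }
  list(fit = fit, selected = keep, trace = trace)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk calibration test: patients are grouped into
#' `n_bins` bins by fitted probability (empty or duplicate-quantile
#' bins are merged), and the chi-square statistic
#' `sum (O_g - E_g)^2 / (E_g (1 - E_g / n_g))` is referred to a
#' chi-square distribution with `bins - 2` degrees of freedom. High
#' p-values indicate good calibration.
#'
#' @param fitted_probabilities predicted event probabilities in (0, 1).
#' @param labels observed outcomes.
#' @param n_bins target number of risk bins (default 10, minimum 3).
#' @param positive positive-class label.
#' @return list with `statistic`, `df`, `p_value`, `bins` (per-bin
#'   observed/expected table).
#' @export
hosmer_lemeshow <- function(fitted_probabilities, labels, n_bins = 10,
                            positive = "recanalized") {
  if (n_bins < 3) stop_recan("n_bins must be >= 3")
  p <- fitted_probabilities
  y <- as_positive(labels, positive)
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = n_bins + 1),
                               type = 7))
  if (length(br) < 4)
    stop_recan("fitted probabilities too concentrated to form >= 3 bins")
  g <- cut(p, breaks = br, include.lowest = TRUE)
  counts <- table(g)
  if (any(counts == 0)) g <- droplevels(g)
  obs <- tapply(as.numeric(y), g, sum)
  exp_ <- tapply(p, g, sum)
  n_g <- tapply(p, g, length)
  stat <- sum((obs - exp_)^2 / (exp_ * (1 - exp_ / n_g)))
  df <- length(obs) - 2
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       bins = data.frame(n = as.vector(n_g), observed = as.vector(obs),
                         expected = as.vector(exp_)))
}

#' Fit the multivariate recanalization model
#'
#' The central fitting routine. Runs the full modelling pipeline on a
#' patient-by-feature table: (1) standardize features to mean 0 / SD 1;
#' (2) univariate logistic screen, retaining features with Wald p <
#' `alpha`; (3) iterative VIF filter removing multicollinear features
#' (VIF > `vif_threshold`); (4) SMOTE oversampling of the recanalized
#' class to balance the outcome; (5) backward stepwise multivariate
#' logistic regression until all retained features have p < `alpha`;
#' (6) Hosmer-Lemeshow calibration test; (7) ROC/PRC evaluation of the
#' fitted probabilities with bootstrap confidence intervals
#' (resubstitution on the balanced set by default — an optimistic
#' protocol, mirrored deliberately; see `eval`).
#'
#' @param data data frame with the outcome column and numeric features
#'   (e.g. from [extract_feature_table()]; non-numeric columns and `id`
#'   are ignored).
#' @param label_col outcome column name (default `"label"`).
#' @param features character vector of candidate feature columns;
#'   default: all numeric columns except the label. Zero-variance
#'   candidates are dropped with a warning.
#' @param positive positive-class label (default `"recanalized"`).
#' @param alpha significance threshold for the screen and the stepwise
#'   stay-in rule (default 0.05).
#' @param vif_threshold VIF exclusion threshold (default 10).
#' @param smote apply SMOTE before the multivariate fit (default TRUE).
#' @param k_smote SMOTE neighbor count (default 5, capped at minority
#'   size - 1).
#' @param eval `"resubstitution"` (default) or `"cv"` (adds stratified
#'   5-fold cross-validated AUROC of the selected model to the
#'   performance report; the optimism of resubstitution-with-SMOTE is
#'   the reason this option exists).
#' @param n_boot bootstrap resamples for performance CIs (default 2000;
#'   0 skips CIs).
#' @param conf confidence level for performance CIs (default 0.95).
#' @param ci_level coefficient interval coverage for the reported
#'   percentile bounds (default 0.90, printed as 5 % and 95 % bounds).
#' @param seed integer seed (SMOTE and bootstrap).
#' @return an object of class `recan_lr`; see Details.
#' @details The returned object contains `screening`, `vif`, `smote`
#'   (balanced-set bookkeeping), `fit` (the final `glm`),
#'   `coefficients` (feature, coefficient, odds ratio, interval bounds,
#'   p-value), `hosmer_lemeshow`, `performance` (AUROC/AUPRC with CIs,
#'   Youden cutoff, sensitivity, specificity), `scaling` and `config`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `plot`.
#' @examples
#' cohort <- generate_cohort(n_stable = 30, n_recanalized = 8,
#'                           n_spatial_samples = 20,
#'                           waveform = waveform_spec(sampling_interval = 0.05),
#'                           seed = 7)
#' tab <- extract_feature_table(cohort)
#' fit <- recan_lr(tab, n_boot = 200, seed = 7)
#' print(fit)
#' @export
recan_lr <- function(data, label_col = "label", features = NULL,
                     positive = "recanalized", alpha = 0.05,
                     vif_threshold = 10, smote = TRUE, k_smote = 5,
                     eval = c("resubstitution", "cv"), n_boot = 2000,
                     conf = 0.95, ci_level = 0.90, seed = 1) {
  eval <- match.arg(eval)
  cl <- match.call()
  labels <- data[[label_col]]
  y <- as_positive(labels, positive)
  if (sum(y) < 2L || sum(!y) < 2L)
    stop_recan("need at least 2 patients per class to fit the model")
  if (is.null(features))
    features <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                        label_col)
  x <- data[features]
  const <- vapply(x, function(v) stats::sd(v) == 0, TRUE)
  if (any(const)) {
    warning(sprintf("dropping zero-variance feature(s): %s",
                    paste(names(x)[const], collapse = ", ")), call. = FALSE)
    x <- x[!const]
  }

  xs <- standardize_features(x)
  scaling <- list(center = attr(xs, "center"), scale = attr(xs, "scale"))

  screening <- univariate_lr_screen(xs, y, alpha = alpha)
  retained <- screening$feature[screening$retained]

  vif <- NULL
  survivors <- retained
  if (length(retained) >= 2L) {
    vif <- vif_filter(xs[retained], threshold = vif_threshold)
    survivors <- vif$selected
  }

  if (!length(survivors)) {
    bal <- list(x = xs, labels = ifelse(y, positive, "stable"),
                synthetic = rep(FALSE, nrow(xs)))
    sel <- list(fit = suppressWarnings(
      stats::glm(y ~ 1, family = stats::binomial(),
                 data = data.frame(y = y))),
      selected = character(), trace = NULL)
  } else {
    if (smote) {
      bal <- smote_oversample(xs[survivors], ifelse(y, positive, "stable"),
                              k_neighbors = k_smote, seed = seed,
                              positive = positive)
    } else {
      bal <- list(x = xs[survivors], labels = ifelse(y, positive, "stable"),
                  synthetic = rep(FALSE, nrow(xs)))
    }
    sel <- stepwise_lr(bal$x, bal$labels, alpha = alpha, positive = positive)
  }

  fit <- sel$fit
  cf <- summary(fit)$coefficients
  zc <- stats::qnorm(1 - (1 - ci_level) / 2)
  coefs <- data.frame(
    term = rownames(cf),
    coefficient = cf[, "Estimate"],
    odds_ratio = exp(cf[, "Estimate"]),
    or_lower = exp(cf[, "Estimate"] - zc * cf[, "Std. Error"]),
    or_upper = exp(cf[, "Estimate"] + zc * cf[, "Std. Error"]),
    p_value = cf[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)

  probs <- as.numeric(fitted(fit))
  y_bal <- as_positive(bal$labels, positive)
  hl <- if (length(sel$selected))
    tryCatch(hosmer_lemeshow(probs, y_bal), error = function(e) NULL)
  else NULL

  perf <- NULL
  if (length(sel$selected)) {
    cut <- optimal_cutoff(probs, y_bal)
    perf <- data.frame(model = "LR", auroc = auroc(probs, y_bal),
                       auprc = auprc(probs, y_bal), cutoff = cut$cutoff,
                       sensitivity = cut$sensitivity,
                       specificity = cut$specificity)
    if (n_boot > 0) {
      ci_roc <- bootstrap_ci("auroc", probs, y_bal, n_boot, conf, seed)
      ci_prc <- bootstrap_ci("auprc", probs, y_bal, n_boot, conf, seed)
      perf$auroc_lower <- ci_roc$lower; perf$auroc_upper <- ci_roc$upper
      perf$auprc_lower <- ci_prc$lower; perf$auprc_upper <- ci_prc$upper
    }
  }

  obj <- structure(
    list(call = cl, selected = sel$selected, coefficients = coefs,
         fit = fit, scaling = scaling, screening = screening, vif = vif,
         smote = list(applied = smote && length(survivors) > 0,
                      labels = bal$labels, synthetic = bal$synthetic,
                      x = bal$x, k = k_smote),
         stepwise_trace = sel$trace, hosmer_lemeshow = hl,
         performance = perf, positive = positive, label_col = label_col,
         probs = probs, labels_balanced = y_bal,
         config = list(alpha = alpha, vif_threshold = vif_threshold,
                       smote = smote, k_smote = k_smote, eval = eval,
                       n_boot = n_boot, conf = conf, ci_level = ci_level,
                       seed = seed)),
    class = "recan_lr")

  if (eval == "cv" && length(sel$selected)) {
    obj$cv_auroc <- cv_auroc(xs[sel$selected], y, positive, seed)
  }
  obj
}

# Stratified 5-fold cross-validated AUROC for a fixed feature set.
cv_auroc <- function(x, y, positive, seed, k_folds = 5) {
  set.seed(seed)
  fold <- integer(length(y))
  fold[y] <- sample(rep_len(seq_len(k_folds), sum(y)))
  fold[!y] <- sample(rep_len(seq_len(k_folds), sum(!y)))
  preds <- numeric(length(y))
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    d <- data.frame(y = y[tr], x[tr, , drop = FALSE], check.names = FALSE)
    fit <- suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                                       data = d))
    nd <- data.frame(x[!tr, , drop = FALSE], check.names = FALSE)
    preds[!tr] <- stats::predict(fit, newdata = nd, type = "response")
  }
  auroc(preds, y)
}

#' @export
print.recan_lr <- function(x, ...) {
  cat("Multivariate logistic recanalization model\n")
  if (!length(x$selected)) {
    cat("  (empty model: no feature survived selection)\n")
    return(invisible(x))
  }
  cat(sprintf("  selected features: %s\n", paste(x$selected, collapse = ", ")))
  print(x$coefficients, digits = 4, row.names = FALSE)
  if (!is.null(x$hosmer_lemeshow))
    cat(sprintf("  Hosmer-Lemeshow: chi2 = %.3f (df %d), p = %.3f\n",
                x$hosmer_lemeshow$statistic, x$hosmer_lemeshow$df,
                x$hosmer_lemeshow$p_value))
  if (!is.null(x$performance))
    cat(sprintf("  AUROC %.3f / AUPRC %.3f; cutoff %.3f -> sens %.3f, spec %.3f\n",
                x$performance$auroc, x$performance$auprc,
                x$performance$cutoff, x$performance$sensitivity,
                x$performance$specificity))
  if (!is.null(x$cv_auroc))
    cat(sprintf("  5-fold CV AUROC: %.3f\n", x$cv_auroc))
  invisible(x)
}

#' @export
summary.recan_lr <- function(object, ...) {
  print(object)
  scr <- object$screening
  cat(sprintf("\nUnivariate screen: %d/%d features retained (p < %g)\n",
              sum(scr$retained), nrow(scr), object$config$alpha))
  if (!is.null(object$vif))
    cat(sprintf("VIF filter: removed %d, kept %d (threshold %g)\n",
                sum(object$vif$report$excluded),
                length(object$vif$selected), object$config$vif_threshold))
  if (isTRUE(object$smote$applied))
    cat(sprintf("SMOTE: %d synthetic minority patients added (k = %d)\n",
                sum(object$smote$synthetic), object$smote$k))
  invisible(object)
}

#' @export
coef.recan_lr <- function(object, ...) {
  stats::setNames(object$coefficients$coefficient,
                  object$coefficients$term)
}

#' Predict recanalization probability for new patients
#'
#' New data on the original feature scale is standardized with the
#' training scaling parameters and scored by the fitted logistic model.
#'
#' @param object a `recan_lr` fit.
#' @param newdata data frame containing the selected feature columns on
#'   the original (unstandardized) scale.
#' @param type `"response"` (probability), `"link"` (log-odds) or
#'   `"class"` (thresholded at the Youden cutoff).
#' @param ... unused.
#' @return numeric vector (or character vector for `type = "class"`).
#' @export
predict.recan_lr <- function(object, newdata,
                             type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  if (!length(object$selected))
    stop_recan("empty model: nothing to predict with")
  miss <- setdiff(object$selected, names(newdata))
  if (length(miss))
    stop_recan("newdata is missing feature(s): %s",
               paste(miss, collapse = ", "))
  ctr <- object$scaling$center; scl <- object$scaling$scale
  xs <- as.data.frame(Map(function(nm) (newdata[[nm]] - ctr[[nm]]) / scl[[nm]],
                          object$selected))
  names(xs) <- object$selected
  pr <- stats::predict(object$fit, newdata = xs,
                       type = if (type == "link") "link" else "response")
  pr <- as.numeric(pr)
  if (type == "class") {
    cut <- object$performance$cutoff %||% 0.5
    return(ifelse(pr >= cut, object$positive, "stable"))
  }
  pr
}

#' ROC curve of the fitted model
#'
#' @param x a `recan_lr` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.recan_lr <- function(x, ...) {
  if (!length(x$selected)) stop_recan("empty model: no curve to plot")
  rc <- roc_curve(x$probs, x$labels_balanced)
  graphics::plot(rc$fpr, rc$tpr, type = "s", xlab = "1 - specificity",
                 ylab = "Sensitivity",
                 main = sprintf("LR model ROC (AUROC %.3f)",
                                auroc(x$probs, x$labels_balanced)), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Evaluate a fitted model as a predictor
#'
#' Scores the fit on a feature table (default: the balanced training
#' set, i.e. resubstitution) and reports AUROC/AUPRC with stratified
#' bootstrap CIs plus the Youden operating point.
#'
#' @param fit a `recan_lr`.
#' @param data optional data frame with feature columns on the original
#'   scale and the outcome column; default: the balanced training set.
#' @param n_boot,conf,seed bootstrap settings (defaults from the fit's
#'   config).
#' @return one-row data frame like the fit's `performance` element.
#' @export
evaluate_model <- function(fit, data = NULL, n_boot = NULL, conf = NULL,
                           seed = NULL) {
  stopifnot(inherits(fit, "recan_lr"))
  n_boot <- n_boot %||% fit$config$n_boot
  conf <- conf %||% fit$config$conf
  seed <- seed %||% fit$config$seed
  if (is.null(data)) {
    probs <- fit$probs
    y <- fit$labels_balanced
  } else {
    probs <- predict(fit, data)
    y <- as_positive(data[[fit$label_col]], fit$positive)
  }
  cut <- optimal_cutoff(probs, y)
  out <- data.frame(model = "LR", auroc = auroc(probs, y),
                    auprc = auprc(probs, y), cutoff = cut$cutoff,
                    sensitivity = cut$sensitivity,
                    specificity = cut$specificity)
  if (n_boot > 0) {
    ci_roc <- bootstrap_ci("auroc", probs, y, n_boot, conf, seed)
    ci_prc <- bootstrap_ci("auprc", probs, y, n_boot, conf, seed)
    out$auroc_lower <- ci_roc$lower; out$auroc_upper <- ci_roc$upper
    out$auprc_lower <- ci_prc$lower; out$auprc_upper <- ci_prc$upper
  }
  out
}
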
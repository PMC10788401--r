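#' Levene's test for equality of variances
#'
#' Classic Levene test (absolute deviations from the group mean, one-way
#' ANOVA F), used to gate the choice between the pooled and Welch
#' two-sample t-tests.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @return the p-value.
#' @export
levene_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop_recan("each sample needs at least 2 values")
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  z <- c(x, y)
  dev <- abs(z - ave(z, g))
  if (all(dev == 0))
    stop_recan("degenerate Levene test: data constant within groups")
  res <- car::leveneTest(z, g, center = mean)
  as.numeric(res[1, "Pr(>F)"])
}

#' Levene-gated two-sample comparison
#'
#' Tests a continuous feature for a group difference: Levene's test
#' decides between the pooled-variance t-test (equal variances,
#' `levene_p >= alpha_levene`) and Welch's t-test (unequal variances).
#'
#' @param x,y numeric samples (stable and recanalized groups).
#' @param alpha_levene significance level of the variance gate
#'   (default 0.05).
#' @return one-row data frame: group means and SDs, `levene_p`,
#'   `test_used` (`"welch_t"` or `"pooled_t"`), `p_value`, `significant`
#'   (at 0.05).
#' @export
two_sample_test <- function(x, y, alpha_levene = 0.05) {
  lev <- levene_test(x, y)
  welch <- lev < alpha_levene
  tt <- stats::t.test(x, y, var.equal = !welch)
  p <- tt$p.value
  data.frame(mean_x = mean(x), sd_x = stats::sd(x),
             mean_y = mean(y), sd_y = stats::sd(y),
             levene_p = lev,
             test_used = if (welch) "welch_t" else "pooled_t",
             p_value = p, significant = p < 0.05,
             stringsAsFactors = FALSE)
}

#' Two-sample t-test from summary statistics
#'
#' Computes the two-sided t-test p-value from group means, SDs and
#' sizes only — the t statistic depends on the data only through these
#' moments, so this reproduces the p-value of any raw sample with the
#' same summaries. Useful for checking published mean-and-SD tables.
#'
#' @param mean1,sd1,n1 first group summaries.
#' @param mean2,sd2,n2 second group summaries.
#' @param var_equal use the pooled-variance test (default `FALSE`,
#'   i.e. Welch with Satterthwaite degrees of freedom).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                var_equal = FALSE) {
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    a <- sd1^2 / n1
    b <- sd2^2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Chi-square test for a contingency table
#'
#' Pearson chi-square test of independence; 2x2 tables use the Yates
#' continuity correction (this choice exactly reproduces the reference
#' clinical-covariate p-values that the uncorrected test does not).
#'
#' @param table matrix of non-negative integer counts with positive
#'   margins.
#' @return the p-value.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop_recan("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_recan("degenerate table: zero margin")
  correct <- nrow(table) == 2L && ncol(table) == 2L
  res <- suppressWarnings(stats::chisq.test(table, correct = correct))
  as.numeric(res$p.value)
}

#' Group-difference screen over a feature table
#'
#' One Levene-gated t-test per continuous feature and one chi-square
#' test per categorical covariate, comparing stable versus recanalized
#' patients. Constant features are reported with a `degenerate` flag
#' rather than aborting the batch. No multiplicity correction is
#' applied (raw p-values are reported, a deliberate caveat).
#'
#' @param features feature table from [extract_feature_table()], or any
#'   data frame with a `label` column.
#' @param label_col name of the outcome column (default `"label"`).
#' @param categorical names of categorical covariate columns present in
#'   `features` to test by chi-square.
#' @param collapse_location optional named character vector mapping
#'   location levels to collapsed categories before the chi-square test
#'   (sparse location subtypes can be merged this way).
#' @return data frame sorted by p-value: `feature`, group means/SDs,
#'   `levene_p`, `test_used`, `p_value`, `significant`, `degenerate`.
#' @export
compare_groups <- function(features, label_col = "label",
                           categorical = intersect(c("sex", "rupture",
                                                     "location"),
                                                   names(features)),
                           collapse_location = NULL) {
  lab <- features[[label_col]]
  if (length(unique(lab)) < 2L)
    stop_recan("both outcome groups must be present")
  stable <- lab == "stable"
  num_cols <- names(features)[vapply(features, is.numeric, TRUE)]
  num_cols <- setdiff(num_cols, label_col)

  rows <- lapply(num_cols, function(nm) {
    x <- features[[nm]][stable]
    y <- features[[nm]][!stable]
    r <- tryCatch(two_sample_test(x, y), error = function(e) NULL)
    if (is.null(r)) {
      # constant feature, or a group too small for the gated test
      return(data.frame(feature = nm, mean_x = mean(x), sd_x = stats::sd(x),
                        mean_y = mean(y), sd_y = stats::sd(y),
                        levene_p = NA_real_, test_used = NA_character_,
                        p_value = NA_real_, significant = FALSE,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    cbind(feature = nm, r, degenerate = FALSE)
  })
  out <- do.call(rbind, rows)

  for (nm in categorical) {
    v <- features[[nm]]
    if (nm == "location" && !is.null(collapse_location)) {
      v <- ifelse(v %in% names(collapse_location),
                  collapse_location[as.character(v)], v)
    }
    tab <- table(v, lab)
    p <- tryCatch(chi_square_test(tab), error = function(e) NA_real_)
    out <- rbind(out, data.frame(
      feature = nm, mean_x = NA_real_, sd_x = NA_real_,
      mean_y = NA_real_, sd_y = NA_real_, levene_p = NA_real_,
      test_used = "chi_square", p_value = p,
      significant = isTRUE(p < 0.05), degenerate = is.na(p),
      stringsAsFactors = FALSE))
  }
  names(out)[names(out) == "mean_x"] <- "mean_stable"
  names(out)[names(out) == "sd_x"] <- "sd_stable"
  names(out)[names(out) == "mean_y"] <- "mean_recanalized"
  names(out)[names(out) == "sd_y"] <- "sd_recanalized"
  out[order(out$p_value), , drop = FALSE]
}
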
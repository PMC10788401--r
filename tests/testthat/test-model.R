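lab_ry <- function(y) ifelse(y, "recanalized", "stable")

test_that("standardization centers, scales, and round-trips", {
  x <- data.frame(a = c(1, 2, 3), b = c(10, 20, 60))
  z <- standardize_features(x)
  expect_equal(z$a, c(-1, 0, 1))
  expect_equal(vapply(z, mean, 0), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(vapply(z, sd, 0), c(a = 1, b = 1), tolerance = 1e-12)
  # idempotence up to tolerance
  z2 <- standardize_features(z)
  expect_equal(as.matrix(z2), as.matrix(z), tolerance = 1e-12,
               ignore_attr = TRUE)
  # inverse transform recovers the original table
  back <- unstandardize_features(z)
  expect_equal(as.matrix(back), as.matrix(x), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(standardize_features(data.frame(a = 1:3, c = rep(2, 3))),
               "c")
})

test_that("univariate screen retains signal, passes duplicates identically", {
  set.seed(60)
  n <- 120
  y <- rep(c(FALSE, TRUE), each = n / 2)
  x <- data.frame(signal = rnorm(n) + 2 * y, noise = rnorm(n))
  x$dup <- x$signal
  scr <- univariate_lr_screen(x, lab_ry(y))
  expect_true(scr$retained[scr$feature == "signal"])
  expect_equal(scr$p_value[scr$feature == "signal"],
               scr$p_value[scr$feature == "dup"], tolerance = 1e-12)
})

test_that("perfectly separating features are flagged and excluded", {
  y <- rep(c(FALSE, TRUE), each = 10)
  x <- data.frame(sep = c(rnorm(10, -5), rnorm(10, 5)), ok = rnorm(20))
  expect_warning(scr <- univariate_lr_screen(x, lab_ry(y)), "separation")
  expect_true(scr$separated[scr$feature == "sep"])
  expect_false(scr$retained[scr$feature == "sep"])
})

test_that("VIF filter matches the least-squares oracle and removes duplicates", {
  set.seed(61)
  # orthogonal features: all VIF ~ 1, none removed
  x <- as.data.frame(qr.Q(qr(matrix(rnorm(200 * 3), 200))))
  names(x) <- c("a", "b", "c")
  vf <- vif_filter(x)
  expect_equal(sort(vf$selected), c("a", "b", "c"))
  expect_true(all(abs(vf$report$vif - 1) < 0.05))

  # general instance: VIFs equal 1/(1 - R^2) by explicit regression
  z <- data.frame(u = rnorm(50))
  z$v <- z$u + rnorm(50, sd = 0.5)
  z$w <- rnorm(50)
  ours <- vif_filter(z, threshold = Inf)
  expect_equal(unname(ours$report$vif[match(names(z), ours$report$feature)]),
               unname(oracle_vif(z)), tolerance = 1e-8)

  # exact duplicate: one copy removed at iteration 1
  z$dup <- z$u
  vf2 <- vif_filter(z)
  first <- vf2$report[vf2$report$iteration %in% 1L, ]
  expect_true(first$feature %in% c("u", "dup"))
  expect_false(all(c("u", "dup") %in% vf2$selected))
  expect_true(all(vf2$report$vif[!vf2$report$excluded] <= 10))
})

test_that("SMOTE balances classes with convex synthetic points", {
  set.seed(62)
  x <- data.frame(f1 = rnorm(66), f2 = rnorm(66))
  y <- rep(c("stable", "recanalized"), c(57, 9))
  out <- smote_oversample(x, y, k_neighbors = 5, seed = 4)
  expect_equal(sum(out$labels == "recanalized"), 57L)
  expect_equal(sum(out$labels == "stable"), 57L)
  # originals preserved as a prefix
  expect_equal(out$x[1:66, ], x, ignore_attr = TRUE)
  expect_equal(sum(out$synthetic), 48L)
  # convexity: synthetic points lie within the minority bounding box
  minority <- x[y == "recanalized", ]
  syn <- out$x[out$synthetic, ]
  for (cn in names(x)) {
    expect_true(all(syn[[cn]] >= min(minority[[cn]]) - 1e-12))
    expect_true(all(syn[[cn]] <= max(minority[[cn]]) + 1e-12))
  }
  # determinism and balanced-input passthrough
  out2 <- smote_oversample(x, y, k_neighbors = 5, seed = 4)
  expect_identical(out$x, out2$x)
  bal <- smote_oversample(x[1:18, ], rep(c("stable", "recanalized"), 9),
                          seed = 1)
  expect_identical(bal$x, x[1:18, ])
  # k reduced with warning when the minority class is small
  expect_warning(
    smote_oversample(x[1:12, ], rep(c("stable", "recanalized"), c(9, 3)),
                     k_neighbors = 5, seed = 1),
    "using k = 2")
})

test_that("backward stepwise keeps a strong single feature, drops pure noise", {
  set.seed(63)
  n <- 200
  strong <- rnorm(n)
  y <- runif(n) < plogis(1.5 * strong)
  x <- data.frame(strong = strong, n1 = rnorm(n), n2 = rnorm(n))
  sel <- stepwise_lr(x, lab_ry(y))
  expect_true("strong" %in% sel$selected)
  p <- summary(sel$fit)$coefficients[-1, "Pr(>|z|)"]
  expect_true(all(p < 0.05))
  # pure noise: empty model is a valid, reported outcome
  xn <- data.frame(n1 = rnorm(60), n2 = rnorm(60))
  yn <- rep(c(FALSE, TRUE), 30)
  seln <- stepwise_lr(xn, lab_ry(yn))
  expect_true(length(seln$selected) <= 2)
})

test_that("Hosmer-Lemeshow matches the manual binning oracle", {
  set.seed(64)
  n <- 400
  p <- runif(n, 0.05, 0.95)
  y <- runif(n) < p
  hl <- hosmer_lemeshow(p, lab_ry(y), n_bins = 10)
  br <- unique(quantile(p, seq(0, 1, length.out = 11), type = 7))
  expect_equal(hl$statistic, oracle_hl(p, y, br), tolerance = 1e-10)
  expect_equal(hl$df, length(unique(cut(p, br, include.lowest = TRUE))) - 2)
  expect_equal(hl$p_value,
               pchisq(hl$statistic, hl$df, lower.tail = FALSE))
  # calibrated probabilities give an unremarkable statistic
  expect_gt(hl$p_value, 1e-4)
  expect_error(hosmer_lemeshow(p, lab_ry(y), n_bins = 2), "n_bins")
  expect_error(hosmer_lemeshow(rep(0.3, 50), lab_ry(rbinom(50, 1, 0.3) == 1)),
               "concentrated")
})

test_that("the fitted model satisfies its structural invariants", {
  co <- small_cohort(n_stable = 24, n_recan = 8, seed = 31, n_spatial = 10)
  tab <- extract_feature_table(co)
  fit <- recan_lr(tab, n_boot = 150, seed = 5)
  # odds ratios are exp(coefficients)
  expect_equal(fit$coefficients$odds_ratio,
               exp(fit$coefficients$coefficient), tolerance = 1e-12)
  expect_true(all(fit$coefficients$or_lower <= fit$coefficients$odds_ratio))
  expect_true(all(fit$coefficients$odds_ratio <= fit$coefficients$or_upper))
  # all selected features significant at convergence
  sel_p <- fit$coefficients$p_value[fit$coefficients$term != "(Intercept)"]
  expect_true(all(sel_p < 0.05))
  # fitted probabilities strictly inside (0, 1)
  expect_true(all(fit$probs > 0 & fit$probs < 1))
  # SMOTE balance with originals preserved
  expect_equal(sum(fit$smote$labels == "recanalized"),
               sum(fit$smote$labels == "stable"))
  # coef/predict methods are consistent with the glm
  expect_equal(unname(coef(fit)[1]), unname(coef(fit$fit)[1]))
  pr <- predict(fit, tab)
  expect_length(pr, nrow(tab))
  expect_true(all(pr > 0 & pr < 1))
  cls <- predict(fit, tab, type = "class")
  expect_true(all(cls %in% c("recanalized", "stable")))
  # determinism: same seed, same fit
  fit2 <- recan_lr(tab, n_boot = 150, seed = 5)
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_identical(fit$performance, fit2$performance)
})

test_that("prediction scores reproduce the training probabilities", {
  # scoring the (unstandardized) training rows through predict() must
  # match the glm's fitted values for the original patients
  co <- small_cohort(n_stable = 20, n_recan = 7, seed = 77, n_spatial = 8)
  tab <- extract_feature_table(co)
  fit <- recan_lr(tab, n_boot = 0, seed = 2)
  skip_if(length(fit$selected) == 0)
  pr <- predict(fit, tab)
  expect_equal(pr, unname(fit$probs[!fit$smote$synthetic]),
               tolerance = 1e-10)
})

test_that("degenerate modelling inputs fail with clear messages", {
  df <- data.frame(label = rep(c("stable", "recanalized"), c(10, 1)),
                   f = rnorm(11))
  expect_error(recan_lr(df), "2 patients per class")
  df2 <- data.frame(label = rep(c("stable", "recanalized"), c(8, 4)),
                    f = rnorm(12), flat = 1)
  expect_warning(recan_lr(df2, n_boot = 0), "zero-variance")
})
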
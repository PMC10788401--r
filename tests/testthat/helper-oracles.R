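# Independent brute-force oracles and small fixtures used across tests.
# Oracles deliberately use naive enumeration, never the package's own
# code paths.

# Pairwise concordance AUROC: loop over every (positive, negative) pair.
oracle_auroc <- function(scores, y) {
  pos <- scores[y]; neg <- scores[!y]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Step-curve AUPRC: naive precision/recall sweep over all thresholds.
oracle_auprc <- function(scores, y) {
  thr <- sort(unique(scores), decreasing = TRUE)
  area <- 0; r_prev <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & y); fp <- sum(pred & !y)
    rec <- tp / sum(y); prec <- tp / (tp + fp)
    area <- area + (rec - r_prev) * prec
    r_prev <- rec
  }
  area
}

# Exhaustive Youden search, ties toward higher specificity (larger
# threshold).
oracle_cutoff <- function(scores, y) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  best <- list(j = -Inf)
  for (t in thr) {
    pred <- scores >= t
    sens <- sum(pred & y) / sum(y)
    spec <- sum(!pred & !y) / sum(!y)
    j <- sens + spec - 1
    if (j > best$j) best <- list(cutoff = t, sens = sens, spec = spec, j = j)
  }
  best
}

# VIF by explicit normal-equation least squares, no lm().
oracle_vif <- function(x) {
  x <- as.matrix(x)
  vapply(seq_len(ncol(x)), function(j) {
    yj <- x[, j]
    Z <- cbind(1, x[, -j, drop = FALSE])
    beta <- solve(crossprod(Z), crossprod(Z, yj))
    res <- yj - Z %*% beta
    r2 <- 1 - sum(res^2) / sum((yj - mean(yj))^2)
    1 / (1 - r2)
  }, 0)
}

# Hosmer-Lemeshow statistic by manual binning over given break points.
oracle_hl <- function(p, y, breaks) {
  g <- cut(p, breaks = breaks, include.lowest = TRUE)
  stat <- 0
  for (lev in levels(g)) {
    i <- g == lev
    if (!any(i)) next
    o <- sum(y[i]); e <- sum(p[i]); n <- sum(i)
    stat <- stat + (o - e)^2 / (e * (1 - e / n))
  }
  stat
}

# One-way ANOVA on absolute deviations from group means (classic
# Levene), computed from first principles.
oracle_levene <- function(x, y) {
  d1 <- abs(x - mean(x)); d2 <- abs(y - mean(y))
  d <- c(d1, d2); n1 <- length(x); n2 <- length(y); n <- n1 + n2
  ssb <- n1 * (mean(d1) - mean(d))^2 + n2 * (mean(d2) - mean(d))^2
  ssw <- sum((d1 - mean(d1))^2) + sum((d2 - mean(d2))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  stats::pf(f, 1, n - 2, lower.tail = FALSE)
}

# Small-cohort fixture: coarse grids keep the tests fast; the
# statistical structure (waveform, group effects) is unchanged.
small_waveform <- function(dt = 0.05) waveform_spec(sampling_interval = dt)

small_cohort <- function(n_stable = 12, n_recan = 6, seed = 42,
                         n_spatial = 12, dt = 0.05) {
  generate_cohort(n_stable, n_recan, waveform = small_waveform(dt),
                  n_spatial_samples = n_spatial, seed = seed)
}

random_instance <- function(n = 12, p_pos = 0.4, ties = TRUE) {
  y <- stats::runif(n) < p_pos
  if (!any(y)) y[1] <- TRUE
  if (all(y)) y[1] <- FALSE
  s <- if (ties) sample(seq_len(max(2, n %/% 2)), n, replace = TRUE) / 2
  else stats::rnorm(n)
  list(scores = s, y = y)
}
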
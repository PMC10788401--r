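test_that("default waveform covers two 0.9 s cycles on a uniform grid", {
  wf <- generate_waveform(waveform_spec())
  expect_equal(max(wf$times), 1.8)
  expect_equal(length(wf$times), 181L)
  expect_equal(diff(wf$times), rep(0.01, 180), tolerance = 1e-12)
  expect_true(all(wf$flow > 0))
})

test_that("waveform is periodic with the cycle duration", {
  spec <- waveform_spec(cycle_duration = 0.9, n_cycles = 2,
                        sampling_interval = 0.01)
  wf <- generate_waveform(spec)
  first <- wf$flow[wf$times < 0.9 - 1e-9]
  second <- wf$flow[wf$times >= 0.9 - 1e-9 & wf$times < 1.8 - 1e-9]
  expect_equal(first, second, tolerance = 1e-10)
})

test_that("waveform without harmonics is constant at the baseline", {
  spec <- waveform_spec(harmonics = matrix(numeric(0), ncol = 2),
                        baseline = 1.3)
  wf <- generate_waveform(spec)
  expect_equal(wf$flow, rep(1.3, length(wf$times)))
})

test_that("invalid waveform specifications are rejected", {
  expect_error(waveform_spec(cycle_duration = -1), "cycle_duration")
  expect_error(waveform_spec(sampling_interval = 0), "sampling_interval")
  expect_error(waveform_spec(harmonics = cbind(2, 0)), "baseline")
})

test_that("patient generation is deterministic given the seed", {
  e <- default_effects()
  wf <- small_waveform()
  p1 <- generate_patient("recanalized", e, wf, n_spatial_samples = 8,
                         seed = 11)
  p2 <- generate_patient("recanalized", e, wf, n_spatial_samples = 8,
                         seed = 11)
  expect_identical(p1$fields$volvel_dome$values, p2$fields$volvel_dome$values)
  expect_identical(p1$morphometry, p2$morphometry)
  expect_identical(p1$clinical, p2$clinical)
})

test_that("zero-SD pressure-difference target is reproduced by extraction", {
  e <- default_effects(temporal_cv = 0)
  e$sd_stable[e$parameter == "PD"] <- 0
  e$mean_stable[e$parameter == "PD"] <- 0.361
  for (seed in c(3, 14)) {
    p <- generate_patient("stable", e, small_waveform(),
                          n_spatial_samples = 10, seed = seed)
    pd <- compute_pd(compute_pp(p$fields$p_vm_neck, p$inlet), p$inlet)
    expect_equal(mean(pd$values), 0.361, tolerance = 0.02)
  }
})

test_that("generated spatiotemporal means calibrate to the effect targets", {
  # Law-of-large-numbers check on the generator: the empirical mean of
  # the spatiotemporally averaged volvel over many stable patients must
  # lie within 3 Monte-Carlo SEs of the target (0.441, Gaussian with SD
  # 0.159; truncation at 0 is negligible at 2.8 sigma).
  n <- 600
  wf <- waveform_spec(sampling_interval = 0.1)
  e <- default_effects()
  means <- vapply(seq_len(n), function(i) {
    p <- generate_patient("stable", e, wf, n_spatial_samples = 4,
                          seed = 1e6 + i)
    f <- normalize_field(p$fields$volvel_dome, p$inlet)
    mean(f$values)
  }, 0)
  se <- 0.159 / sqrt(n)
  expect_lt(abs(mean(means) - 0.441), 3 * se + 0.002)
})

test_that("generated fields satisfy the field-type invariants", {
  p <- generate_patient("recanalized", seed = 5,
                        waveform = small_waveform(),
                        n_spatial_samples = 6)
  for (f in p$fields) {
    expect_s3_class(f, "field_ts")
    expect_true(all(is.finite(f$values)))
    expect_equal(ncol(f$values), length(f$times))
  }
  expect_true(all(p$q_inlet > 0))
})

test_that("cohort has the requested sizes, labels and reproducibility", {
  co <- small_cohort(n_stable = 5, n_recan = 3, seed = 9)
  labs <- vapply(co$patients, `[[`, "", "label")
  expect_equal(sum(labs == "stable"), 5L)
  expect_equal(sum(labs == "recanalized"), 3L)

  co2 <- small_cohort(n_stable = 5, n_recan = 3, seed = 9)
  expect_identical(co$patients[[4]]$fields$p_vm_neck$values,
                   co2$patients[[4]]$fields$p_vm_neck$values)

  # any patient is reproducible in isolation from its recorded seed
  p <- co$patients[[2]]
  solo <- generate_patient(p$label, co$effects, co$waveform,
                           n_spatial_samples = 12, seed = p$seed)
  expect_identical(solo$fields$volvel_dome$values,
                   p$fields$volvel_dome$values)

  expect_error(generate_cohort(0, 1), "at least 2")
  co3 <- small_cohort(n_stable = 4, n_recan = 0)
  expect_true(all(vapply(co3$patients, `[[`, "", "label") == "stable"))
})

test_that("missing effect parameters raise a configuration error", {
  e <- default_effects()
  e2 <- effect_spec(as.data.frame(e)[e$parameter != "FR", ])
  expect_error(generate_patient("stable", e2, small_waveform(), 4, seed = 1),
               "missing parameter 'FR'")
  expect_error(effect_spec(data.frame(parameter = "bogus", mean_stable = 1,
                                      sd_stable = 1, mean_recanalized = 1,
                                      sd_recanalized = 1)),
               "unknown parameter")
})

test_that("cohort serialization round-trips", {
  co <- small_cohort(n_stable = 2, n_recan = 2, n_spatial = 5, dt = 0.1)
  dir <- file.path(tempdir(), "cohort_rt")
  on.exit(unlink(dir, recursive = TRUE))
  write_cohort(co, dir)
  co2 <- read_cohort(dir)
  expect_equal(length(co2$patients), 4L)
  for (i in seq_along(co$patients)) {
    a <- co$patients[[i]]; b <- co2$patients[[i]]
    expect_equal(a$label, b$label)
    expect_equal(a$fields$p_vm_neck$values, b$fields$p_vm_neck$values,
                 tolerance = 1e-12)
    expect_equal(a$q_neck, b$q_neck, tolerance = 1e-12)
    expect_equal(unlist(a$morphometry), unlist(b$morphometry),
                 tolerance = 1e-12)
  }
  # identical features from the reloaded cohort
  expect_equal(extract_features(co$patients[[1]]),
               extract_features(co2$patients[[1]]), tolerance = 1e-10)
})
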
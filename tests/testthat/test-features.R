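mk_field <- function(values, times = seq_len(ncol(as.matrix(values))) / 10,
                     parameter = "volvel", region = "dome", weights = NULL) {
  field_ts(as.matrix(values), times, parameter, region, weights)
}

test_that("field container enforces its invariants", {
  expect_error(mk_field(matrix(1, 1, 1), times = 0.1), "timepoints")
  expect_error(field_ts(matrix(c(1, NA), 1), c(0.1, 0.2), "P", "dome"),
               "finite")
  expect_error(field_ts(matrix(1:4, 2), c(0.2, 0.1), "P", "dome"),
               "increasing")
  expect_error(field_ts(matrix(1:4, 2), c(0.1, 0.2), "P", "dome",
                        weights = c(1, -1)), "weights")
})

test_that("normalization divides by the right inlet scalar", {
  ref <- inlet_reference(0.25, 100, 2, c(1e-6, 1e-6))
  # identity: a field equal to its normalizer becomes all ones
  f <- mk_field(matrix(0.25, 2, 3), parameter = "volvel")
  expect_equal(normalize_field(f, ref)$values, matrix(1, 2, 3))
  # velocity 0.05 / 0.25 = 0.2
  f <- mk_field(matrix(0.05, 1, 2), parameter = "volvel")
  expect_equal(normalize_field(f, ref)$values[1, 1], 0.2)
  # Pdyn 27.5 Pa at v_inlet 0.1, rho 1100: 27.5 / 5.5 = 5
  ref2 <- inlet_reference(0.1, 100, 2, c(1e-6, 1e-6))
  f <- mk_field(matrix(27.5, 1, 2), parameter = "Pdyn", region = "neck_plane")
  expect_equal(normalize_field(f, ref2)$values[1, 1], 5)
  # degenerate normalizer
  expect_error(inlet_reference(0, 100, 2, 1e-6), "v_inlet")
})

test_that("dynamic pressure is 0.5 rho v^2 with quadratic scaling", {
  f <- mk_field(matrix(c(0, 0.1, 0.2, 0.1), 2), parameter = "volvel",
                region = "neck_plane")
  pd <- compute_dynamic_pressure(f, sim_constants(1100))
  expect_equal(pd$values[1, 1], 0)
  expect_equal(pd$values[2, 1], 5.5)
  expect_equal(pd$values[1, 2], 4 * pd$values[2, 1])  # doubling v quadruples
  expect_error(compute_dynamic_pressure(mk_field(matrix(-1, 1, 2))),
               "non-negative")
})

test_that("PP and PD follow their defining identities", {
  ref <- inlet_reference(0.1, 100, 2, c(1e-6, 1e-6))
  f <- mk_field(matrix(c(100, 105, 100, 111), 2), parameter = "P",
                region = "vm_neck")
  pp <- compute_pp(f, ref)
  expect_equal(pp$values, matrix(c(0, 5, 0, 11), 2))
  expect_equal(pp$parameter, "PP")
  # PD = PP / (0.5 * 1100 * 0.1^2) = PP / 5.5
  pd <- compute_pd(pp, ref)
  expect_equal(pd$values[2, 2], 2)
  # halving v_inlet multiplies PD by 4
  ref2 <- inlet_reference(0.05, 100, 2, c(1e-6, 1e-6))
  expect_equal(compute_pd(pp, ref2)$values, 4 * pd$values)
  # P identical to the inlet pressure gives identically zero PD
  f0 <- mk_field(matrix(100, 3, 4), parameter = "P", region = "vm_neck")
  expect_true(all(compute_pd(compute_pp(f0, ref), ref)$values == 0))
  # region guard
  expect_error(compute_pp(mk_field(matrix(1, 1, 2), parameter = "P",
                                   region = "neck_plane"), ref), "vm_neck")
})

test_that("inflow rate ratio is the pointwise flow quotient", {
  expect_equal(compute_fr(c(1, 2), c(1, 2)), c(1, 1))
  expect_equal(compute_fr(c(0.001, 0.002), c(1, 1)), c(0.001, 0.002))
  expect_equal(compute_fr(c(0, 1), c(2, 2)), c(0, 0.5))
  expect_error(compute_fr(1:3, 1:2), "time grid")
  expect_error(compute_fr(c(1, 1), c(1, 0)), "positive")
})

test_that("spatial reduction averages (with weights) and maximizes", {
  f <- mk_field(matrix(c(1, 2, 3), 3, 2), parameter = "P",
                region = "neck_plane")
  expect_equal(spatial_reduce(f, "ave"), c(2, 2))
  expect_equal(spatial_reduce(f, "max"), c(3, 3))
  fw <- mk_field(matrix(c(1, 3), 2, 2), parameter = "P",
                 region = "neck_plane", weights = c(3, 1))
  expect_equal(spatial_reduce(fw, "ave"), c(1.5, 1.5))
  expect_equal(spatial_reduce(fw, "max"), c(3, 3))
  f1 <- mk_field(matrix(5, 1, 3), parameter = "P", region = "neck_plane")
  expect_equal(spatial_reduce(f1, "ave"), spatial_reduce(f1, "max"))
})

test_that("temporal descriptors match hand values and invariants", {
  ts <- temporal_reduce(1:5)
  expect_equal(unname(ts[c("min", "max", "a", "median", "q1", "q2")]),
               c(1, 5, 3, 3, 2, 4))
  expect_equal(unname(ts["std"]), sd(1:5), tolerance = 1e-12)
  expect_equal(round(unname(ts["std"]), 4), 1.5811)

  const <- temporal_reduce(rep(2.5, 4))
  expect_equal(unname(const[c("a", "median", "q1", "q2", "max", "min")]),
               rep(2.5, 6))
  expect_equal(unname(const["std"]), 0)

  # translation equivariance: location stats shift, std unchanged
  set.seed(1)
  x <- rnorm(30)
  a <- temporal_reduce(x); b <- temporal_reduce(x + 3)
  expect_equal(b[c("a", "median", "q1", "q2", "max", "min")],
               a[c("a", "median", "q1", "q2", "max", "min")] + 3)
  expect_equal(b["std"], a["std"])

  # windowing
  expect_error(temporal_reduce(1:5, times = 1:5, window = c(10, 11)),
               "fewer than 2")
  expect_equal(unname(temporal_reduce(1:5, times = 1:5,
                                      window = c(2, 4))["a"]), 3)
})

test_that("temporal summaries are internally ordered", {
  set.seed(7)
  for (i in 1:25) {
    ts <- temporal_reduce(rnorm(sample(3:40, 1)))
    expect_true(ts["min"] <= ts["q1"] && ts["q1"] <= ts["median"] &&
                ts["median"] <= ts["q2"] && ts["q2"] <= ts["max"])
    expect_true(ts["min"] <= ts["a"] && ts["a"] <= ts["max"])
    expect_gte(ts["std"], 0)
  }
})

test_that("a complete patient yields exactly the expected feature counts", {
  p <- generate_patient("stable", seed = 2, waveform = small_waveform(),
                        n_spatial_samples = 8)
  fv <- extract_features(p)
  hemo <- intersect(names(fv), hemodynamic_feature_names())
  expect_length(hemo, 91L)
  expect_length(grep("^PD_(ave|max)_", names(fv)), 14L)
  expect_length(grep("^volvel_(ave|max)_", names(fv)), 14L)
  expect_length(grep("^FR_", names(fv)), 7L)
  expect_true(all(c("AspectRatio", "BottleneckFactor", "SizeRatio",
                    "AreaRatio", "VER") %in% names(fv)))
  expect_true(all(is.finite(fv)))
})

test_that("partial records fail loudly, naming the missing pieces", {
  p <- generate_patient("stable", seed = 2, waveform = small_waveform(),
                        n_spatial_samples = 4)
  p$fields$wss_neck <- NULL
  expect_error(extract_features(p), "wss_neck")
  p2 <- generate_patient("stable", seed = 2, waveform = small_waveform(),
                         n_spatial_samples = 4)
  p2$q_neck <- NULL
  expect_error(extract_features(p2), "q_neck")
})

test_that("spatial-maximum features dominate spatial-average features", {
  p <- generate_patient("recanalized", seed = 6, waveform = small_waveform(),
                        n_spatial_samples = 15)
  fv <- extract_features(p)
  for (param in c("volvel", "WSS", "P", "Pdyn", "PP", "PD")) {
    for (d in c("a", "median", "q1", "q2", "max", "min")) {
      expect_gte(fv[paste(param, "max", d, sep = "_")],
                 fv[paste(param, "ave", d, sep = "_")])
    }
  }
})

test_that("features scale linearly in the field magnitude", {
  set.seed(3)
  f <- mk_field(matrix(abs(rnorm(40)) + 0.1, 5, 8), parameter = "PD",
                region = "vm_neck",
                times = seq(0.1, 0.8, by = 0.1))
  k <- 3.7
  fk <- mk_field(k * f$values, parameter = "PD", region = "vm_neck",
                 times = f$times)
  for (sp in c("ave", "max")) {
    a <- temporal_reduce(spatial_reduce(f, sp))
    b <- temporal_reduce(spatial_reduce(fk, sp))
    expect_equal(b, k * a, tolerance = 1e-12)
  }
})

test_that("morphological ratios match their definitions", {
  m <- list(max_size = 5, neck_width = 4, height = 6,
            perpendicular_height = 8, dome_width = 5,
            parent_vessel_diameter = 3, area_neck = 34.3,
            area_inlet = 17.15, area_pcom = 2, aneurysm_volume = 100,
            coil_volume = 25)
  r <- morphological_ratios(m)
  expect_equal(unname(r["AspectRatio"]), 2)
  expect_equal(unname(r["BottleneckFactor"]), 1.25)
  expect_equal(unname(r["SizeRatio"]), 2)
  expect_equal(unname(r["AreaRatio"]), 2)
  expect_equal(unname(r["VER"]), 4)
  same <- as.list(setNames(rep(2, 11), names(m)))
  expect_true(all(morphological_ratios(same) == 1))
  m$neck_width <- 0
  expect_error(morphological_ratios(m), "degenerate")
})

test_that("the analysis window changes the summarized span", {
  p <- generate_patient("stable", seed = 4, waveform = small_waveform(),
                        n_spatial_samples = 4)
  full <- extract_features(p, window = "full")
  second <- extract_features(p, window = "second-cycle")
  expect_length(intersect(names(full), hemodynamic_feature_names()), 91L)
  # explicit numeric window equal to the second cycle matches the preset
  num <- extract_features(p, window = c(0.9, 1.8))
  expect_equal(second, num)
})
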
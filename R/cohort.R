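#' Pulsatile waveform specification
#'
#' Describes the periodic inflow pulse that modulates every generated
#' field: a truncated Fourier series around a positive baseline, sampled
#' on a uniform grid covering two cardiac cycles by default.
#'
#' @param cycle_duration cardiac cycle length in seconds (default 0.9).
#' @param n_cycles number of cycles simulated (default 2, i.e. 1.8 s).
#' @param sampling_interval uniform sampling interval in seconds
#'   (default 0.01, giving 181 points over 1.8 s).
#' @param harmonics numeric matrix or two-column data frame of
#'   (amplitude, phase) pairs for harmonics 1, 2, ... of the cycle; the
#'   default three harmonics give a systolic-peaked pulse. An empty
#'   matrix yields a constant waveform.
#' @param baseline dimensionless mean level (default 1). Must exceed the
#'   summed harmonic amplitudes so the waveform stays strictly positive.
#' @return list of class `waveform_spec`.
#' @export
waveform_spec <- function(cycle_duration = 0.9, n_cycles = 2,
                          sampling_interval = 0.01,
                          harmonics = default_harmonics(),
                          baseline = 1) {
  check_number(cycle_duration, "cycle_duration", positive = TRUE)
  check_number(sampling_interval, "sampling_interval", positive = TRUE)
  check_number(baseline, "baseline", positive = TRUE)
  if (n_cycles < 1) stop_recan("n_cycles must be >= 1")
  harmonics <- as.matrix(harmonics)
  if (length(harmonics) && ncol(harmonics) != 2L)
    stop_recan("harmonics must have two columns: amplitude, phase")
  if (length(harmonics) && sum(abs(harmonics[, 1])) >= baseline)
    stop_recan("summed harmonic amplitudes must stay below the baseline")
  structure(list(cycle_duration = cycle_duration, n_cycles = n_cycles,
                 sampling_interval = sampling_interval,
                 harmonics = harmonics, baseline = baseline),
            class = "waveform_spec")
}

default_harmonics <- function() {
  cbind(amplitude = c(0.22, 0.10, 0.05), phase = c(0.0, 1.1, 2.3))
}

waveform_times <- function(spec) {
  total <- spec$n_cycles * spec$cycle_duration
  seq(0, total, by = spec$sampling_interval)
}

#' Generate the pulsatile flow waveform
#'
#' Evaluates the waveform specification on its uniform closed grid
#' `[0, n_cycles * cycle_duration]`. The series is strictly positive and
#' periodic with period `cycle_duration`; with no harmonics it is
#' constant at the baseline.
#'
#' @param spec a [waveform_spec()].
#' @param seed unused (the waveform is deterministic); accepted for
#'   interface symmetry with the other generators.
#' @return list with `times` (s) and `flow` (dimensionless amplitude).
#' @export
generate_waveform <- function(spec = waveform_spec(), seed = NULL) {
  stopifnot(inherits(spec, "waveform_spec"))
  t <- waveform_times(spec)
  flow <- rep(spec$baseline, length(t))
  h <- spec$harmonics
  if (length(h)) {
    for (k in seq_len(nrow(h))) {
      flow <- flow + h[k, 1] * cos(2 * pi * k * t / spec$cycle_duration - h[k, 2])
    }
  }
  list(times = t, flow = flow)
}

cohort_parameters <- c("volvel", "P", "Pdyn", "WSS", "PP", "PD", "FR")

#' Group-conditional effect specification
#'
#' Targets for the spatiotemporally averaged value of each generated
#' hemodynamic parameter, per outcome group, plus the heterogeneity
#' scales of the generator. A patient's spatiotemporal mean for a
#' parameter is an independent draw from the group's (mean, SD),
#' truncated at zero for non-negative parameters (volvel, WSS, Pdyn, FR).
#' PP is tied to PD through the inlet dynamic pressure (PP in Pa equals
#' PD times `0.5 * rho * v_inlet^2`), so its row documents the implied
#' pascal scale rather than being drawn independently.
#'
#' @param params data frame with columns `parameter`, `mean_stable`,
#'   `sd_stable`, `mean_recanalized`, `sd_recanalized`, one row per
#'   parameter in `c("volvel","P","Pdyn","WSS","PP","PD","FR")`.
#' @param spatial_cv dimensionless spatial heterogeneity scale
#'   (coefficient of variation across spatial samples; default 0.15).
#' @param temporal_cv dimensionless temporal noise scale (default 0.05).
#' @return data frame of class `effect_spec`.
#' @export
effect_spec <- function(params, spatial_cv = 0.15, temporal_cv = 0.05) {
  need <- c("parameter", "mean_stable", "sd_stable",
            "mean_recanalized", "sd_recanalized")
  if (!all(need %in% names(params)))
    stop_recan("params must have columns: %s", paste(need, collapse = ", "))
  bad <- setdiff(params$parameter, cohort_parameters)
  if (length(bad))
    stop_recan("unknown parameter(s): %s", paste(bad, collapse = ", "))
  sds <- c(params$sd_stable, params$sd_recanalized)
  if (any(sds < 0)) stop_recan("standard deviations must be >= 0")
  if (spatial_cv < 0 || temporal_cv < 0)
    stop_recan("heterogeneity scales must be >= 0")
  structure(as.data.frame(params), spatial_cv = spatial_cv,
            temporal_cv = temporal_cv, class = c("effect_spec", "data.frame"))
}

#' Default generative targets
#'
#' Group means and SDs for the spatiotemporally averaged parameters. For
#' volvel and PD these are the time-averaged spatial-average summaries of
#' the recanalized-vs-stable comparison (recanalized aneurysms: higher PD
#' and FR, lower volvel); P, Pdyn and WSS carry no group effect. The PP
#' row is the PD row expressed in Pa at the default inlet reference
#' (0.25 m/s, rho 1100 -> 34.4 Pa inlet dynamic pressure).
#'
#' @param spatial_cv,temporal_cv passed to [effect_spec()].
#' @return an [effect_spec()].
#' @export
default_effects <- function(spatial_cv = 0.15, temporal_cv = 0.05) {
  q <- 0.5 * 1100 * 0.25^2
  params <- data.frame(
    parameter        = c("volvel", "P", "Pdyn", "WSS", "PD", "PP", "FR"),
    mean_stable      = c(0.441, 1.00, 0.50, 1.10, 0.361, 0.361 * q, 0.0009),
    sd_stable        = c(0.159, 0.08, 0.25, 0.50, 0.623, 0.623 * q, 0.0008),
    mean_recanalized = c(0.299, 1.00, 0.50, 1.10, 0.903, 0.903 * q, 0.0022),
    sd_recanalized   = c(0.161, 0.08, 0.25, 0.50, 0.765, 0.765 * q, 0.0030))
  effect_spec(params, spatial_cv = spatial_cv, temporal_cv = temporal_cv)
}

effect_row <- function(effects, parameter, group) {
  i <- match(parameter, effects$parameter)
  if (is.na(i))
    stop_recan("effect specification is missing parameter '%s'", parameter)
  if (group == "stable")
    c(mean = effects$mean_stable[i], sd = effects$sd_stable[i])
  else
    c(mean = effects$mean_recanalized[i], sd = effects$sd_recanalized[i])
}

# Draw one dimensionless field around patient-level mean m: waveform
# modulation (unit mean on the grid) x fixed spatial profile (unit
# weighted mean) x multiplicative temporal noise (unit mean).
make_field_values <- function(m, mod, n_spatial, spatial_cv, temporal_cv,
                              nonneg) {
  h <- 1 + spatial_cv * stats::rnorm(n_spatial)
  h <- pmax(h, 0.05)
  h <- h / mean(h)
  eps <- 1 + temporal_cv * stats::rnorm(n_spatial * length(mod))
  v <- m * outer(h, mod) * matrix(eps, nrow = n_spatial)
  if (nonneg) v <- pmax(v, 0)
  v
}

generate_morphometry <- function(group) {
  rec <- group == "recanalized"
  max_size  <- rtruncnorm1(1, if (rec) 11.344 else 7.987,
                           if (rec) 4.330 else 3.135, lower = 1.5)
  height    <- rtruncnorm1(1, if (rec) 8.444 else 5.967,
                           if (rec) 3.855 else 2.630, lower = 1.0)
  area_neck <- rtruncnorm1(1, if (rec) 34.336 else 21.813,
                           if (rec) 19.490 else 13.745, lower = 2.0)
  neck_width <- 2 * sqrt(area_neck / pi) * exp(stats::rnorm(1, 0, 0.08))
  perpendicular_height <- height * exp(stats::rnorm(1, -0.08, 0.08))
  dome_width <- max_size * exp(stats::rnorm(1, -0.15, 0.10))
  parent_vessel_diameter <- rtruncnorm1(1, 3.5, 0.7, lower = 1.5)
  area_inlet <- rtruncnorm1(1, 12, 4, lower = 3)
  area_pcom  <- rtruncnorm1(1, 3, 1.5, lower = 0.4)
  aneurysm_volume <- pi / 6 * max_size * dome_width * height
  coil_volume <- aneurysm_volume * rtruncnorm1(1, 0.25, 0.05, lower = 0.08)
  list(max_size = max_size, neck_width = neck_width, height = height,
       perpendicular_height = perpendicular_height, dome_width = dome_width,
       parent_vessel_diameter = parent_vessel_diameter,
       area_neck = area_neck, area_inlet = area_inlet, area_pcom = area_pcom,
       aneurysm_volume = aneurysm_volume, coil_volume = coil_volume)
}

generate_clinical <- function(group) {
  rec <- group == "recanalized"
  locations <- c("ICPC", "IC_paraclinoid", "IC_Oph", "C1")
  loc_prob <- if (rec) c(8, 1, 0, 0) / 9 else c(43, 10, 2, 2) / 57
  list(age = round(rtruncnorm1(1, if (rec) 64 else 65,
                               if (rec) 12 else 13, lower = 18)),
       sex = if (stats::runif(1) < (if (rec) 7 / 9 else 51 / 57))
         "female" else "male",
       rupture = stats::runif(1) < (if (rec) 4 / 9 else 12 / 57),
       location = sample(locations, 1, prob = loc_prob))
}

#' Generate one synthetic patient record
#'
#' Builds the full set of waveform-modulated spatial field samples,
#' inlet references, inflow-rate series, morphometry and clinical
#' covariates for one patient, standing in for time-resolved CFD output.
#' The spatiotemporal mean of each generated parameter is an independent
#' draw from the group's (mean, SD) in `effects` (truncated at zero for
#' non-negative parameters). Deterministic given `seed`.
#'
#' Field construction: volvel (dome), WSS and static pressure P (neck
#' plane) are drawn as dimensionless fields and scaled by the patient's
#' inlet references; the neck-plane velocity implied by the dimensionless
#' Pdyn target is stored so that `0.5 * rho * v^2` recovers Pdyn; the
#' virtual-model neck pressure is `p_inlet + PD * (0.5 * rho *
#' v_inlet^2)` so that the extracted PD matches its target; FR is a
#' small positive time series (lognormal temporal noise around the group
#' mean) with the neck inflow stored as `FR * q_inlet`.
#'
#' @param group_label `"stable"` or `"recanalized"`.
#' @param effects an [effect_spec()].
#' @param waveform a [waveform_spec()].
#' @param n_spatial_samples spatial samples per region (default 200).
#' @param seed integer seed.
#' @param constants a [sim_constants()].
#' @param id patient identifier.
#' @return list of class `recan_patient` with elements `id`, `label`,
#'   `fields` (named list of [field_ts()]), `q_inlet`, `q_neck`,
#'   `times`, `inlet`, `morphometry`, `clinical`, `cycle_duration`,
#'   `n_cycles`, `seed`.
#' @export
generate_patient <- function(group_label = c("stable", "recanalized"),
                             effects = default_effects(),
                             waveform = waveform_spec(),
                             n_spatial_samples = 200,
                             seed = 1,
                             constants = sim_constants(),
                             id = paste0(substr(group_label[1], 1, 1), seed)) {
  group_label <- match.arg(group_label)
  stopifnot(inherits(effects, "effect_spec"))
  for (p in cohort_parameters) effect_row(effects, p, group_label)

  set.seed(seed)
  wf <- generate_waveform(waveform)
  t <- wf$times
  mod <- wf$flow / mean(wf$flow)
  s_cv <- attr(effects, "spatial_cv")
  t_cv <- attr(effects, "temporal_cv")
  ns <- n_spatial_samples

  # Patient inlet references; the inflow waveform is shared, the scale
  # carries mild patient-to-patient jitter.
  v_inlet <- rtruncnorm1(1, 0.25, 0.03, lower = 0.10)
  wss_inlet <- rtruncnorm1(1, 2.0, 0.3, lower = 0.5)
  p_inlet <- 100
  q0 <- rtruncnorm1(1, 4e-6, 5e-7, lower = 1e-6)
  q_inlet <- q0 * mod
  ref <- inlet_reference(v_inlet, p_inlet, wss_inlet, q_inlet)
  qdyn <- inlet_dynamic_pressure(ref, constants)

  draw <- function(parameter, lower = -Inf) {
    e <- effect_row(effects, parameter, group_label)
    rtruncnorm1(1, e["mean"], e["sd"], lower = lower)
  }

  m_volvel <- draw("volvel", lower = 0)
  m_p      <- draw("P")
  m_pdyn   <- draw("Pdyn", lower = 0)
  m_wss    <- draw("WSS", lower = 0)
  m_pd     <- draw("PD")
  m_fr     <- draw("FR", lower = 1e-6)

  fields <- list(
    volvel_dome = field_ts(
      v_inlet * make_field_values(m_volvel, mod, ns, s_cv, t_cv, TRUE),
      t, "volvel", "dome"),
    wss_neck = field_ts(
      wss_inlet * make_field_values(m_wss, mod, ns, s_cv, t_cv, TRUE),
      t, "WSS", "neck_plane"),
    p_neck = field_ts(
      p_inlet * make_field_values(m_p, mod, ns, s_cv, t_cv, FALSE),
      t, "P", "neck_plane"),
    vel_neck = field_ts(
      v_inlet * sqrt(make_field_values(m_pdyn, mod, ns, s_cv, t_cv, TRUE)),
      t, "volvel", "neck_plane"),
    p_vm_neck = field_ts(
      p_inlet + qdyn * make_field_values(m_pd, mod, ns, s_cv, t_cv, FALSE),
      t, "P", "vm_neck"))

  # FR: small positive series, lognormal temporal noise with unit mean.
  fr <- m_fr * mod * exp(t_cv * stats::rnorm(length(t)) - t_cv^2 / 2)
  q_neck <- fr * q_inlet

  structure(
    list(id = id, label = group_label, fields = fields,
         q_inlet = q_inlet, q_neck = q_neck, times = t, inlet = ref,
         morphometry = generate_morphometry(group_label),
         clinical = generate_clinical(group_label),
         cycle_duration = waveform$cycle_duration,
         n_cycles = waveform$n_cycles, seed = seed),
    class = "recan_patient")
}

#' @export
print.recan_patient <- function(x, ...) {
  cat(sprintf("<recan_patient> %s (%s): %d fields, %d timepoints over %.2f s\n",
              x$id, x$label, length(x$fields), length(x$times),
              max(x$times)))
  invisible(x)
}

#' Generate a labeled synthetic cohort
#'
#' Default sizes reproduce the study imbalance: 57 stable and 9
#' recanalized aneurysms (66 records). Per-patient seeds are derived
#' from the master seed, so any patient can be regenerated in isolation
#' from its recorded seed.
#'
#' @param n_stable,n_recanalized group sizes (defaults 57 and 9; their
#'   sum must be at least 2).
#' @param effects an [effect_spec()].
#' @param waveform a [waveform_spec()].
#' @param n_spatial_samples spatial samples per region.
#' @param seed master integer seed.
#' @param constants a [sim_constants()].
#' @return list of class `recan_cohort` with elements `patients`,
#'   `effects`, `waveform`, `seed`.
#' @export
generate_cohort <- function(n_stable = 57, n_recanalized = 9,
                            effects = default_effects(),
                            waveform = waveform_spec(),
                            n_spatial_samples = 200,
                            seed = 1,
                            constants = sim_constants()) {
  if (n_stable < 0 || n_recanalized < 0)
    stop_recan("group sizes must be non-negative")
  n <- n_stable + n_recanalized
  if (n < 2) stop_recan("cohort must contain at least 2 patients")
  set.seed(seed)
  patient_seeds <- sample.int(.Machine$integer.max - 1L, n)
  labels <- c(rep("stable", n_stable), rep("recanalized", n_recanalized))
  ids <- sprintf("%s_%03d", ifelse(labels == "stable", "stab", "recan"),
                 seq_len(n))
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    patients[[i]] <- generate_patient(
      labels[i], effects = effects, waveform = waveform,
      n_spatial_samples = n_spatial_samples, seed = patient_seeds[i],
      constants = constants, id = ids[i])
  }
  structure(list(patients = patients, effects = effects,
                 waveform = waveform, seed = seed),
            class = "recan_cohort")
}

#' @export
print.recan_cohort <- function(x, ...) {
  labs <- vapply(x$patients, `[[`, "", "label")
  cat(sprintf("<recan_cohort> %d patients (%d stable, %d recanalized), seed %d\n",
              length(labs), sum(labs == "stable"),
              sum(labs == "recanalized"), x$seed))
  invisible(x)
}
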
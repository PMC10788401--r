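spatial_parameters <- c("volvel", "WSS", "P", "Pdyn", "PP", "PD")

#' Names of the 91 spatiotemporal hemodynamic features
#'
#' The six spatially resolved parameters (volvel, WSS, P, Pdyn, PP, PD)
#' each contribute 14 features: \{spatial average, spatial maximum\}
#' crossed with the seven temporal descriptors (a, median, q1, q2, max,
#' min, std). The inflow rate ratio FR, a pure time series, contributes
#' the seven temporal descriptors, for 84 + 7 = 91 features, named
#' `<parameter>_<ave|max>_<descriptor>` and `FR_<descriptor>`.
#'
#' @return character vector of length 91.
#' @export
hemodynamic_feature_names <- function() {
  spatial <- as.vector(t(outer(
    spatial_parameters,
    as.vector(outer(c("ave", "max"), temporal_descriptors, paste, sep = "_")),
    paste, sep = "_")))
  c(spatial, paste("FR", temporal_descriptors, sep = "_"))
}

morph_ratio_names <- c("AspectRatio", "BottleneckFactor", "SizeRatio",
                       "AreaRatio", "VER")

#' Morphological ratios
#'
#' Classic shape descriptors of a saccular aneurysm: aspect ratio
#' (maximum perpendicular height / neck width), bottleneck factor (dome
#' width / neck width), size ratio (height / parent vessel diameter),
#' area ratio (neck area / inlet area) and the volume embolization ratio
#' VER (aneurysm volume / coil-occupied volume).
#'
#' @param m named list or vector of morphometric measurements with
#'   entries `max_size`, `neck_width`, `height`, `perpendicular_height`,
#'   `dome_width`, `parent_vessel_diameter`, `area_neck`, `area_inlet`,
#'   `aneurysm_volume`, `coil_volume` (lengths mm, areas mm^2, volumes
#'   mm^3, all positive).
#' @return named numeric vector of the five ratios.
#' @export
morphological_ratios <- function(m) {
  m <- as.list(m)
  need <- c("neck_width", "perpendicular_height", "dome_width", "height",
            "parent_vessel_diameter", "area_neck", "area_inlet",
            "aneurysm_volume", "coil_volume")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop_recan("morphometry is missing: %s", paste(miss, collapse = ", "))
  vals <- unlist(m[need])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_recan("degenerate morphometry: all measurements must be > 0")
  c(AspectRatio = m$perpendicular_height / m$neck_width,
    BottleneckFactor = m$dome_width / m$neck_width,
    SizeRatio = m$height / m$parent_vessel_diameter,
    AreaRatio = m$area_neck / m$area_inlet,
    VER = m$aneurysm_volume / m$coil_volume)
}

resolve_window <- function(window, times, cycle_duration = NULL) {
  if (is.numeric(window)) {
    if (length(window) != 2L) stop_recan("numeric window must be c(t0, t1)")
    return(window)
  }
  window <- match.arg(window, c("second-cycle", "full"))
  if (window == "full") return(range(times))
  cd <- cycle_duration %||% (diff(range(times)) / 2)
  c(max(times) - cd, max(times))
}

#' Extract the spatiotemporal feature vector for one patient
#'
#' Runs the full derivation chain on a patient record: normalizes
#' volvel, WSS and P by their inlet references, computes dynamic
#' pressure from the neck-plane velocity and normalizes it by the inlet
#' dynamic pressure, derives PP (neck pressure change, Pa) and the
#' dimensionless pressure difference PD on the virtual post-coiling
#' neck, and the inflow rate ratio FR; reduces each spatial parameter to
#' its `ave` and `max` temporal profiles; and summarizes every profile
#' with the seven temporal descriptors over the analysis window. Raw
#' morphometry and the morphological ratios are appended.
#'
#' @param patient a `recan_patient` (from [generate_patient()] or
#'   [read_cohort()]). Required fields: `volvel_dome`, `wss_neck`,
#'   `p_neck`, `vel_neck`, `p_vm_neck`, plus `q_neck`/`q_inlet` series
#'   and morphometry; missing components raise an error naming them.
#' @param window `"second-cycle"` (default; drops the first cycle's
#'   initialization transient), `"full"`, or a numeric `c(t0, t1)`.
#' @param constants a [sim_constants()].
#' @return named numeric vector: 91 hemodynamic features, then raw
#'   morphometry, then the five morphological ratios.
#' @export
extract_features <- function(patient, window = "second-cycle",
                             constants = sim_constants()) {
  need_fields <- c("volvel_dome", "wss_neck", "p_neck", "vel_neck",
                   "p_vm_neck")
  miss <- setdiff(need_fields, names(patient$fields))
  if (is.null(patient$q_neck) || is.null(patient$q_inlet))
    miss <- c(miss, "q_neck/q_inlet")
  if (is.null(patient$morphometry)) miss <- c(miss, "morphometry")
  if (length(miss))
    stop_recan("patient record is incomplete; missing: %s",
               paste(miss, collapse = ", "))

  ref <- patient$inlet
  f <- patient$fields
  dimless <- list(
    volvel = normalize_field(f$volvel_dome, ref, constants),
    WSS    = normalize_field(f$wss_neck, ref, constants),
    P      = normalize_field(f$p_neck, ref, constants),
    Pdyn   = normalize_field(compute_dynamic_pressure(f$vel_neck, constants),
                             ref, constants),
    PP     = compute_pp(f$p_vm_neck, ref),
    PD     = compute_pd(compute_pp(f$p_vm_neck, ref), ref, constants))

  times <- patient$times
  win <- resolve_window(window, times, patient$cycle_duration)

  out <- numeric(0)
  for (param in spatial_parameters) {
    fld <- dimless[[param]]
    for (sp in c("ave", "max")) {
      series <- spatial_reduce(fld, sp)
      ts <- temporal_reduce(series, fld$times, win)
      names(ts) <- paste(param, sp, temporal_descriptors, sep = "_")
      out <- c(out, ts)
    }
  }
  fr <- compute_fr(patient$q_neck, patient$q_inlet)
  ts <- temporal_reduce(fr, times, win)
  names(ts) <- paste("FR", temporal_descriptors, sep = "_")
  out <- c(out, ts)

  morph <- unlist(patient$morphometry)
  c(out, morph, morphological_ratios(patient$morphometry))
}

#' Build the cohort feature table
#'
#' Applies [extract_features()] to every patient and assembles the
#' patients-by-features data frame used by the statistical and
#' predictive modules, with the outcome label and clinical covariates in
#' front.
#'
#' @param cohort a `recan_cohort`.
#' @param window analysis window, see [extract_features()].
#' @param constants a [sim_constants()].
#' @return data frame with columns `id`, `label`, `age`, `sex`,
#'   `rupture`, `location`, then all numeric features. Attributes
#'   `hemodynamic_cols` and `feature_cols` name the 91 hemodynamic and
#'   all numeric feature columns.
#' @export
extract_feature_table <- function(cohort, window = "second-cycle",
                                  constants = sim_constants()) {
  stopifnot(inherits(cohort, "recan_cohort"))
  rows <- lapply(cohort$patients, extract_features, window = window,
                 constants = constants)
  feat <- do.call(rbind, rows)
  clin <- data.frame(
    id = vapply(cohort$patients, `[[`, "", "id"),
    label = vapply(cohort$patients, `[[`, "", "label"),
    age = vapply(cohort$patients, function(p) as.numeric(p$clinical$age), 0),
    sex = vapply(cohort$patients, function(p) p$clinical$sex, ""),
    rupture = vapply(cohort$patients, function(p) isTRUE(p$clinical$rupture),
                     NA),
    location = vapply(cohort$patients, function(p) p$clinical$location, ""),
    stringsAsFactors = FALSE)
  out <- cbind(clin, as.data.frame(feat))
  attr(out, "hemodynamic_cols") <- hemodynamic_feature_names()
  attr(out, "feature_cols") <- colnames(feat)
  out
}
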
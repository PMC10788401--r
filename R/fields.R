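#' Time-resolved spatial field container
#'
#' A `field_ts` holds spatial samples of one hemodynamic parameter over a
#' common time grid: a matrix of `n_spatial` samples by `n_time` points,
#' optionally with per-sample area weights. It is the unit of exchange
#' between the cohort generator and feature extraction.
#'
#' @param values numeric matrix, spatial samples in rows, timepoints in
#'   columns. Physical units (m/s for velocity, Pa for pressures and wall
#'   shear stress) before normalization; dimensionless after.
#' @param times numeric vector of timepoints in seconds, strictly
#'   increasing, one per column of `values`.
#' @param parameter one of `"volvel"`, `"WSS"`, `"P"`, `"Pdyn"`, `"PP"`,
#'   `"PD"`.
#' @param region one of `"dome"`, `"neck_plane"`, `"vm_neck"` (the neck
#'   plane of the virtual post-coiling model).
#' @param weights optional positive per-sample area weights (length
#'   `nrow(values)`); used by the area-weighted spatial average.
#' @return an object of class `field_ts`.
#' @seealso [spatial_reduce()], [temporal_reduce()], [normalize_field()]
#' @export
field_ts <- function(values, times, parameter, region, weights = NULL) {
  parameter <- match.arg(parameter, c("volvel", "WSS", "P", "Pdyn", "PP", "PD"))
  region <- match.arg(region, c("dome", "neck_plane", "vm_neck"))
  if (!is.matrix(values)) values <- matrix(values, nrow = 1L)
  if (nrow(values) < 1L || ncol(values) < 2L)
    stop_recan("field needs >= 1 spatial sample and >= 2 timepoints")
  if (!all(is.finite(values)))
    stop_recan("field values must all be finite")
  if (length(times) != ncol(values))
    stop_recan("length(times) must equal ncol(values)")
  if (any(diff(times) <= 0))
    stop_recan("times must be strictly increasing")
  if (!is.null(weights)) {
    if (length(weights) != nrow(values) || any(!is.finite(weights)) ||
        any(weights <= 0))
      stop_recan("weights must be positive and match the spatial dimension")
  }
  structure(
    list(values = values, times = as.numeric(times), parameter = parameter,
         region = region, weights = weights),
    class = "field_ts")
}

#' @export
print.field_ts <- function(x, ...) {
  cat(sprintf("<field_ts> %s @ %s: %d spatial samples x %d timepoints, t in [%g, %g] s%s\n",
              x$parameter, x$region, nrow(x$values), ncol(x$values),
              min(x$times), max(x$times),
              if (is.null(x$weights)) "" else ", area-weighted"))
  invisible(x)
}

#' Simulation constants
#'
#' @param rho blood density in kg/m^3; default 1100.
#' @return list of class `sim_constants`.
#' @export
sim_constants <- function(rho = 1100) {
  check_number(rho, "rho", positive = TRUE)
  structure(list(rho = rho), class = "sim_constants")
}

#' Inlet reference quantities
#'
#' Spatiotemporally averaged quantities at the aneurysm inlet plane of the
#' parent artery, used as time-constant normalizers, plus the inlet
#' volumetric flow-rate time series.
#'
#' @param v_inlet spatiotemporally averaged inlet velocity, m/s (> 0).
#' @param p_inlet spatiotemporally averaged inlet static pressure, Pa.
#' @param wss_inlet spatiotemporally averaged inlet wall shear stress,
#'   Pa (> 0).
#' @param q_inlet inlet volumetric flow-rate time series, m^3/s, all
#'   positive.
#' @return list of class `inlet_reference`.
#' @export
inlet_reference <- function(v_inlet, p_inlet, wss_inlet, q_inlet) {
  check_number(v_inlet, "v_inlet", positive = TRUE)
  check_number(p_inlet, "p_inlet")
  check_number(wss_inlet, "wss_inlet", positive = TRUE)
  if (any(q_inlet <= 0)) stop_recan("q_inlet must be positive everywhere")
  structure(list(v_inlet = v_inlet, p_inlet = p_inlet,
                 wss_inlet = wss_inlet, q_inlet = as.numeric(q_inlet)),
            class = "inlet_reference")
}

# Inlet dynamic pressure 0.5 * rho * v_inlet^2, the denominator of the
# dimensionless pressure-difference score.
inlet_dynamic_pressure <- function(ref, constants) {
  0.5 * constants$rho * ref$v_inlet^2
}

#' Normalize a hemodynamic field by its inlet reference
#'
#' Converts a field in physical units to the dimensionless form used for
#' feature extraction: velocity is divided by the averaged inlet velocity,
#' wall shear stress by the inlet WSS, static pressure by the inlet
#' pressure, and dynamic pressure by the inlet dynamic pressure
#' `0.5 * rho * v_inlet^2`. The normalizer is a single time-constant
#' scalar.
#'
#' @param field a [field_ts()] in physical units.
#' @param ref an [inlet_reference()].
#' @param constants a [sim_constants()].
#' @return the dimensionless `field_ts`.
#' @export
normalize_field <- function(field, ref, constants = sim_constants()) {
  stopifnot(inherits(field, "field_ts"))
  norm <- switch(field$parameter,
    volvel = ref$v_inlet,
    WSS    = ref$wss_inlet,
    P      = ref$p_inlet,
    Pdyn   = inlet_dynamic_pressure(ref, constants),
    stop_recan("no inlet normalizer defined for parameter '%s'",
               field$parameter))
  if (!is.finite(norm) || norm == 0)
    stop_recan("degenerate inlet reference: zero normalizer for '%s'",
               field$parameter)
  field$values <- field$values / norm
  field
}

#' Dynamic pressure from a velocity field
#'
#' `Pdyn = 0.5 * rho * v^2`, elementwise, in Pa.
#'
#' @param velocity_field a [field_ts()] of velocity magnitude in m/s
#'   (all values must be non-negative).
#' @param constants a [sim_constants()].
#' @return a `field_ts` with `parameter = "Pdyn"`.
#' @export
compute_dynamic_pressure <- function(velocity_field, constants = sim_constants()) {
  stopifnot(inherits(velocity_field, "field_ts"))
  if (any(velocity_field$values < 0))
    stop_recan("velocity magnitude must be non-negative")
  field_ts(0.5 * constants$rho * velocity_field$values^2,
           velocity_field$times, "Pdyn", velocity_field$region,
           velocity_field$weights)
}

#' Pressure change between the post-coiling neck and the inlet
#'
#' `PP = P - p_inlet` elementwise, in Pa, computed on the static-pressure
#' field at the neck plane of the virtual post-coiling model.
#'
#' @param p_field a [field_ts()] of static pressure at region
#'   `"vm_neck"`, Pa.
#' @param ref an [inlet_reference()].
#' @return a `field_ts` with `parameter = "PP"`.
#' @export
compute_pp <- function(p_field, ref) {
  stopifnot(inherits(p_field, "field_ts"))
  if (p_field$region != "vm_neck")
    stop_recan("PP is defined on the virtual-model neck plane ('vm_neck')")
  field_ts(p_field$values - ref$p_inlet, p_field$times, "PP",
           p_field$region, p_field$weights)
}

#' Dimensionless pressure difference
#'
#' `PD = PP / (0.5 * rho * v_inlet^2)`: the neck pressure excess in units
#' of the inlet dynamic pressure.
#'
#' @param pp_field a [field_ts()] of pressure change (`PP`) in Pa.
#' @param ref an [inlet_reference()] with `v_inlet > 0`.
#' @param constants a [sim_constants()].
#' @return a dimensionless `field_ts` with `parameter = "PD"`.
#' @export
compute_pd <- function(pp_field, ref, constants = sim_constants()) {
  stopifnot(inherits(pp_field, "field_ts"))
  q <- inlet_dynamic_pressure(ref, constants)
  if (!is.finite(q) || q == 0)
    stop_recan("degenerate inlet reference: v_inlet must be > 0")
  field_ts(pp_field$values / q, pp_field$times, "PD",
           pp_field$region, pp_field$weights)
}

#' Inflow rate ratio time series
#'
#' `FR(t) = q_neck(t) / q_inlet(t)`: the inflow rate through the neck
#' plane relative to the flow rate at the inlet plane, per timepoint.
#'
#' @param q_neck neck-plane inflow-rate time series, m^3/s.
#' @param q_inlet inlet flow-rate time series, m^3/s, all positive, on
#'   the same time grid.
#' @return numeric vector of dimensionless ratios.
#' @export
compute_fr <- function(q_neck, q_inlet) {
  if (length(q_neck) != length(q_inlet))
    stop_recan("q_neck and q_inlet must share one time grid")
  if (any(q_inlet <= 0)) stop_recan("q_inlet must be positive everywhere")
  as.numeric(q_neck) / as.numeric(q_inlet)
}

#' Spatial reduction of a field to a time series
#'
#' Reduces the spatial dimension at each timepoint, either by the
#' (area-weighted) mean (`"ave"`) or the maximum (`"max"`), giving the
#' `X_ave` and `X_max` temporal profiles.
#'
#' @param field a [field_ts()].
#' @param method `"ave"` or `"max"`.
#' @return numeric vector, one value per timepoint.
#' @export
spatial_reduce <- function(field, method = c("ave", "max")) {
  stopifnot(inherits(field, "field_ts"))
  method <- match.arg(method)
  v <- field$values
  if (method == "max") {
    out <- apply(v, 2L, max)
  } else if (is.null(field$weights)) {
    out <- colMeans(v)
  } else {
    w <- field$weights / sum(field$weights)
    out <- as.numeric(crossprod(w, v))
  }
  names(out) <- NULL
  out
}

temporal_descriptors <- c("a", "median", "q1", "q2", "max", "min", "std")

#' Seven temporal descriptors of a reduced time series
#'
#' Computes the time-average (`a`), median, 25th and 75th percentiles
#' (`q1`, `q2`), maximum, minimum and sample standard deviation (`std`,
#' denominator n-1) of a time series, optionally restricted to an
#' analysis window. Percentiles use linear interpolation between order
#' statistics.
#'
#' @param series numeric time series.
#' @param times optional timepoints (needed when `window` is given).
#' @param window optional numeric `c(t0, t1)`: only timepoints with
#'   `t0 <= t <= t1` enter the summary.
#' @return named numeric vector with elements `a`, `median`, `q1`, `q2`,
#'   `max`, `min`, `std`.
#' @export
temporal_reduce <- function(series, times = NULL, window = NULL) {
  x <- as.numeric(series)
  if (!is.null(window)) {
    if (is.null(times)) stop_recan("'times' is required when 'window' is given")
    keep <- times >= window[1] & times <= window[2]
    x <- x[keep]
  }
  if (length(x) < 2L)
    stop_recan("analysis window contains fewer than 2 timepoints")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(a = mean(x), median = q[2], q1 = q[1], q2 = q[3],
    max = max(x), min = min(x), std = stats::sd(x))
}
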
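# Plain-text cohort serialization: one CSV per patient-region-parameter
# (columns sample_id, weight, t_0..t_N) plus flows.csv per patient, and a
# JSON manifest carrying labels, covariates, morphometry, inlet
# references, time grids and file paths.

field_to_df <- function(field) {
  v <- field$values
  df <- data.frame(sample_id = seq_len(nrow(v)),
                   weight = field$weights %||% rep(NA_real_, nrow(v)))
  vt <- as.data.frame(v)
  names(vt) <- paste0("t_", seq_len(ncol(v)) - 1L)
  cbind(df, vt)
}

df_to_field <- function(df, times, parameter, region) {
  w <- df$weight
  if (all(is.na(w))) w <- NULL
  v <- as.matrix(df[, grep("^t_", names(df)), drop = FALSE])
  dimnames(v) <- NULL
  field_ts(v, times, parameter, region, weights = w)
}

#' Write a cohort to a plain-text directory layout
#'
#' Serializes each patient's fields to one CSV per region-parameter,
#' the inflow series to `flows.csv`, and all metadata (labels, clinical
#' covariates, morphometry, inlet references, time grid, file paths) to
#' `manifest.json`. [read_cohort()] round-trips the result.
#'
#' @param cohort a `recan_cohort`.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "recan_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort$patients, function(p) {
    pdir <- file.path(dir, p$id)
    dir.create(pdir, showWarnings = FALSE)
    files <- list()
    for (nm in names(p$fields)) {
      f <- p$fields[[nm]]
      rel <- file.path(p$id, paste0(nm, ".csv"))
      utils::write.csv(field_to_df(f), file.path(dir, rel), row.names = FALSE)
      files[[nm]] <- list(path = rel, parameter = f$parameter,
                          region = f$region)
    }
    flows <- data.frame(series = c("q_inlet", "q_neck"))
    ft <- as.data.frame(rbind(p$q_inlet, p$q_neck))
    names(ft) <- paste0("t_", seq_along(p$q_inlet) - 1L)
    rel_flow <- file.path(p$id, "flows.csv")
    utils::write.csv(cbind(flows, ft), file.path(dir, rel_flow),
                     row.names = FALSE)
    list(id = p$id, label = p$label, seed = p$seed,
         cycle_duration = p$cycle_duration, n_cycles = p$n_cycles,
         times = p$times, clinical = p$clinical,
         morphometry = p$morphometry,
         inlet = list(v_inlet = p$inlet$v_inlet, p_inlet = p$inlet$p_inlet,
                      wss_inlet = p$inlet$wss_inlet),
         fields = files, flow_file = rel_flow)
  })
  manifest <- list(
    seed = cohort$seed,
    waveform = unclass(cohort$waveform),
    effects = list(params = as.data.frame(cohort$effects),
                   spatial_cv = attr(cohort$effects, "spatial_cv"),
                   temporal_cv = attr(cohort$effects, "temporal_cv")),
    patients = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.json`.
#' @return a `recan_cohort`.
#' @export
read_cohort <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE, simplifyDataFrame = FALSE)
  wf <- mf$waveform
  waveform <- waveform_spec(wf$cycle_duration, wf$n_cycles,
                            wf$sampling_interval,
                            matrix(unlist(wf$harmonics), ncol = 2),
                            wf$baseline)
  eff <- effect_spec(as.data.frame(mf$effects$params),
                     spatial_cv = mf$effects$spatial_cv,
                     temporal_cv = mf$effects$temporal_cv)
  patients <- lapply(mf$patients, function(e) {
    times <- as.numeric(e$times)
    fields <- lapply(e$fields, function(fi) {
      df <- utils::read.csv(file.path(dir, fi$path))
      df_to_field(df, times, fi$parameter, fi$region)
    })
    flows <- utils::read.csv(file.path(dir, e$flow_file))
    fv <- as.matrix(flows[, grep("^t_", names(flows)), drop = FALSE])
    q_inlet <- as.numeric(fv[flows$series == "q_inlet", ])
    q_neck <- as.numeric(fv[flows$series == "q_neck", ])
    structure(
      list(id = e$id, label = e$label, fields = fields,
           q_inlet = q_inlet, q_neck = q_neck, times = times,
           inlet = inlet_reference(e$inlet$v_inlet, e$inlet$p_inlet,
                                   e$inlet$wss_inlet, q_inlet),
           morphometry = e$morphometry, clinical = e$clinical,
           cycle_duration = e$cycle_duration, n_cycles = e$n_cycles,
           seed = e$seed),
      class = "recan_patient")
  })
  structure(list(patients = patients, effects = eff, waveform = waveform,
                 seed = mf$seed),
            class = "recan_cohort")
}
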
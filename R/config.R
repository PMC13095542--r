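# Configuration files and clinical-record ingestion.

CONFIG_KEYS <- c("T", "TBV", "pump", "speed", "solver", "overrides",
                 "seed", "log_level")

#' Load a run configuration from JSON
#'
#' Schema: optional `T`, `TBV`, `speed`, `seed`, `log_level`, `pump`
#' (`"none"`, `"heartmate3"`, `"corheart6"`), `solver` (object with `dt`,
#' `t_end`, `fs`, `rtol`) and `overrides` (flat parameter name -> value).
#' Unknown keys are rejected by name; defaults fill everything else.
#'
#' @param path JSON file path.
#' @return list of class `run_config` with `params` (a
#'   [circulation_params()]), `solver` (a [solver_config()]), `seed` and
#'   `log_level`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  pump <- NULL
  if (!is.null(raw$pump) && raw$pump != "none")
    pump <- pump_presets(raw$pump)
  params <- circulation_params(
    T = raw$T %||% 0.8, TBV = raw$TBV %||% 900, pump = pump,
    speed = raw$speed %||% 0,
    overrides = as.list(raw$overrides %||% list()))
  sv <- raw$solver %||% list()
  solver <- solver_config(dt = sv$dt %||% 5e-5, t_end = sv$t_end %||% 60,
                          fs = sv$fs %||% 200, rtol = sv$rtol %||% 1e-3)
  structure(list(params = params, solver = solver,
                 seed = as.integer(raw$seed %||% 1L),
                 log_level = raw$log_level %||% "info"),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dump a run configuration back to JSON
#'
#' Round-trips through [load_config()]: `load -> dump -> load` is
#' idempotent.
#'
#' @param config a `run_config`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  p <- config$params
  defaults <- circulation_params(T = p$T, TBV = p$TBV)
  ov <- list()
  for (nm in unlist(lapply(SEGMENT_NAMES, .flat_seg), use.names = FALSE)) {
    if (!identical(get_param(p, nm), get_param(defaults, nm)))
      ov[[nm]] <- get_param(p, nm)
  }
  for (ch in CHAMBER_NAMES) for (f in c("Emax", "Emin", "V0")) {
    nm <- paste0(f, "_", ch)
    if (!identical(get_param(p, nm), get_param(defaults, nm)))
      ov[[nm]] <- get_param(p, nm)
  }
  jsonlite::write_json(list(
    T = p$T, TBV = p$TBV,
    pump = if (is.null(p$pump)) "none" else p$pump$name,
    speed = p$speed, overrides = ov,
    solver = config$solver[c("dt", "t_end", "fs", "rtol")],
    seed = config$seed, log_level = config$log_level),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Body surface area by the Du Bois formula
#'
#' `BSA = 0.007184 * height^0.725 * weight^0.425` (height cm, weight kg).
#'
#' @param height_cm height in cm.
#' @param weight_kg weight in kg.
#' @return BSA in m^2.
#' @export
bsa_du_bois <- function(height_cm, weight_kg) {
  stopifnot(height_cm > 0, weight_kg > 0)
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

#' Ingest a clinical record into the estimator's feature layout
#'
#' Reads a JSON file with echo-derived waveforms and scalars, resamples
#' the waveforms to the dataset grid, and derives total blood volume from
#' body surface area (Du Bois formula from height/weight, or a direct
#' `BSA` override) via a configurable volume coefficient.  The
#' blood-pressure *waveform* is required: reconstructing one from a
#' systolic/diastolic pair is refused unless `allow_template = TRUE`, in
#' which case a scaled template beat is substituted and flagged.
#'
#' Required fields: `T` (s; never predicted, always measured),
#' `q_lv`, `q_rv` (outflow-tract flow waveforms, mL/s), `ap` (arterial
#' pressure waveform, mmHg) or `ap_sys`/`ap_dia` with the template flag,
#' `LV_EDV`, `LV_ESV`, `RV_EDV`, `RV_ESV` (mL), and `height`/`weight` (cm,
#' kg) or `BSA` (m^2).
#'
#' @param path JSON file path.
#' @param n_wave target waveform length.
#' @param tbv_per_m2 blood volume per body surface area (mL/m^2); an
#'   assumption, documented and configurable.
#' @param allow_template permit blood-pressure reconstruction from a
#'   systolic/diastolic pair.
#' @return a single-record container compatible with
#'   [predict_parameters()] (fields `q_lv`, `q_rv`, `ap`, `scalars`).
#' @export
ingest_clinical_record <- function(path, n_wave = 256, tbv_per_m2 = 2500,
                                   allow_template = FALSE) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("T", "q_lv", "q_rv", "LV_EDV", "LV_ESV", "RV_EDV", "RV_ESV")
  missing <- setdiff(need, names(raw))
  if (!("ap" %in% names(raw))) {
    if (all(c("ap_sys", "ap_dia") %in% names(raw))) {
      if (!allow_template)
        stop("blood-pressure waveform required; a systolic/diastolic ",
             "pair is only accepted with allow_template = TRUE")
    } else missing <- c(missing, "ap")
  }
  if (!("BSA" %in% names(raw)) &&
      !all(c("height", "weight") %in% names(raw)))
    missing <- c(missing, "height/weight or BSA")
  if (length(missing))
    stop("clinical record missing fields: ",
         paste(missing, collapse = ", "))
  bsa <- raw$BSA %||% bsa_du_bois(raw$height, raw$weight)
  tbv <- bsa * tbv_per_m2
  res <- function(y) stats::approx(seq(0, 1, length.out = length(y)), y,
                                   xout = seq(0, 1 - 1 / n_wave,
                                              length.out = n_wave))$y
  ap <- if (!is.null(raw$ap)) res(raw$ap) else {
    # scaled template beat: a systolic half-sine on the diastolic baseline
    phase <- seq(0, 1 - 1 / n_wave, length.out = n_wave)
    raw$ap_dia + (raw$ap_sys - raw$ap_dia) *
      ifelse(phase < 0.4, sin(pi * phase / 0.4), 0)
  }
  scalars <- matrix(c(raw$LV_EDV, raw$LV_ESV, raw$RV_EDV, raw$RV_ESV,
                      tbv, raw$T, NA, NA, NA, NA), nrow = 1,
                    dimnames = list(NULL, c("LV_EDV", "LV_ESV", "RV_EDV",
                                            "RV_ESV", "TBV", "T", "Pes_lv",
                                            "Pes_rv", "Ves_lv", "Ves_rv")))
  structure(list(q_lv = matrix(res(raw$q_lv), 1),
                 q_rv = matrix(res(raw$q_rv), 1),
                 ap = matrix(ap, 1), scalars = scalars,
                 labels = matrix(numeric(0), 1, 0), split = factor("test"),
                 provenance = list(source = path, BSA = bsa,
                                   tbv_per_m2 = tbv_per_m2)),
            class = "lpm_dataset")
}

#' Write a simulation result to CSV (long format)
#'
#' Columns `time`, `variable`, `value`; variables are `P_<node>`,
#' `V_<node>` and `Q_<branch>`.
#'
#' @param result a `simulation_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(result, path) {
  long <- function(m, prefix) do.call(rbind, lapply(colnames(m),
    function(nm) data.frame(time = result$time,
                            variable = paste0(prefix, nm),
                            value = m[, nm])))
  out <- rbind(long(result$pressures, "P_"), long(result$volumes, "V_"),
               long(result$flows, "Q_"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
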
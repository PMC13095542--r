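# Clinical hemodynamic indices, pressure-volume loops, and ramp tests.

# Measurement-site conventions used across the package: arterial ("cuff")
# pressure is read at the systemic-artery node, pulmonary-artery pressure at
# the proximal pulmonary node where a catheter tip would sit.
AP_NODE <- "SAT"
PAP_NODE <- "PAS"

#' Hemodynamic indicators over one steady cycle
#'
#' Cardiac output is the cycle-mean systemic forward flow (aortic valve
#' plus pump outflow) in L/min.  Arterial pressure statistics are taken at
#' the systemic-artery node (the brachial-cuff site); pulmonary artery
#' pressure at the proximal pulmonary-artery node;
#' PCWP is approximated by the cycle-mean pulmonary-venous pressure and CVP
#' by the cycle-mean right-atrial pressure (standard lumped-model
#' surrogates).  EDV/ESV are the extrema of the ventricular volume traces.
#'
#' @param result a `simulation_result`.
#' @param window a window from [detect_steady_state()]; computed if `NULL`.
#' @return a list of class `hemodynamic_indicators`.
#' @export
compute_indicators <- function(result, window = NULL) {
  if (is.null(window)) window <- detect_steady_state(result)
  i <- window$idx
  if (length(i) < 2 ||
      diff(range(result$time[i])) < window$T * (1 - 2 / length(i)))
    stop("window must span one full cardiac cycle")
  ap <- result$pressures[i, AP_NODE]
  pap <- result$pressures[i, PAP_NODE]
  q_sys <- result$flows[i, "AV"] + result$flows[i, "PUMP"]
  out <- list(
    CO = mean(q_sys) * 60 / 1000,
    AP_max = max(ap), AP_min = min(ap), AP_mean = mean(ap),
    PAP_max = max(pap), PAP_min = min(pap), PAP_mean = mean(pap),
    PCWP = mean(result$pressures[i, "PVN"]),
    CVP = mean(result$pressures[i, "RA"]),
    LV_EDV = max(result$volumes[i, "LV"]),
    LV_ESV = min(result$volumes[i, "LV"]),
    RV_EDV = max(result$volumes[i, "RV"]),
    RV_ESV = min(result$volumes[i, "RV"]))
  structure(out, class = "hemodynamic_indicators")
}

#' Pressure-volume loop
#'
#' Ordered (volume, pressure) points of one chamber over one steady cycle,
#' closed by repeating the first point; the loop area (stroke work,
#' mmHg.mL) is computed with the shoelace rule.
#'
#' @param result a `simulation_result`.
#' @param chamber chamber name, default `"LV"`.
#' @param window steady-cycle window (defaults to [detect_steady_state()]).
#' @return list of class `pv_loop` with `volume`, `pressure`, `area`.
#' @export
pv_loop <- function(result, chamber = "LV", window = NULL) {
  if (is.null(window)) window <- detect_steady_state(result)
  i <- window$idx
  v <- result$volumes[i, chamber]
  p <- result$pressures[i, chamber]
  v <- c(v, v[1]); p <- c(p, p[1])
  structure(list(chamber = chamber, volume = v, pressure = p,
                 area = shoelace_area(v, p)),
            class = "pv_loop")
}

#' Polygon area by the shoelace rule
#'
#' @param x,y vertex coordinates (the polygon is closed implicitly).
#' @return absolute enclosed area.
#' @export
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Stepped pump-speed ramp test
#'
#' Holds each speed of an increasing staircase until a periodic steady
#' state, recording per-step ventricular volumes, pump flow, and
#' backflow/suction flags.  The run is warm-started from the previous
#' step's final state, as in a clinical ramp protocol.
#'
#' @param params a [circulation_params()] (a pump must be attached or
#'   passed via `pump`).
#' @param pump optional [pump_model()] overriding `params$pump`.
#' @param speeds increasing vector of pump speeds (rpm).
#' @param settle seconds simulated per step (the last cycle is analysed).
#' @param solver solver settings for each step (t_end is overridden).
#' @return data.frame of class `ramp_result`: one row per speed with
#'   `speed`, `LV_mean`, `LV_EDV`, `LV_ESV`, `RV_mean`, `RV_EDV`,
#'   `RV_ESV`, `pump_flow` (cycle-mean, mL/s), `backflow`, `suction`,
#'   `av_opens` (aortic valve opens during the cycle).
#' @export
ramp_test <- function(params, pump = NULL, speeds = seq(2000, 6000, 400),
                      settle = 20, solver = solver_config()) {
  if (!is.null(pump)) params$pump <- pump
  if (is.null(params$pump)) stop("ramp test needs a pump")
  if (any(diff(speeds) <= 0)) stop("speed schedule must be increasing")
  validate_params(params)
  sv <- solver; sv$t_end <- settle
  state <- NULL
  rows <- vector("list", length(speeds))
  for (k in seq_along(speeds)) {
    params$speed <- speeds[k]
    if (is.null(state)) state <- initial_state(params)
    r <- simulate_lpm(params, sv, init = state)
    state <- r$final_state
    w <- detect_steady_state(r)
    i <- w$idx
    qp <- r$flows[i, "PUMP"]
    rows[[k]] <- data.frame(
      speed = speeds[k],
      LV_mean = mean(r$volumes[i, "LV"]),
      LV_EDV = max(r$volumes[i, "LV"]), LV_ESV = min(r$volumes[i, "LV"]),
      RV_mean = mean(r$volumes[i, "RV"]),
      RV_EDV = max(r$volumes[i, "RV"]), RV_ESV = min(r$volumes[i, "RV"]),
      pump_flow = mean(qp),
      backflow = mean(qp) < 0,
      suction = any(r$suction[i]),
      av_opens = max(r$flows[i, "AV"]) > 1)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ramp_result", class(out))
  out
}

#' Left-to-right ventricular volume change ratio over a ramp
#'
#' `|dV_LV| / |dV_RV|` between the first step without pump backflow and the
#' last step before suction onset; the published clinical observation is a
#' ratio of about two.
#'
#' @param ramp a `ramp_result`.
#' @return the dimensionless ratio.
#' @export
volume_change_ratio <- function(ramp) {
  lo <- which(!ramp$backflow)[1]
  pre_suction <- which(!ramp$suction)
  hi <- if (any(ramp$suction)) max(pre_suction[pre_suction < which(ramp$suction)[1]])
        else nrow(ramp)
  if (is.na(lo) || !length(hi) || hi <= lo)
    stop("ramp does not span a backflow-free, pre-suction range")
  d_lv <- ramp$LV_mean[hi] - ramp$LV_mean[lo]
  d_rv <- ramp$RV_mean[hi] - ramp$RV_mean[lo]
  if (abs(d_rv) < 1e-9) stop("degenerate ramp: no RV volume change")
  abs(d_lv) / abs(d_rv)
}

#' @export
print.hemodynamic_indicators <- function(x, ...) {
  cat(sprintf("CO %.2f L/min | AP %.0f/%.0f (mean %.0f) mmHg | PAP %.1f/%.1f (mean %.1f)\n",
              x$CO, x$AP_max, x$AP_min, x$AP_mean, x$PAP_max, x$PAP_min,
              x$PAP_mean))
  cat(sprintf("PCWP %.1f | CVP %.1f mmHg | LV %.0f/%.0f mL | RV %.0f/%.0f mL (EDV/ESV)\n",
              x$PCWP, x$CVP, x$LV_EDV, x$LV_ESV, x$RV_EDV, x$RV_ESV))
  invisible(x)
}
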
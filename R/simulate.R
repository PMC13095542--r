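# Simulation of the closed-loop circulation to hemodynamic steady state.

#' Solver configuration
#'
#' The circuit is integrated with a fixed-step classic Runge-Kutta scheme in
#' compiled code.  The step is chosen well inside the stability limit set by
#' the fastest R*C time constant of the circuit (about 0.5 ms with the
#' shipped defaults); `rtol` is used for steady-state and conservation
#' diagnostics, not for step control.
#'
#' @param dt integration step (s).
#' @param t_end simulated duration (s); the default 60 s reaches a periodic
#'   hemodynamic steady state from any reasonable initial charge.
#' @param fs output sampling rate (Hz).
#' @param rtol relative tolerance used by diagnostics.
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(dt = 5e-5, t_end = 60, fs = 200, rtol = 1e-3) {
  stopifnot(dt > 0, t_end > 0, fs > 0, rtol > 0)
  structure(list(method = "rk4", dt = dt, t_end = t_end, fs = fs,
                 rtol = rtol), class = "solver_config")
}

#' Time-varying chamber elastance
#'
#' `E(t) = Emin + (Emax - Emin) e(t)` with a cosine rise over the systolic
#' duration and a cosine relaxation over half that duration, periodic with
#' the cardiac cycle `T`; the maximum `Emax` is attained at end-systole.
#'
#' @param t time(s) in seconds (vectorised).
#' @param chamber a [chamber_params()].
#' @param T cardiac cycle length (s), `> 0`.
#' @return elastance in mmHg/mL, same length as `t`.
#' @export
elastance_waveform <- function(t, chamber, T) {
  if (!(is.numeric(T) && T > 0)) stop("cycle length T must be > 0")
  .elastance_cpp(as.numeric(t), chamber$Emax, chamber$Emin,
                 chamber$onset_frac, chamber$ts_frac * T, T)
}

#' Chamber pressure from volume and elastance
#'
#' `P = E (V - V0)`; linear in the stressed volume.
#'
#' @param V chamber volume (mL).
#' @param chamber a [chamber_params()] (supplies `V0`).
#' @param E elastance (mmHg/mL).
#' @return pressure in mmHg.
#' @export
chamber_pressure <- function(V, chamber, E) E * (V - chamber$V0)

#' Pump pressure head
#'
#' The quadratic pump law `H = Ka Q^2 + Kb Q w + Kc w^2`, algebraically
#' exact for forward flow.  For reverse flow the quadratic loss term uses
#' the odd extension `Ka Q |Q|` so that it keeps opposing the flow.
#'
#' @param Q pump flow (mL/s).
#' @param w pump speed (rpm).
#' @param pump a [pump_model()].
#' @return pressure head in mmHg.
#' @export
pump_pressure_head <- function(Q, w, pump) {
  pump$Ka * Q * abs(Q) + pump$Kb * Q * w + pump$Kc * w^2
}

#' Smoothed diode valve flow
#'
#' A heart valve is a two-state resistor: `R_open` when forward-biased,
#' `R_closed` when reverse-biased, blended over a narrow logistic
#' transition in the pressure drop for solver stability.
#'
#' @param dP pressure drop across the valve (mmHg), forward positive.
#' @param R_open,R_closed open/closed resistances (mmHg.s/mL).
#' @param width logistic transition scale (mmHg).
#' @return flow in mL/s (vectorised over `dP`).
#' @export
valve_flow <- function(dP, R_open = 0.005, R_closed = 1e6, width = 0.025) {
  .valve_flow_cpp(as.numeric(dP), R_open, R_closed, width)
}

#' Suction-dependent inflow cannula resistance
#'
#' Equal to the baseline cannula resistance while LV pressure stays at or
#' above the suction threshold; grows linearly (continuously at the knee)
#' with the pressure deficit below it.
#'
#' @param P_lv left-ventricular pressure (mmHg), vectorised.
#' @param pump a [pump_model()].
#' @return inlet resistance (mmHg.s/mL).
#' @export
suction_resistance <- function(P_lv, pump) {
  pump$R_in + pump$suction_gain * pmax(0, pump$suction_threshold - P_lv)
}

#' Initial state distributing total blood volume
#'
#' Chambers start at their unstressed volume plus a share of the stressed
#' blood volume proportional to each element's compliance evaluated at a
#' uniform reference pressure (chambers use their diastolic compliance
#' `1/Emin`).  Any distribution converges to the same periodic state; this
#' one avoids start-up stiffness.
#'
#' @param params a [circulation_params()].
#' @return numeric state vector (volumes, then branch flows).
#' @export
initial_state <- function(params) {
  caps_ch <- vapply(params$chambers, function(ch) 1 / ch$Emin, 0)
  caps_sg <- vapply(params$segments, function(sg) sg$C, 0)
  v0_ch <- vapply(params$chambers, function(ch) ch$V0, 0)
  v0_sg <- vapply(params$segments, function(sg) sg$V0, 0)
  stressed <- params$TBV - sum(v0_ch) - sum(v0_sg)
  if (stressed <= 0) stop("TBV smaller than total unstressed volume")
  caps <- c(caps_ch, caps_sg)
  share <- stressed * caps / sum(caps)
  y <- c(v0_ch + share[1:4], v0_sg + share[5:12], 0)
  if (!is.null(params$pump)) y <- c(y, 0)
  unname(y)
}

#' Circuit right-hand side
#'
#' Time derivative of the state (Kirchhoff current balance at every storage
#' node, pump and aortic branch momentum).  Exposed mainly for testing; the
#' integrator calls the same compiled code.
#'
#' @param state state vector as produced by [initial_state()].
#' @param t time (s).
#' @param params a [circulation_params()].
#' @return derivative vector of the same length.
#' @export
circuit_rhs <- function(state, t, params) {
  .lpm_rhs_cpp(t, as.numeric(state), flatten_params(params))
}

#' Simulate the closed loop to steady state
#'
#' @param params a [circulation_params()].
#' @param solver a [solver_config()].
#' @param init optional initial state (defaults to [initial_state()]).
#' @return an object of class `simulation_result` with fields `time`,
#'   `volumes` and `pressures` (matrices with one column per node, in the
#'   order RA, RV, LA, LV, AO, SAT, SAR, SVN, PAS, PAT, PCP, PVN), `flows`
#'   (columns TV, PV, MV, AV, AOBR, PUMP), `suction` (logical), the
#'   `final_state`, and the originating `params`/`solver`.
#' @export
simulate_lpm <- function(params, solver = solver_config(), init = NULL) {
  validate_params(params)
  if (is.null(init)) init <- initial_state(params)
  raw <- .lpm_simulate_cpp(flatten_params(params), as.numeric(init),
                           solver$t_end, solver$dt, solver$fs)
  nodes <- c(CHAMBER_NAMES, SEGMENT_NAMES)
  colnames(raw$volumes) <- nodes
  colnames(raw$pressures) <- nodes
  colnames(raw$flows) <- c("TV", "PV", "MV", "AV", "AOBR", "PUMP")
  structure(list(time = raw$time, volumes = raw$volumes,
                 pressures = raw$pressures, flows = raw$flows,
                 suction = raw$suction, final_state = raw$final_state,
                 params = params, solver = solver),
            class = "simulation_result")
}

#' Locate the last full steady-state cycle
#'
#' Returns the final complete `[t0, t0 + T)` window aligned to the
#' ventricular activation onset (cycle boundaries at multiples of `T`),
#' together with the cycle-to-cycle residual against the preceding window.
#'
#' @param result a `simulation_result`.
#' @param T cardiac cycle (s); defaults to the simulated parameter set's.
#' @return list with `t0`, `T`, integer sample `idx`, and `residual` (max
#'   over traces of the relative L2 difference to the previous cycle).
#' @export
detect_steady_state <- function(result, T = result$params$T) {
  t_end <- result$time[length(result$time)]
  if (t_end < 3 * T) stop("need at least three cycles, got ", t_end, " s")
  n_full <- floor(t_end / T + 1e-9)
  t0 <- (n_full - 1) * T
  idx <- which(result$time >= t0 - 1e-9 & result$time < t0 + T - 1e-9)
  prev <- which(result$time >= t0 - T - 1e-9 & result$time < t0 - 1e-9)
  n <- min(length(idx), length(prev))
  traces <- cbind(result$pressures, result$volumes)
  num <- sqrt(colSums((traces[idx[1:n], , drop = FALSE] -
                       traces[prev[1:n], , drop = FALSE])^2))
  den <- sqrt(colSums(traces[idx[1:n], , drop = FALSE]^2))
  list(t0 = t0, T = T, idx = idx, residual = max(num / pmax(den, 1e-12)))
}

#' Resample one cyclic trace onto a fixed-length grid
#'
#' Linear interpolation of `y(t)` onto `n` evenly spaced points across one
#' window; used to build fixed-length network inputs.
#'
#' @param t,y sampled trace.
#' @param t0,T window start and length (s).
#' @param n number of output points.
#' @return numeric vector of length `n`.
#' @export
resample_cycle <- function(t, y, t0, T, n = 256) {
  grid <- t0 + T * (seq_len(n) - 1) / n
  stats::approx(t, y, xout = pmin(grid, max(t)), rule = 2)$y
}
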
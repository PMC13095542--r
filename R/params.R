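# Parameter containers for the closed-loop lumped-parameter circulation.
#
# Units used throughout the package: pressure mmHg, volume mL, time s,
# resistance mmHg.s/mL, compliance mL/mmHg, inertance mmHg.s^2/mL,
# pump speed rpm, flow mL/s (cardiac output reported in L/min).

CHAMBER_NAMES <- c("RA", "RV", "LA", "LV")
SEGMENT_NAMES <- c("AO", "SAT", "SAR", "SVN", "PAS", "PAT", "PCP", "PVN")

#' Heart chamber parameters
#'
#' A chamber is a time-varying elastance element: `P(t) = E(t) (V(t) - V0)`
#' with `E(t)` sweeping `[Emin, Emax]` once per cardiac cycle.
#'
#' @param name one of `"RA"`, `"RV"`, `"LA"`, `"LV"`.
#' @param Emax,Emin peak / baseline elastance (mmHg/mL), `Emax >= Emin > 0`.
#' @param V0 unstressed volume (mL).
#' @param onset_frac activation onset as a fraction of the cycle in `[0, 1]`.
#' @param ts_frac systolic (rise) duration as a fraction of the cycle; the
#'   relaxation limb lasts half as long again.
#' @return an object of class `chamber_params`.
#' @export
chamber_params <- function(name, Emax, Emin, V0, onset_frac = 0,
                           ts_frac = 0.335) {
  name <- match.arg(name, CHAMBER_NAMES)
  stopifnot(is.numeric(Emax), is.numeric(Emin), length(Emax) == 1L)
  if (!(Emax >= Emin && Emin > 0)) stop("need Emax >= Emin > 0 for ", name)
  if (V0 < 0) stop("V0 must be >= 0 for ", name)
  if (onset_frac < 0 || onset_frac > 1 || ts_frac < 0 || ts_frac > 1)
    stop("activation timing fractions must lie in [0, 1]")
  structure(list(name = name, Emax = Emax, Emin = Emin, V0 = V0,
                 onset_frac = onset_frac, ts_frac = ts_frac),
            class = "chamber_params")
}

#' Vessel segment parameters
#'
#' Each vascular segment stores blood on a compliance `C` at its node and
#' drains through its exit resistance `R` (plus inertance `L` for the
#' aortic branch) into the next node.
#'
#' @param name one of `"AO"`, `"SAT"`, `"SAR"`, `"SVN"`, `"PAS"`, `"PAT"`,
#'   `"PCP"`, `"PVN"`.
#' @param R exit resistance (mmHg.s/mL, `>= 0`).
#' @param C node compliance (mL/mmHg, `> 0`).
#' @param L exit inertance (mmHg.s^2/mL, `>= 0`).
#' @param V0 unstressed volume (mL, `>= 0`): node pressure is
#'   `(V - V0) / C`.  Nonzero mainly on the venous reservoirs, where most
#'   blood volume is stored at near-zero distending pressure.
#' @return an object of class `vessel_segment`.
#' @export
vessel_segment <- function(name, R, C, L = 0, V0 = 0) {
  name <- match.arg(name, SEGMENT_NAMES)
  if (!(C > 0)) stop("compliance must be > 0 for segment ", name)
  if (R < 0 || L < 0 || V0 < 0) stop("R, L and V0 must be >= 0 for segment ", name)
  structure(list(name = name, R = R, C = C, L = L, V0 = V0),
            class = "vessel_segment")
}

#' Continuous-flow pump model
#'
#' Pressure head across the pump follows the quadratic law
#' `H = Ka Q^2 + Kb Q w + Kc w^2` with flow `Q` (mL/s) and speed `w` (rpm).
#' Inflow and outflow cannulae carry series resistance and inertance; a
#' variable inlet resistor emulates ventricular suction, growing linearly
#' once left-ventricular pressure falls below `suction_threshold`.
#'
#' @param name pump label (free text; see [pump_presets()]).
#' @param Ka,Kb,Kc pump coefficients (mmHg.s^2/mL^2, mmHg.s/(mL.rpm),
#'   mmHg/rpm^2); `Kc` must be positive.
#' @param R_in,L_in,R_out,L_out cannula resistance/inertance.
#' @param suction_threshold LV pressure (mmHg) below which the inlet
#'   resistance starts to grow.
#' @param suction_gain added inlet resistance per mmHg of pressure deficit.
#' @return an object of class `pump_model`.
#' @export
pump_model <- function(name, Ka, Kb, Kc, R_in = 0.025, L_in = 0.01,
                       R_out = 0.025, L_out = 0.01,
                       suction_threshold = 2.5, suction_gain = 5) {
  if (!(Kc > 0)) stop("Kc must be > 0")
  if (any(c(R_in, L_in, R_out, L_out) < 0)) stop("cannula R/L must be >= 0")
  structure(list(name = name, Ka = Ka, Kb = Kb, Kc = Kc, R_in = R_in,
                 L_in = L_in, R_out = R_out, L_out = L_out,
                 suction_threshold = suction_threshold,
                 suction_gain = suction_gain),
            class = "pump_model")
}

#' Shipped pump coefficient presets
#'
#' Quadratic pressure-flow coefficients for two clinical continuous-flow
#' LVADs.  Note the pediatric pump's positive `Ka`: its head rises with
#' flow, so in a closed loop it is only marginally stable at high flow.
#'
#' @param name `"heartmate3"` or `"corheart6"`.
#' @return a [pump_model()].
#' @export
pump_presets <- function(name = c("heartmate3", "corheart6")) {
  name <- match.arg(name)
  switch(name,
    heartmate3 = pump_model("heartmate3", Ka = -1.8e-3, Kb = -1.2e-5,
                            Kc = 7.3e-6),
    corheart6  = pump_model("corheart6", Ka = 4.82e-3, Kb = 6.66e-5,
                            Kc = 7.2e-6))
}

#' Default circulation parameter set
#'
#' The healthy adult baseline: chamber elastances, cycle length and total
#' blood volume follow the published baseline table (LV 2.5/0.05/5,
#' RV 1.15/0.07/10, atria 0.25/0.15/0, T = 0.8 s, TBV = 900 mL).  Vessel
#' R/L/C values that the baseline table leaves unprinted are shipped as a
#' documented default set tuned once so that this baseline produces
#' physiological pressures (AP about 120/80 mmHg) and a cardiac output of
#' about 5 L/min; all of them can be overridden.  The venous unstressed
#' volume scales with `TBV` so that the stressed fraction of blood volume
#' stays physiological across the sampled blood-volume range.
#'
#' @param T cardiac cycle length (s).
#' @param TBV total blood volume (mL).
#' @param pump optional [pump_model()].
#' @param speed pump speed (rpm) when a pump is attached.
#' @param overrides named list of scalar parameter overrides using the flat
#'   names of [set_param()] (e.g. `list(Emax_LV = 1.0, Rsar = 0.8)`).
#' @return an object of class `circulation_params`.
#' @export
circulation_params <- function(T = 0.8, TBV = 900, pump = NULL, speed = 0,
                               overrides = list()) {
  stopifnot(T > 0, TBV > 0)
  ts_v <- min(0.3 * sqrt(T) / T, 0.45)  # systole scales with sqrt(T)
  chambers <- list(
    RA = chamber_params("RA", 0.25, 0.15, 0, onset_frac = 0.85,
                        ts_frac = 0.10),
    RV = chamber_params("RV", 1.15, 0.07, 10, 0, ts_v),
    LA = chamber_params("LA", 0.25, 0.15, 0, onset_frac = 0.85,
                        ts_frac = 0.10),
    LV = chamber_params("LV", 2.5, 0.05, 5, 0, ts_v))
  segments <- list(
    AO  = vessel_segment("AO",  R = 0.003, C = 0.30, L = 1.5e-5),
    SAT = vessel_segment("SAT", R = 0.05,  C = 1.0),
    SAR = vessel_segment("SAR", R = 1.02,  C = 0.02),
    SVN = vessel_segment("SVN", R = 0.008, C = 15,
                          V0 = 325 * TBV / 900),
    PAS = vessel_segment("PAS", R = 0.002, C = 0.03),
    PAT = vessel_segment("PAT", R = 4e-4,  C = 0.45),
    PCP = vessel_segment("PCP", R = 4e-4,  C = 0.15),
    PVN = vessel_segment("PVN", R = 4e-4,  C = 20.5))
  obj <- structure(list(chambers = chambers, segments = segments,
                        pump = pump, speed = speed, T = T, TBV = TBV,
                        valve = list(R_open = 0.005, R_closed = 1e6,
                                     width = 0.025)),
                   class = "circulation_params")
  for (nm in names(overrides)) obj <- set_param(obj, nm, overrides[[nm]])
  validate_params(obj)
  obj
}

validate_params <- function(p) {
  stopifnot(inherits(p, "circulation_params"), p$T > 0, p$TBV > 0)
  stopifnot(identical(names(p$chambers), CHAMBER_NAMES),
            identical(names(p$segments), SEGMENT_NAMES))
  for (ch in p$chambers)
    if (!(ch$Emax >= ch$Emin && ch$Emin > 0)) stop("bad elastances: ", ch$name)
  for (sg in p$segments) if (!(sg$C > 0)) stop("bad compliance: ", sg$name)
  if (!is.null(p$pump) && !inherits(p$pump, "pump_model"))
    stop("pump must be a pump_model or NULL")
  invisible(p)
}

# ---- flat parameter naming -------------------------------------------------
# Scalar access by the field's conventional names: Emax_LV, Emin_RA, V0_RV,
# Rao/Lao/Cao, Rsat/Csat, Rsar/Csar, Rsvn/Csvn, Rpas/Cpas, Rpat/Cpat,
# Rpcp/Cpcp, Rpvn/Cpvn, T, TBV.

.flat_seg <- function(nm) {
  lower <- tolower(nm)
  c(R = paste0("R", lower), C = paste0("C", lower), L = paste0("L", lower),
    V0 = paste0("V0", lower))
}

#' Get or set one scalar parameter by its flat name
#'
#' @param p a `circulation_params` object.
#' @param name flat parameter name, e.g. `"Rsar"`, `"Csat"`, `"Lao"`,
#'   `"Emax_LV"`, `"T"`, `"TBV"`.
#' @param value new value (for `set_param`).
#' @return `get_param` the scalar value; `set_param` the modified object.
#' @export
get_param <- function(p, name) {
  if (name %in% c("T", "TBV")) return(p[[name]])
  m <- regmatches(name, regexec("^(Emax|Emin|V0)_(RA|RV|LA|LV)$", name))[[1]]
  if (length(m)) {
    field <- c(Emax = "Emax", Emin = "Emin", V0 = "V0")[[m[2]]]
    return(p$chambers[[m[3]]][[field]])
  }
  for (sg in SEGMENT_NAMES) {
    fl <- .flat_seg(sg)
    hit <- names(fl)[fl == name]
    if (length(hit)) return(p$segments[[sg]][[hit]])
  }
  stop("unknown parameter name: ", name)
}

#' @rdname get_param
#' @export
set_param <- function(p, name, value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (name %in% c("T", "TBV")) { p[[name]] <- value; return(p) }
  m <- regmatches(name, regexec("^(Emax|Emin|V0)_(RA|RV|LA|LV)$", name))[[1]]
  if (length(m)) { p$chambers[[m[3]]][[m[2]]] <- value; return(p) }
  for (sg in SEGMENT_NAMES) {
    fl <- .flat_seg(sg)
    hit <- names(fl)[fl == name]
    if (length(hit)) { p$segments[[sg]][[hit]] <- value; return(p) }
  }
  stop("unknown parameter name: ", name)
}

#' Names of the systemic and pulmonary circulation parameters
#'
#' The candidate set for sensitivity-based identifiability analysis: every
#' vascular R/L/C except the small aortic node compliance `Cao`, which is a
#' numerical regularisation of the proximal windkessel (the classic
#' three-element windkessel has no storage between valve and characteristic
#' impedance) and is therefore held fixed.
#'
#' @return character vector of flat parameter names.
#' @export
circulation_parameter_names <- function() {
  out <- character(0)
  for (sg in SEGMENT_NAMES) {
    seg <- paste0(tolower(sg))
    out <- c(out, paste0("R", seg), paste0("C", seg))
    if (sg == "AO") out <- c(out, "Lao")
  }
  setdiff(out, "Cao")
}

# flatten to the fixed-order numeric vector consumed by the C++ integrator
flatten_params <- function(p) {
  v <- numeric(68)
  i <- 0
  for (nm in CHAMBER_NAMES) {
    ch <- p$chambers[[nm]]
    v[i + 1:5] <- c(ch$Emax, ch$Emin, ch$V0, ch$onset_frac, ch$ts_frac * p$T)
    i <- i + 5
  }
  for (nm in SEGMENT_NAMES) {
    sg <- p$segments[[nm]]
    v[i + 1:4] <- c(sg$R, sg$C, sg$L, sg$V0)
    i <- i + 4
  }
  v[53:55] <- c(p$valve$R_open, p$valve$R_closed, p$valve$width)
  v[56:57] <- c(p$T, p$TBV)
  if (is.null(p$pump)) {
    v[58] <- 0
  } else {
    pm <- p$pump
    v[58] <- 1
    v[59:68] <- c(pm$Ka, pm$Kb, pm$Kc, pm$R_in, pm$L_in, pm$R_out, pm$L_out,
                  pm$suction_threshold, pm$suction_gain, p$speed)
  }
  v
}

#' @export
print.circulation_params <- function(x, ...) {
  cat("Closed-loop circulation parameters\n")
  cat(sprintf("  T = %.3g s, TBV = %.4g mL, pump: %s\n", x$T, x$TBV,
              if (is.null(x$pump)) "none"
              else sprintf("%s @ %g rpm", x$pump$name, x$speed)))
  for (ch in x$chambers)
    cat(sprintf("  %-3s Emax %-6.3g Emin %-6.3g V0 %g\n", ch$name, ch$Emax,
                ch$Emin, ch$V0))
  for (sg in x$segments)
    cat(sprintf("  %-3s R %-8.4g C %-6.3g L %g\n", sg$name, sg$R, sg$C,
                sg$L))
  invisible(x)
}
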
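# Parameter registry, validation, unit conversion and nondimensionalisation.
#
# Internal unit system: lengths m, time s, pressure Pa.  Concentrations are
# carried normalised by the reference scales of `reference_scales()`:
# vascular/extracellular by 0.001 ug/mm^3 (= 1 ug/ml = 1 ng/mm^3),
# intracellular by 1 ng/(1e5 cells).  Cell density is carried in units of
# 1e5 cells/mm^3 (so the default initial density is 10), because the
# transmembrane rates V1/V2 and the logistic saturation b are tabulated per
# 1e5 cells.

MMHG_TO_PA <- 133.322

.param_defaults <- function() {
  list(
    ## geometry
    R_C_um  = 100,       # vessel radius (um)
    R_T_um  = 1200,      # interstitium outer radius (um)
    L_cm    = 1,         # domain length (cm)
    ## blood
    rho     = 1000,      # blood density (kg/m^3)
    mu      = 0.004,     # blood viscosity (Pa s)
    ## wall / tissue hydraulics (upper ends of the literature ranges: the
    ## reported orders of magnitude for J_F and interstitial Pe are only
    ## attained near the upper end)
    L_p      = 2.8e-6,   # vascular hydraulic conductivity (cm/(mmHg s))
    K_tissue = 2.0e-7,   # tissue hydraulic conductivity (cm^2/(mmHg s))
    P_A     = 15,        # inlet pressure (mmHg)
    P_V     = 0,         # outlet pressure (mmHg)
    P_0     = 0,         # ambient interstitial pressure (mmHg)
    ## drug transport (doxorubicin)
    D_E     = 1.5778e-6, # interstitial diffusivity (cm^2/s)
    D_v     = 1.5778e-6, # vascular diffusivity (cm^2/s); defaults to D_E
    P_wall  = 2.778e-4,  # diffusive wall permeability (cm/s)
    V1      = 0.28,      # max influx rate (ng/(1e5 cells)/min)
    V2      = 0.28,      # max efflux rate (ng/(1e5 cells)/min)
    k1      = 0.219,     # Michaelis constant, extracellular (ug/ml)
    k2      = 1.37,      # Michaelis constant, intracellular (ng/(1e5 cells))
    sigma_f = 0,         # osmotic reflection coefficient for solute
    ## cell density
    c_t0    = 1e6,       # initial cell density (cells/mm^3)
    a1      = 0.5,       # growth rate (1/day)
    a2      = 0.24,      # natural decay rate (1/day)
    b       = 0.02592,   # logistic saturation (mm^3/(1e5 cells)/day)
    ## bistable switch
    Vf      = 27,        # (1/hr)
    Vr      = 0.459,     # (1/hr)
    Km1     = 100,
    Km2     = 0.01,
    kfb     = 2.927,     # feedback strength (1/hr)
    p       = 0.7,       # basal level
    q       = 0.3,       # input coupling (per ng/(1e5 cells))
    ## monostable switch
    k_mono  = 0.432,     # response rate (1/hr)
    kh      = 1,         # Hill constant (ng/(1e5 cells))^n (literal form)
    n_hill  = 10,
    ## downstream trigger R1
    kf      = 3.6,       # activation (1/hr)
    kr      = 0.144,     # degradation (1/hr)
    R1_th   = 0.9,       # apoptosis threshold
    ## pulse
    pulse_S   = 1,       # normalised inlet intensity
    pulse_T_h = 1.5,     # infusion time (h)
    switch_kind = "bistable",
    hill_denominator = "literal"
  )
}

.numerics_defaults <- function() {
  list(nr_i = 240, nz = 100, refinement = 3, dt_s = 10, t_end_h = 10,
       output_every_s = 1800)
}

#' Construct a validated model parameter set
#'
#' Builds the full parameter registry for a run, starting from the built-in
#' doxorubicin/tumour defaults and overriding any named field.  All physical
#' magnitudes are in the tabulated laboratory units (see the field comments
#' in the package source and the methods vignette); conversion to the
#' coherent internal system is done by [to_internal_units()].
#'
#' @param ... named overrides of default fields (e.g. `pulse_T_h = 4`).
#'   Unknown names are an error, not a warning: a silently ignored typo
#'   would corrupt an experiment.
#' @return An object of class `tds_params` (a named list).
#' @examples
#' p <- model_parameters(pulse_S = 0.5, pulse_T_h = 4)
#' p$pulse_S
#' @export
model_parameters <- function(...) {
  defs <- .param_defaults()
  ov <- list(...)
  if (length(ov) && (is.null(names(ov)) || any(names(ov) == "")))
    stop("all overrides must be named")
  unknown <- setdiff(names(ov), names(defs))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  defs[names(ov)] <- ov
  validate_parameters(defs)
  structure(defs, class = "tds_params")
}

#' @keywords internal
validate_parameters <- function(p) {
  chk_pos <- function(nm) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a positive finite number")
  }
  for (nm in c("R_C_um", "R_T_um", "L_cm", "rho", "mu", "K_tissue",
               "D_E", "D_v", "k1", "k2", "c_t0",
               "a1", "a2", "b", "Vf", "Vr", "Km1", "Km2", "kfb",
               "k_mono", "kh", "kf", "kr", "pulse_T_h"))
    chk_pos(nm)
  # zero is admissible for wall conductances and exchange rates (decoupled
  # limits used in verification runs)
  for (nm in c("L_p", "P_wall", "V1", "V2")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] < 0)
      stop("parameter '", nm, "' must be a non-negative finite number")
  }
  if (p$R_T_um <= p$R_C_um)
    stop("parameter 'R_T_um' must exceed R_C_um (interstitium outside vessel)")
  if (p$P_A <= p$P_V)
    stop("parameter 'P_A' must exceed P_V (flow direction)")
  if (p$sigma_f < 0 || p$sigma_f > 1)
    stop("parameter 'sigma_f' must lie in [0, 1]")
  if (p$R1_th <= 0 || p$R1_th >= 1)
    stop("parameter 'R1_th' must lie in (0, 1)")
  if (p$n_hill < 1) stop("parameter 'n_hill' must be >= 1")
  if (p$pulse_S < 0) stop("parameter 'pulse_S' must be >= 0")
  if (!p$switch_kind %in% c("bistable", "monostable"))
    stop("parameter 'switch_kind' must be 'bistable' or 'monostable'")
  if (!p$hill_denominator %in% c("literal", "homogeneous"))
    stop("parameter 'hill_denominator' must be 'literal' or 'homogeneous'")
  invisible(p)
}

#' Load a run configuration from a YAML file
#'
#' The file is a flat mapping of parameter keys (named exactly as in
#' [model_parameters()]) plus an optional `numerics:` section with keys
#' `nr_i`, `nz`, `refinement`, `dt_s`, `t_end_h`, `output_every_s`.
#' Missing keys take the package defaults; unknown keys are rejected.
#'
#' @param path path to a YAML configuration file.
#' @return A list with elements `params` (class `tds_params`) and
#'   `numerics` (named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping")
  num <- raw$numerics
  raw$numerics <- NULL
  ndef <- .numerics_defaults()
  if (!is.null(num)) {
    unknown <- setdiff(names(num), names(ndef))
    if (length(unknown))
      stop("unknown numerics key(s): ", paste(unknown, collapse = ", "))
    ndef[names(num)] <- num
  }
  params <- do.call(model_parameters, raw)
  list(params = params, numerics = ndef)
}

#' Reference scales used to nondimensionalise concentrations
#'
#' Vascular and extracellular drug concentrations are normalised by
#' 0.001 ug/mm^3 (equivalently 1 ug/ml), intracellular concentration by
#' 1 ng/(1e5 cells), and cell density by 1e6 cells/mm^3.
#'
#' @return named list `c_ref_vE` (ug/mm^3), `c_ref_I` (ng/(1e5 cells)),
#'   `c_ref_t` (cells/mm^3).
#' @export
reference_scales <- function() {
  list(c_ref_vE = 0.001, c_ref_I = 1, c_ref_t = 1e6)
}

#' Normalise a physical concentration by its reference scale
#'
#' @param value physical value: ug/mm^3 for compartments `"vE"`,
#'   ng/(1e5 cells) for `"I"`, cells/mm^3 for `"t"`.
#' @param compartment one of `"vE"`, `"I"`, `"t"`.
#' @param scales reference scales, see [reference_scales()].
#' @return dimensionless value.
#' @export
normalize_conc <- function(value, compartment, scales = reference_scales()) {
  s <- switch(compartment,
              vE = scales$c_ref_vE, I = scales$c_ref_I, t = scales$c_ref_t,
              stop("unknown compartment tag: ", compartment))
  if (s <= 0) stop("reference scale must be positive")
  value / s
}

#' @rdname normalize_conc
#' @export
denormalize_conc <- function(value, compartment, scales = reference_scales()) {
  s <- switch(compartment,
              vE = scales$c_ref_vE, I = scales$c_ref_I, t = scales$c_ref_t,
              stop("unknown compartment tag: ", compartment))
  value * s
}

#' Convert a parameter set to the coherent internal unit system
#'
#' Lengths to m, times to s, pressures to Pa (1 mmHg = 133.322 Pa),
#' diffusivities to m^2/s, conductivities to m/(Pa s) and m^2/(Pa s).
#' Concentration-like constants are expressed in the normalised system:
#' k1 in units of the vascular/extracellular reference (1 ug/ml), k2 and kh
#' in units of the intracellular reference (1 ng/1e5 cells), cell density in
#' 1e5 cells/mm^3.  All kinetic rates become 1/s.
#'
#' @param p a `tds_params` object.
#' @param scales reference scales.
#' @return object of class `tds_internal` (named list).
#' @export
to_internal_units <- function(p, scales = reference_scales()) {
  stopifnot(inherits(p, "tds_params"))
  ref_vE_ugml <- scales$c_ref_vE * 1000   # ug/mm^3 -> ug/ml (1 ml = 1000 mm^3)
  ip <- list(
    R_C = p$R_C_um * 1e-6,
    R_T = p$R_T_um * 1e-6,
    L   = p$L_cm * 0.01,
    rho = p$rho,
    mu  = p$mu,
    L_p = p$L_p * 0.01 / MMHG_TO_PA,        # cm/(mmHg s) -> m/(Pa s)
    K   = p$K_tissue * 1e-4 / MMHG_TO_PA,   # cm^2/(mmHg s) -> m^2/(Pa s)
    P_A = p$P_A * MMHG_TO_PA,
    P_V = p$P_V * MMHG_TO_PA,
    P_0 = p$P_0 * MMHG_TO_PA,
    D_E = p$D_E * 1e-4,
    D_v = p$D_v * 1e-4,
    P_wall = p$P_wall * 0.01,
    V1 = p$V1 / 60 / scales$c_ref_I,        # ng/(1e5 cells)/min -> ref_I/s
    V2 = p$V2 / 60 / scales$c_ref_I,
    k1 = p$k1 / ref_vE_ugml,                # ug/ml -> vascular reference units
    k2 = p$k2 / scales$c_ref_I,
    sigma_f = p$sigma_f,
    # cell density carried in 1e5 cells/mm^3
    c_t0 = p$c_t0 / 1e5,
    a1 = p$a1 / 86400,
    a2 = p$a2 / 86400,
    b  = p$b / 86400,                       # per (1e5 cells/mm^3) per s
    Vf = p$Vf / 3600, Vr = p$Vr / 3600,
    Km1 = p$Km1, Km2 = p$Km2,
    kfb = p$kfb / 3600,
    p_basal = p$p,
    q = p$q * scales$c_ref_I,               # per ref_I unit of normalised c_I
    k_mono = p$k_mono / 3600,
    kh = p$kh / scales$c_ref_I^p$n_hill,    # literal form: kh + c_I^n
    n_hill = p$n_hill,
    kf = p$kf / 3600, kr = p$kr / 3600,
    R1_th = p$R1_th,
    pulse_S = p$pulse_S,
    pulse_T = p$pulse_T_h * 3600,
    switch_kind = p$switch_kind,
    hill_denominator = p$hill_denominator,
    # conversion: cellular uptake c_t[1e5/mm^3] * V[ng/1e5/s] is ng/(mm^3 s);
    # the vascular/extracellular reference is scales$c_ref_vE*1000 ng/mm^3.
    uptake_conv = scales$c_ref_I / (scales$c_ref_vE * 1000)
  )
  structure(ip, class = "tds_internal", scales = scales)
}

#' Convert internal parameters back to the tabulated laboratory units
#'
#' Inverse of [to_internal_units()]; round-trip recovers inputs to ten
#' significant digits.
#'
#' @param ip a `tds_internal` object.
#' @return a `tds_params` object.
#' @export
to_model_units <- function(ip) {
  stopifnot(inherits(ip, "tds_internal"))
  scales <- attr(ip, "scales")
  ref_vE_ugml <- scales$c_ref_vE * 1000
  model_parameters(
    R_C_um = ip$R_C / 1e-6, R_T_um = ip$R_T / 1e-6, L_cm = ip$L / 0.01,
    rho = ip$rho, mu = ip$mu,
    L_p = ip$L_p * MMHG_TO_PA / 0.01,
    K_tissue = ip$K * MMHG_TO_PA / 1e-4,
    P_A = ip$P_A / MMHG_TO_PA, P_V = ip$P_V / MMHG_TO_PA,
    P_0 = ip$P_0 / MMHG_TO_PA,
    D_E = ip$D_E / 1e-4, D_v = ip$D_v / 1e-4,
    P_wall = ip$P_wall / 0.01,
    V1 = ip$V1 * 60 * scales$c_ref_I, V2 = ip$V2 * 60 * scales$c_ref_I,
    k1 = ip$k1 * ref_vE_ugml, k2 = ip$k2 * scales$c_ref_I,
    sigma_f = ip$sigma_f,
    c_t0 = ip$c_t0 * 1e5,
    a1 = ip$a1 * 86400, a2 = ip$a2 * 86400, b = ip$b * 86400,
    Vf = ip$Vf * 3600, Vr = ip$Vr * 3600, Km1 = ip$Km1, Km2 = ip$Km2,
    kfb = ip$kfb * 3600, p = ip$p_basal, q = ip$q / scales$c_ref_I,
    k_mono = ip$k_mono * 3600, kh = ip$kh * scales$c_ref_I^ip$n_hill,
    n_hill = ip$n_hill,
    kf = ip$kf * 3600, kr = ip$kr * 3600, R1_th = ip$R1_th,
    pulse_S = ip$pulse_S, pulse_T_h = ip$pulse_T / 3600,
    switch_kind = ip$switch_kind, hill_denominator = ip$hill_denominator
  )
}

#' @method print tds_params
#' @export
print.tds_params <- function(x, ...) {
  cat("<tds_params> tumour/drug parameter set\n")
  cat("  geometry: R_C =", x$R_C_um, "um, R_T =", x$R_T_um, "um, L =",
      x$L_cm, "cm\n")
  cat("  pulse: S =", x$pulse_S, ", T =", x$pulse_T_h, "h; switch:",
      x$switch_kind, "\n")
  cat("  (", length(unclass(x)), "fields; see model_parameters() )\n")
  invisible(x)
}

#' @method print tds_internal
#' @export
print.tds_internal <- function(x, ...) {
  cat("<tds_internal> parameters in SI / normalised units\n")
  cat("  D_E =", x$D_E, "m^2/s, P_wall =", x$P_wall, "m/s, L_p =",
      x$L_p, "m/(Pa s)\n")
  invisible(x)
}
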
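#' Model parameter registry
#'
#' Constructs the full constant set used to model an amphibian skeletal
#' muscle fibre and its sarcoplasmic reticulum (SR), in SI units throughout
#' (m, s, F m^-2, mol m^-3; note mol m^-3 is numerically identical to mM).
#' The defaults are the established literature values for amphibian twitch
#' fibres: fibre and sarcomere geometry, tubular membrane capacitance ratio,
#' SR volume fraction, free Ca2+ diffusivity, calsequestrin concentration and
#' affinity, and the boundary flux densities for ryanodine-receptor (RyR)
#' release and background SERCA uptake.
#'
#' Flux densities are signed so that positive flux adds Ca2+ to the SR lumen:
#' the release efflux is negative, the SERCA influx positive.
#'
#' @param ... named overrides of any default field (see Fields below).
#' @param use_formula_tubular_area logical; if `TRUE` the sarcomere tubular
#'   membrane area A_T is recomputed as (C_T/C_S) * pi * a * l rather than
#'   taken from the tabulated value. The tabulated area (5,733 um^2) differs
#'   from the formula value (5,655 um^2) by about 1.4%; downstream tabulated
#'   fluxes were derived from the tabulated area, which is therefore the
#'   default.
#'
#' @section Fields:
#' \describe{
#'   \item{sarcomere_length}{l, m (default 3.6e-6)}
#'   \item{fiber_diameter}{a, m (default 100e-6)}
#'   \item{surface_capacitance}{C_S, F m^-2 (default 1.00e-2)}
#'   \item{tubular_capacitance}{C_T, F m^-2 (default 5.00e-2)}
#'   \item{tubular_area}{A_T, m^2 (default 5.733e-9, tabulated)}
#'   \item{junction_fraction}{xi, fraction of tubular membrane at triad
#'     junctions (default 0.3)}
#'   \item{junctional_area}{A_TSR, m^2 (default 1.720e-9, tabulated; equals
#'     xi * A_T at the tabulated rounding and is the default area in the
#'     boundary-flux derivations, whose tabulated results were computed
#'     from it)}
#'   \item{sr_volume_fraction}{V_SR*, SR/fibre volume ratio (default 0.12)}
#'   \item{element_diameter}{a_dSR, diameter of one SR element, m
#'     (default 3.00e-8)}
#'   \item{D_ca}{free Ca2+ diffusion coefficient, m^2 s^-1 (default 3e-10)}
#'   \item{D_casq}{calsequestrin diffusion coefficient, m^2 s^-1 (fixed 0;
#'     calsequestrin is anchored, not mobile)}
#'   \item{casq_total}{total calsequestrin, mol m^-3 (default 6.1)}
#'   \item{ca_free_initial}{resting free SR Ca2+, mol m^-3 (default 3.6)}
#'   \item{Kd}{calsequestrin Ca2+ affinity, mol m^-3 (default 1.1)}
#'   \item{J_efflux_0}{initial RyR release efflux density, mol m^-2 s^-1,
#'     negative (default -2.7375e-6)}
#'   \item{J_serca_influx}{SERCA influx density on the lateral face,
#'     mol m^-2 s^-1 (default 3.688e-10)}
#'   \item{ca_cyt}{cytosolic free Ca2+, mol m^-3, treated as ~0 relative to
#'     luminal levels (default 0)}
#' }
#'
#' @return An object of class `sr_parameters` (a validated named list).
#' @examples
#' p <- sr_parameters()
#' p$ca_free_initial    # 3.6 mol m^-3 (= 3.6 mM)
#' sr_parameters(Kd = 0.8)$Kd
#' @seealso [sr_derived()], [load_parameters()], [parameter_table()]
#' @export
sr_parameters <- function(..., use_formula_tubular_area = FALSE) {
  p <- list(
    sarcomere_length    = 3.6e-6,
    fiber_diameter      = 100e-6,
    surface_capacitance = 1.00e-2,
    tubular_capacitance = 5.00e-2,
    tubular_area        = 5.733e-9,
    junction_fraction   = 0.3,
    junctional_area     = 1.720e-9,
    sr_volume_fraction  = 0.12,
    element_diameter    = 3.00e-8,
    D_ca                = 3e-10,
    D_casq              = 0,
    casq_total          = 6.1,
    ca_free_initial     = 3.6,
    Kd                  = 1.1,
    J_efflux_0          = -2.7375e-6,
    J_serca_influx      = 3.688e-10,
    ca_cyt              = 0
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  p$use_formula_tubular_area <- isTRUE(use_formula_tubular_area)
  if (p$use_formula_tubular_area)
    p$tubular_area <- (p$tubular_capacitance / p$surface_capacitance) *
      pi * p$fiber_diameter * p$sarcomere_length
  class(p) <- "sr_parameters"
  validate_parameters(p)
  p
}

validate_parameters <- function(p) {
  pos <- c("sarcomere_length", "fiber_diameter", "surface_capacitance",
           "tubular_capacitance", "tubular_area", "junctional_area",
           "element_diameter", "D_ca", "casq_total", "ca_free_initial",
           "Kd")
  for (f in pos)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) ||
        p[[f]] <= 0)
      stop("parameter '", f, "' must be a single positive finite number")
  if (p$D_casq != 0)
    stop("D_casq is fixed at 0 (anchored calsequestrin)")
  if (p$junction_fraction <= 0 || p$junction_fraction >= 1)
    stop("junction_fraction must lie in (0, 1)")
  if (p$sr_volume_fraction <= 0 || p$sr_volume_fraction >= 1)
    stop("sr_volume_fraction must lie in (0, 1)")
  if (p$J_efflux_0 >= 0)
    stop("J_efflux_0 must be negative (Ca2+ leaves the SR)")
  if (p$J_serca_influx < 0)
    stop("J_serca_influx must be >= 0")
  if (p$ca_cyt < 0) stop("ca_cyt must be >= 0")
  invisible(p)
}

#' @export
print.sr_parameters <- function(x, ...) {
  cat("SR model parameters (SI units)\n")
  tab <- parameter_table(x)
  print(tab, row.names = FALSE, ...)
  invisible(x)
}

# Symbol-name aliases accepted in config files (Table-style symbols).
.parameter_symbols <- c(
  l = "sarcomere_length", a = "fiber_diameter",
  C_S = "surface_capacitance", C_T = "tubular_capacitance",
  A_T = "tubular_area", xi = "junction_fraction",
  A_TSR = "junctional_area",
  V_SR = "sr_volume_fraction", a_dSR = "element_diameter",
  D_Ca = "D_ca", D_Casq = "D_casq", Casq_total = "casq_total",
  Ca_free_0 = "ca_free_initial", K_d = "Kd",
  J_efflux_0 = "J_efflux_0", J_SERCA = "J_serca_influx",
  Ca_cyt = "ca_cyt"
)

#' Load parameter overrides from a flat YAML config file
#'
#' Reads a flat key--value YAML file whose keys are either the symbol names
#' of the tabulated constants (`l`, `a`, `C_S`, `C_T`, `A_T`, `xi`, `V_SR`,
#' `a_dSR`, `D_Ca`, `D_Casq`, `Casq_total`, `Ca_free_0`, `K_d`,
#' `J_efflux_0`, `J_SERCA`, `Ca_cyt`) or the field names of
#' [sr_parameters()]. Values are in SI units. Unknown keys are an error.
#'
#' @param path path to a YAML file.
#' @param base an `sr_parameters` object supplying defaults for keys absent
#'   from the file.
#' @return An `sr_parameters` object.
#' @export
load_parameters <- function(path, base = sr_parameters()) {
  stopifnot(inherits(base, "sr_parameters"))
  cfg <- yaml::read_yaml(path)
  if (length(cfg) == 0L) return(base)
  if (is.null(names(cfg)) || any(!nzchar(names(cfg))))
    stop("config entries must be 'key: value' pairs")
  keys <- names(cfg)
  mapped <- ifelse(keys %in% names(.parameter_symbols),
                   .parameter_symbols[keys], keys)
  known <- setdiff(names(unclass(base)), "use_formula_tubular_area")
  unknown <- keys[!(mapped %in% known)]
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  p <- unclass(base)
  for (i in seq_along(cfg)) p[[mapped[i]]] <- as.numeric(cfg[[i]])
  class(p) <- "sr_parameters"
  validate_parameters(p)
  p
}

#' Derived geometric and flux quantities
#'
#' Computes every quantity derived from the primary constants: the sarcomere
#' tubular membrane area A_T, the junctional area A_TSR = xi * A_T, the
#' equivalent lumped-SR diameter a_SR = a * sqrt(V_SR*) and its
#' cross-sectional area A_SR = pi * a_SR^2 / 4, the number of SR elements
#' n ~ (a_SR / a_dSR)^2, and the initial total Ca2+ concentration implied by
#' the buffer equilibrium.
#'
#' @param p an [sr_parameters()] object.
#' @return A named list of class `sr_derived`.
#' @examples
#' d <- sr_derived(sr_parameters())
#' d$junctional_area * 1e12   # 1720 um^2
#' @export
sr_derived <- function(p = sr_parameters()) {
  stopifnot(inherits(p, "sr_parameters"))
  areas <- tubular_areas(p)
  a_sr <- equivalent_sr_diameter(p)
  out <- list(
    tubular_area      = areas[["A_T"]],
    junctional_area   = areas[["A_TSR"]],
    lumped_sr_diameter = a_sr,
    lumped_sr_cross_section = pi * a_sr^2 / 4,
    element_count     = (a_sr / p$element_diameter)^2,
    ca_total_initial  = ca_total_from_free(p$ca_free_initial,
                                           p$casq_total, p$Kd)
  )
  class(out) <- "sr_derived"
  out
}

#' @export
print.sr_derived <- function(x, ...) {
  cat("Derived SR quantities:\n")
  cat(sprintf("  A_T    = %.4g m^2\n", x$tubular_area))
  cat(sprintf("  A_TSR  = %.4g m^2\n", x$junctional_area))
  cat(sprintf("  a_SR   = %.4g m\n", x$lumped_sr_diameter))
  cat(sprintf("  A_SR   = %.4g m^2\n", x$lumped_sr_cross_section))
  cat(sprintf("  n      = %.4g elements\n", x$element_count))
  cat(sprintf("  [Ca]total(0) = %.4f mol m^-3\n", x$ca_total_initial))
  invisible(x)
}

#' Sarcomere tubular and junctional membrane areas
#'
#' A_T is the tabulated sarcomere tubular membrane area (or the capacitance
#' formula (C_T/C_S) * pi * a * l if the parameter set was built with
#' `use_formula_tubular_area = TRUE`); A_TSR = xi * A_T is the part of it
#' apposed to triad (T--SR) junctions.
#'
#' @param p an [sr_parameters()] object.
#' @return Named numeric vector `c(A_T = , A_TSR = )` in m^2.
#' @export
tubular_areas <- function(p = sr_parameters()) {
  stopifnot(inherits(p, "sr_parameters"))
  A_T <- p$tubular_area
  c(A_T = A_T, A_TSR = p$junction_fraction * A_T)
}

#' Equivalent diameter of the lumped SR cylinder
#'
#' All SR elements of a half sarcomere are lumped into one cylinder whose
#' cross-section carries the SR volume fraction: a_SR = a * sqrt(V_SR*).
#'
#' @param p an [sr_parameters()] object.
#' @return Diameter in m.
#' @export
equivalent_sr_diameter <- function(p = sr_parameters()) {
  stopifnot(inherits(p, "sr_parameters"))
  p$fiber_diameter * sqrt(p$sr_volume_fraction)
}

#' Initial RyR release efflux density of one SR element
#'
#' Maps the whole-sarcomere T--SR junctional flux density J_TSR(0) to the
#' per-element cisternal efflux density,
#' J_efflux(0) = 2 * J_TSR(0) * A_TSR / (pi * a^2 * V_SR*).
#' The result carries the sign of `J_tsr_0` (negative = Ca2+ leaving the SR).
#' With the reference J_TSR(0) = -3.0e-6 mol m^-2 s^-1 and the tabulated
#' A_TSR this reproduces the tabulated J_efflux(0) = -2.7375e-6 mol m^-2 s^-1.
#'
#' @param J_tsr_0 junctional flux density at t = 0, mol m^-2 s^-1 (signed).
#' @param p an [sr_parameters()] object.
#' @param A_tsr junctional membrane area, m^2; defaults to the tabulated
#'   `p$junctional_area`.
#' @return Efflux density in mol m^-2 s^-1, linear in both `J_tsr_0` and
#'   `A_tsr`.
#' @export
initial_efflux_density <- function(J_tsr_0, p = sr_parameters(),
                                   A_tsr = p$junctional_area) {
  stopifnot(inherits(p, "sr_parameters"), is.numeric(J_tsr_0),
            is.numeric(A_tsr), A_tsr >= 0)
  2 * J_tsr_0 * A_tsr / (pi * p$fiber_diameter^2 * p$sr_volume_fraction)
}

#' SERCA-mediated influx density on the lateral SR membrane
#'
#' Distributes the steady background T--SR uptake flux over the lateral
#' membrane of the n SR elements:
#' J_influx = J_TSR(inf) * A_TSR * a_dSR / (a^2 * V_SR* * pi * l),
#' a constant density on face F3.
#'
#' @param J_tsr_inf steady background junctional flux density,
#'   mol m^-2 s^-1 (positive into the SR).
#' @param p an [sr_parameters()] object.
#' @param A_tsr junctional membrane area, m^2; defaults to the tabulated
#'   `p$junctional_area`.
#' @return Influx density in mol m^-2 s^-1. With the tabulated inputs
#'   (J_TSR(inf) = 9.70e-8 mol m^-2 s^-1) this gives 3.6880e-10
#'   mol m^-2 s^-1 (= 3.6880e-28 mol nm^-2 s^-1).
#' @export
serca_influx_density <- function(J_tsr_inf, p = sr_parameters(),
                                 A_tsr = p$junctional_area) {
  stopifnot(inherits(p, "sr_parameters"), is.numeric(J_tsr_inf),
            is.numeric(A_tsr), A_tsr >= 0)
  J_tsr_inf * A_tsr * p$element_diameter /
    (p$fiber_diameter^2 * p$sr_volume_fraction * pi * p$sarcomere_length)
}

# Unit conversion factors SI -> physiological display units, per field.
.display_units <- data.frame(
  field = c("sarcomere_length", "fiber_diameter", "surface_capacitance",
            "tubular_capacitance", "tubular_area", "junction_fraction",
            "junctional_area", "sr_volume_fraction", "element_diameter",
            "D_ca", "D_casq", "casq_total", "ca_free_initial", "Kd",
            "J_efflux_0", "J_serca_influx", "ca_cyt"),
  symbol = c("l", "a", "C_S", "C_T", "A_T", "xi", "A_TSR", "V_SR",
             "a_dSR", "D_Ca", "D_Casq", "Casq_total", "Ca_free_0", "K_d",
             "J_efflux_0", "J_SERCA", "Ca_cyt"),
  unit_si = c("m", "m", "F m-2", "F m-2", "m2", "-", "m2", "-", "m",
              "m2 s-1", "m2 s-1", "mol m-3", "mol m-3", "mol m-3",
              "mol m-2 s-1", "mol m-2 s-1", "mol m-3"),
  unit_phys = c("um", "um", "uF cm-2", "uF cm-2", "um2", "-", "um2", "-",
                "um", "cm2 s-1", "cm2 s-1", "mM", "mM", "uM",
                "mol nm-2 s-1", "mol nm-2 s-1", "mM"),
  si_to_phys = c(1e6, 1e6, 1e2, 1e2, 1e12, 1, 1e12, 1, 1e6, 1e4, 1e4,
                 1, 1, 1e3, 1e-18, 1e-18, 1),
  stringsAsFactors = FALSE
)

#' Tabulate the resolved parameter set with units
#'
#' Emits the full parameter registry as a data frame with both SI and
#' physiological display columns (the two columns are exact unit
#' conversions of one another).
#'
#' @param p an [sr_parameters()] object.
#' @param derived logical; append the derived quantities of [sr_derived()].
#' @return A data frame with columns `symbol`, `field`, `value_si`,
#'   `unit_si`, `value_phys`, `unit_phys`.
#' @export
parameter_table <- function(p = sr_parameters(), derived = FALSE) {
  stopifnot(inherits(p, "sr_parameters"))
  u <- .display_units
  tab <- data.frame(
    symbol = u$symbol, field = u$field,
    value_si = vapply(u$field, function(f) p[[f]], numeric(1)),
    unit_si = u$unit_si,
    value_phys = vapply(seq_len(nrow(u)), function(i)
      p[[u$field[i]]] * u$si_to_phys[i], numeric(1)),
    unit_phys = u$unit_phys,
    stringsAsFactors = FALSE
  )
  if (derived) {
    d <- sr_derived(p)
    tab <- rbind(tab, data.frame(
      symbol = c("xi*A_T", "a_SR", "A_SR", "n", "Ca_total_0"),
      field = c("junctional_area", "lumped_sr_diameter",
                "lumped_sr_cross_section", "element_count",
                "ca_total_initial"),
      value_si = c(d$junctional_area, d$lumped_sr_diameter,
                   d$lumped_sr_cross_section, d$element_count,
                   d$ca_total_initial),
      unit_si = c("m2", "m", "m2", "-", "mol m-3"),
      value_phys = c(d$junctional_area * 1e12, d$lumped_sr_diameter * 1e6,
                     d$lumped_sr_cross_section * 1e12, d$element_count,
                     d$ca_total_initial),
      unit_phys = c("um2", "um", "um2", "-", "mM"),
      stringsAsFactors = FALSE
    ))
  }
  rownames(tab) <- NULL
  tab
}

#' Convert a tabulated value between SI and physiological display units
#'
#' @param value numeric value(s).
#' @param field one of the field names of [sr_parameters()].
#' @param to `"phys"` (SI -> display) or `"si"` (display -> SI).
#' @return Converted numeric value(s); the two directions are exact
#'   inverses.
#' @export
convert_units <- function(value, field, to = c("phys", "si")) {
  to <- match.arg(to)
  i <- match(field, .display_units$field)
  if (is.na(i)) stop("unknown field: ", field)
  f <- .display_units$si_to_phys[i]
  if (to == "phys") value * f else value / f
}
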
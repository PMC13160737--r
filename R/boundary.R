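#' RyR release efflux model at the cisternal (F2) face
#'
#' Two variants of the cisternal Ca2+ release boundary flux: a constant
#' efflux held at its initial density, and the physiologically more
#' realistic depletion-proportional ("decaying") efflux whose magnitude
#' scales with the free Ca2+ concentration at the release face,
#' `J(t) = J0 * free(0, t) / free(0, 0)` (the cytosolic concentration is
#' negligible relative to luminal levels and is taken as zero).
#'
#' @param mode `"decaying"` or `"constant"`.
#' @param J0 initial efflux density, mol m^-2 s^-1, negative (Ca2+ leaves
#'   the SR); 0 is allowed and represents a shut release channel.
#' @param reference_free_ca free Ca2+ at the F2 face at t = 0, mol m^-3
#'   (> 0); the normalisation of the decaying mode.
#' @return An object of class `sr_efflux_model`.
#' @export
efflux_model <- function(mode = c("decaying", "constant"),
                         J0 = -2.7375e-6, reference_free_ca = 3.6) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(J0), length(J0) == 1L, J0 <= 0,
            is.numeric(reference_free_ca), length(reference_free_ca) == 1L,
            reference_free_ca > 0)
  structure(list(mode = mode, J0 = J0,
                 reference_free_ca = reference_free_ca),
            class = "sr_efflux_model")
}

#' SERCA influx model at the lateral (F3) face
#'
#' A constant background influx density on the lateral membrane,
#' representing steady SERCA-mediated re-uptake; zero when disabled.
#'
#' @param enabled logical.
#' @param J_in influx density, mol m^-2 s^-1 (>= 0).
#' @return An object of class `sr_influx_model`.
#' @export
influx_model <- function(enabled = TRUE, J_in = 3.688e-10) {
  stopifnot(is.logical(enabled), length(enabled) == 1L,
            is.numeric(J_in), length(J_in) == 1L, J_in >= 0)
  structure(list(enabled = enabled, J_in = J_in),
            class = "sr_influx_model")
}

#' Evaluate the release efflux density
#'
#' @param model an [efflux_model()].
#' @param t time, s (unused by either mode; kept for the boundary-condition
#'   interface).
#' @param free_ca_at_F2 area-averaged free Ca2+ at the F2 face, mol m^-3
#'   (>= 0); required in decaying mode.
#' @return Signed flux density, mol m^-2 s^-1 (negative = leaving the SR);
#'   in decaying mode the magnitude shrinks linearly with the face free
#'   Ca2+.
#' @export
efflux_density <- function(model, t = 0, free_ca_at_F2 = NULL) {
  stopifnot(inherits(model, "sr_efflux_model"))
  if (model$mode == "constant") return(model$J0)
  if (is.null(free_ca_at_F2))
    stop("decaying efflux requires the F2 free Ca2+ concentration")
  if (any(free_ca_at_F2 < 0))
    stop("free Ca2+ concentration must be >= 0")
  model$J0 * free_ca_at_F2 / model$reference_free_ca
}

#' Evaluate the SERCA influx density
#'
#' @param model an [influx_model()].
#' @return Flux density, mol m^-2 s^-1; 0 when the model is disabled.
#' @export
influx_density <- function(model) {
  stopifnot(inherits(model, "sr_influx_model"))
  if (model$enabled) model$J_in else 0
}

#' Integrated molar boundary rates of one SR element
#'
#' Converts the face flux densities to molar rates for mass auditing:
#' the release rate out through F2 (`|J_efflux| * pi r^2`) and the SERCA
#' uptake rate in through F3 (`J_influx * 2 pi r L`).
#'
#' @param efflux an [efflux_model()].
#' @param influx an [influx_model()].
#' @param geometry an [sr_geometry()].
#' @param free_ca_at_F2 face free Ca2+, mol m^-3 (decaying mode).
#' @return Named numeric vector `c(out = , inn = )`, mol s^-1 (both >= 0).
#' @export
molar_rates <- function(efflux, influx, geometry = sr_geometry(),
                        free_ca_at_F2 = efflux$reference_free_ca) {
  stopifnot(inherits(geometry, "sr_geometry"))
  J_out <- efflux_density(efflux, free_ca_at_F2 = free_ca_at_F2)
  c(out = abs(J_out) * geometry$area_F2,
    inn = influx_density(influx) * geometry$area_F3)
}
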
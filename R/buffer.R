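#' Total Ca2+ from free Ca2+ at calsequestrin binding equilibrium
#'
#' Closed form of the 1:1 mass-action equilibrium,
#' `total = free * (casq_total + free + Kd) / (Kd + free)`.
#' With the resting amphibian values (free 3.6, casq 6.1, Kd 1.1 mol m^-3)
#' this gives 8.2723 mol m^-3.
#'
#' All buffer-algebra functions are vectorized and recycle their arguments.
#'
#' @param ca_free free Ca2+ concentration, mol m^-3 (>= 0).
#' @param casq_total total calsequestrin concentration, mol m^-3 (>= 0).
#' @param Kd calsequestrin dissociation constant, mol m^-3 (> 0).
#' @return Total Ca2+ concentration, mol m^-3.
#' @examples
#' ca_total_from_free(3.6, 6.1, 1.1)   # 8.2723
#' @export
ca_total_from_free <- function(ca_free, casq_total, Kd) {
  check_buffer_args(ca_free, casq_total, Kd)
  ca_free * (casq_total + ca_free + Kd) / (Kd + ca_free)
}

#' Calsequestrin-bound Ca2+ from total Ca2+
#'
#' Solves the mass-action quadratic
#' `b^2 - (Kd + total + casq_total) b + total * casq_total = 0`
#' for the physical (smaller) root, so that `0 <= b <= min(total,
#' casq_total)`. Evaluated in the numerically stable product form
#' `b = 2 T Cq / (S + sqrt(S^2 - 4 T Cq))`, `S = Kd + T + Cq`, which avoids
#' cancellation at small concentrations.
#'
#' @inheritParams ca_total_from_free
#' @param ca_total total Ca2+ concentration, mol m^-3 (>= 0).
#' @return Bound Ca2+ concentration, mol m^-3.
#' @export
ca_bound_from_total <- function(ca_total, casq_total, Kd) {
  check_buffer_args(ca_total, casq_total, Kd)
  S <- Kd + ca_total + casq_total
  disc <- S^2 - 4 * ca_total * casq_total
  if (any(disc < 0))
    stop("negative discriminant in bound-Ca2+ quadratic; invalid inputs")
  2 * ca_total * casq_total / (S + sqrt(disc))
}

#' Free Ca2+ from total Ca2+
#'
#' Positive root of the equilibrium quadratic
#' `f^2 + (casq_total - total + Kd) f - Kd * total = 0`, the inverse of
#' [ca_total_from_free()]. Evaluated in a cancellation-free form.
#'
#' @inheritParams ca_bound_from_total
#' @return Free Ca2+ concentration, mol m^-3, with `0 <= free <= total`.
#' @export
ca_free_from_total <- function(ca_total, casq_total, Kd) {
  check_buffer_args(ca_total, casq_total, Kd)
  b <- casq_total - ca_total + Kd
  disc <- sqrt(b^2 + 4 * Kd * ca_total)
  # stable in both regimes: -b + disc cancels when b > 0
  ifelse(b > 0, 2 * Kd * ca_total / (b + disc), (disc - b) / 2)
}

#' Effective diffusion coefficient of total Ca2+ under rapid buffering
#'
#' Concentration-weighted average of the free-Ca2+ and (immobile)
#' bound-Ca2+ diffusivities: with D_casq = 0 this reduces to
#' `D* = D_ca * free(total) / total`, a nonlinear function of the local
#' total Ca2+. The `ca_total = 0` limit is taken continuously:
#' `D*(0) = D_ca * Kd / (Kd + casq_total)`.
#'
#' @inheritParams ca_bound_from_total
#' @param D_ca free Ca2+ diffusion coefficient, m^2 s^-1 (> 0).
#' @return Effective diffusivity in (0, D_ca]; equals `D_ca` iff
#'   `casq_total = 0`.
#' @examples
#' effective_diffusivity(8.2723, 6.1, 1.1, 3e-10)  # ~1.3056e-10
#' @export
effective_diffusivity <- function(ca_total, casq_total, Kd, D_ca) {
  check_buffer_args(ca_total, casq_total, Kd)
  if (any(D_ca <= 0)) stop("D_ca must be positive")
  n <- max(length(ca_total), length(casq_total), length(Kd), length(D_ca))
  ca_total <- rep_len(ca_total, n); casq_total <- rep_len(casq_total, n)
  Kd <- rep_len(Kd, n); D_ca <- rep_len(D_ca, n)
  out <- numeric(n)
  z <- ca_total == 0
  out[z] <- D_ca[z] * Kd[z] / (Kd[z] + casq_total[z])
  if (any(!z))
    out[!z] <- D_ca[!z] *
      ca_free_from_total(ca_total[!z], casq_total[!z], Kd[!z]) / ca_total[!z]
  out
}

#' Full buffer state at one (or several) points
#'
#' Assembles the (total, free, bound, free-calsequestrin) state from either
#' the free or the total Ca2+ concentration, at 1:1 binding equilibrium.
#'
#' @param ca_free,ca_total exactly one of the two must be supplied,
#'   mol m^-3.
#' @inheritParams ca_total_from_free
#' @return A list of class `sr_buffer_state` with components `ca_total`,
#'   `ca_free`, `casq_bound`, `casq_free`, `casq_total`, `Kd`.
#' @export
buffer_state <- function(ca_free = NULL, ca_total = NULL,
                         casq_total = 6.1, Kd = 1.1) {
  if (is.null(ca_free) == is.null(ca_total))
    stop("supply exactly one of ca_free or ca_total")
  if (is.null(ca_total)) {
    ca_total <- ca_total_from_free(ca_free, casq_total, Kd)
  } else {
    ca_free <- ca_free_from_total(ca_total, casq_total, Kd)
  }
  st <- list(ca_total = ca_total, ca_free = ca_free,
             casq_bound = ca_total - ca_free,
             casq_free = casq_total - (ca_total - ca_free),
             casq_total = casq_total, Kd = Kd)
  class(st) <- "sr_buffer_state"
  st
}

check_buffer_args <- function(ca, casq_total, Kd) {
  if (any(ca < 0)) stop("Ca2+ concentration must be >= 0")
  if (any(casq_total < 0)) stop("casq_total must be >= 0")
  if (any(Kd <= 0)) stop("Kd must be positive")
  invisible(TRUE)
}
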
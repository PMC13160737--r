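#' Simulation configuration
#'
#' Collects the run controls for [sr_simulate()]: window length, output
#' sampling, condition flags and solver tolerances. The two standard
#' windows are 0--20 ms (single-twitch timescale) and 0--2 s (tetanus
#' timescale), each sampled at 1,000 equally spaced output points; the
#' output points are sampling times only, the stiff integrator steps
#' adaptively between them.
#'
#' @param duration window length, s (e.g. `0.02` or `2`).
#' @param n_output_points number of equally spaced output times including
#'   t = 0 (default 1000).
#' @param efflux_mode `"decaying"` (release scales with cisternal free
#'   Ca2+) or `"constant"`.
#' @param serca_enabled logical; include the lateral SERCA influx.
#' @param casq_enabled logical; include calsequestrin buffering. When
#'   `FALSE` the buffer algebra is bypassed entirely: total = free and the
#'   diffusivity is the free-Ca2+ value.
#' @param operator_form `"conservative"` (div(D* grad C), mass-consistent,
#'   default) or `"nonconservative"` (D* Laplacian C, for sensitivity
#'   checks; 1D only).
#' @param rel_tol,abs_tol integrator tolerances (defaults 1e-8 and 1e-12
#'   mol m^-3).
#' @param discretization `"axial_1d"` (production) or `"axisymmetric_2d"`.
#' @param spacing 1D node spacing, m (default 1e-8).
#' @param hmax 2D maximal edge length, m (default 1e-8).
#' @return An object of class `sr_config`.
#' @export
simulation_config <- function(duration = 0.02, n_output_points = 1000L,
                              efflux_mode = c("decaying", "constant"),
                              serca_enabled = FALSE, casq_enabled = TRUE,
                              operator_form = c("conservative",
                                                "nonconservative"),
                              rel_tol = 1e-8, abs_tol = 1e-12,
                              discretization = c("axial_1d",
                                                 "axisymmetric_2d"),
                              spacing = 1e-8, hmax = 1e-8) {
  efflux_mode <- match.arg(efflux_mode)
  operator_form <- match.arg(operator_form)
  discretization <- match.arg(discretization)
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0,
            n_output_points >= 2L, rel_tol > 0, abs_tol > 0)
  structure(list(duration = duration,
                 n_output_points = as.integer(n_output_points),
                 efflux_mode = efflux_mode,
                 serca_enabled = isTRUE(serca_enabled),
                 casq_enabled = isTRUE(casq_enabled),
                 operator_form = operator_form,
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 discretization = discretization,
                 spacing = spacing, hmax = hmax),
            class = "sr_config")
}

#' Initial total Ca2+ field
#'
#' The SR element starts spatially uniform: with calsequestrin present the
#' initial total is the buffer-equilibrium closed form evaluated at the
#' resting free Ca2+ (8.2723 mol m^-3 with default constants); without
#' calsequestrin total and free coincide (3.6 mol m^-3).
#'
#' @param params an [sr_parameters()] object.
#' @param casq_enabled logical.
#' @param grid optionally an `sr_grid`; if supplied, a vector over its
#'   nodes is returned instead of a scalar.
#' @return Initial total Ca2+ concentration (mol m^-3), scalar or per-node.
#' @export
initial_condition <- function(params = sr_parameters(),
                              casq_enabled = TRUE, grid = NULL) {
  c0 <- if (casq_enabled) {
    ca_total_from_free(params$ca_free_initial, params$casq_total, params$Kd)
  } else {
    params$ca_free_initial
  }
  if (is.null(grid)) return(c0)
  stopifnot(inherits(grid, "sr_grid"))
  n <- if (grid$mode == "axial_1d") grid$n_nodes else grid$n_r * grid$n_z
  rep(c0, n)
}

#' Simulate intraluminal SR Ca2+ diffusion
#'
#' Integrates the nonlinear diffusion equation for total Ca2+,
#' `dC/dt = div(D*(C) grad C)`, on the discretised SR element, with the
#' release efflux applied as a Neumann flux on the cisternal face F2, the
#' optional SERCA influx on the lateral face F3, and a no-flux condition
#' on the closed end F1 (and on the symmetry axis in 2D). Under
#' instantaneous 1:1 calsequestrin buffering the effective diffusivity is
#' `D*(C) = D_ca * free(C) / C`; the boundary fluxes are fluxes of free
#' Ca2+, which under instantaneous local re-equilibration are equal in
#' magnitude to the total-Ca2+ fluxes entering the equation.
#'
#' The method of lines is used: a conservative finite-volume spatial
#' operator (arithmetic-mean face diffusivities) coupled to the stiff BDF
#' integrator of \pkg{deSolve} (`lsodes`), which handles the nonlinearity
#' implicitly. Two auxiliary states accumulate the boundary fluxes so the
#' mass audit is quadrature-consistent with the integration itself.
#'
#' @param config an [simulation_config()] object.
#' @param params an [sr_parameters()] object.
#' @param geometry an [sr_geometry()] object.
#' @param efflux,influx optional [efflux_model()] / [influx_model()];
#'   built from `config` and `params` when `NULL`.
#' @param grid optional pre-built `sr_grid` consistent with
#'   `config$discretization`.
#' @return An object of class `sr_simulation`: list with `field` (an
#'   `sr_field`: times, coordinates, total Ca2+ matrix of dimension
#'   time x node), `fluxes` (data frame: time, efflux and influx densities,
#'   cumulative moles out/in, total moles in the domain), plus the resolved
#'   `config`, `params`, `geometry`, `grid` and integrator `stats`.
#' @examples
#' cfg <- simulation_config(duration = 0.001, n_output_points = 11,
#'                          spacing = 1e-7)
#' sim <- sr_simulate(cfg)
#' tail(sim$fluxes$efflux_density, 1)
#' @export
sr_simulate <- function(config = simulation_config(),
                        params = sr_parameters(),
                        geometry = sr_geometry(),
                        efflux = NULL, influx = NULL, grid = NULL) {
  stopifnot(inherits(config, "sr_config"), inherits(params, "sr_parameters"),
            inherits(geometry, "sr_geometry"))
  if (is.null(efflux))
    efflux <- efflux_model(config$efflux_mode, params$J_efflux_0,
                           params$ca_free_initial)
  if (is.null(influx))
    influx <- influx_model(config$serca_enabled, params$J_serca_influx)
  if (is.null(grid)) {
    grid <- if (config$discretization == "axial_1d")
      axial_grid(geometry, config$spacing)
    else axisymmetric_grid(geometry, config$hmax)
  }
  stopifnot(inherits(grid, "sr_grid"))
  if (grid$mode != config$discretization)
    stop("grid mode does not match config$discretization")
  if (config$operator_form == "nonconservative" && grid$mode != "axial_1d")
    stop("the nonconservative operator is available on the 1D grid only")

  times <- seq(0, config$duration, length.out = config$n_output_points)
  if (grid$mode == "axial_1d") {
    sol <- .solve_axial(config, params, geometry, grid, efflux, influx,
                        times)
  } else {
    sol <- .solve_axisym(config, params, geometry, grid, efflux, influx,
                         times)
  }
  sol
}

# Area-averaged free Ca2+ on the F2 face from the state.
.face_free <- function(T_face, casq_enabled, casq_total, Kd) {
  if (casq_enabled) ca_free_from_total(T_face, casq_total, Kd) else T_face
}

.node_diffusivity <- function(Tn, casq_enabled, params) {
  if (casq_enabled)
    effective_diffusivity(pmax(Tn, 0), params$casq_total, params$Kd,
                          params$D_ca)
  else rep_len(params$D_ca, length(Tn))
}

.solve_axial <- function(config, params, geometry, grid, efflux, influx,
                         times) {
  nn <- grid$n_nodes
  h <- grid$h
  r <- geometry$radius
  L <- geometry$axial_length
  casq <- config$casq_enabled
  J_in <- influx_density(influx)
  s_lat <- 2 * J_in / r                      # lateral influx per volume
  conservative <- config$operator_form == "conservative"
  ref_free <- efflux$reference_free_ca

  rhs <- function(t, y, parms) {
    Tn <- y[seq_len(nn)]
    f_face <- .face_free(Tn[1L], casq, params$casq_total, params$Kd)
    J_eff <- efflux_density(efflux, t, free_ca_at_F2 = max(f_face, 0))
    Ds <- .node_diffusivity(Tn, casq, params)
    dT <- numeric(nn)
    if (conservative) {
      Dface <- (Ds[-nn] + Ds[-1L]) / 2
      Fi <- Dface * diff(Tn) / h             # transport toward node i from i+1
      dT[1L] <- (Fi[1L] + J_eff) / (h / 2)
      if (nn > 2L) dT[2:(nn - 1L)] <- diff(Fi) / h
      dT[nn] <- -Fi[nn - 1L] / (h / 2)
    } else {
      # D* Laplacian form with flux-consistent ghost nodes
      Tg0 <- Tn[2L] + 2 * h * J_eff / Ds[1L]
      TgL <- Tn[nn - 1L]
      Text <- c(Tg0, Tn, TgL)
      lap <- (Text[1:nn] - 2 * Tn + Text[3:(nn + 2L)]) / h^2
      dT <- Ds * lap
    }
    dT <- dT + s_lat
    # cumulative boundary throughput on the concentration scale
    list(c(dT, -J_eff / L, s_lat))
  }

  y0 <- c(initial_condition(params, casq, grid), 0, 0)
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsodes", rtol = config$rel_tol,
                      atol = config$abs_tol, maxsteps = 100000)
  .package_solution(out, config, params, geometry, grid, efflux, influx,
                    times, nn)
}

.solve_axisym <- function(config, params, geometry, grid, efflux, influx,
                          times) {
  nr <- grid$n_r; nzn <- grid$n_z
  hz <- grid$hz; dr <- grid$dr
  R <- geometry$radius; L <- geometry$axial_length
  casq <- config$casq_enabled
  J_in <- influx_density(influx)
  ring_area <- grid$ring_area          # length nr, sums to pi R^2
  wz <- grid$z_weights                 # length nzn
  V <- grid$volumes                    # nr x nzn
  face_area_F2 <- geometry$area_F2
  # radial internal faces at edges 2..nr (circumference * axial weight)
  circ_in <- 2 * pi * grid$r_edges[2:nr]          # length nr-1
  circ_out <- 2 * pi * R
  nstate <- nr * nzn

  rhs <- function(t, y, parms) {
    Tm <- matrix(y[seq_len(nstate)], nr, nzn)
    f_face <- .face_free(Tm[, 1L], casq, params$casq_total, params$Kd)
    fbar <- sum(ring_area * f_face) / face_area_F2
    J_eff <- efflux_density(efflux, t, free_ca_at_F2 = max(fbar, 0))
    Ds <- matrix(.node_diffusivity(as.vector(Tm), casq, params), nr, nzn)

    acc <- matrix(0, nr, nzn)          # molar rate into each cell
    # axial diffusion within each ring
    Dz <- (Ds[, -nzn, drop = FALSE] + Ds[, -1L, drop = FALSE]) / 2
    Fz <- Dz * (Tm[, -1L, drop = FALSE] - Tm[, -nzn, drop = FALSE]) / hz
    AFz <- Fz * ring_area              # recycles ring_area down columns
    acc[, -nzn] <- acc[, -nzn, drop = FALSE] + AFz
    acc[, -1L] <- acc[, -1L, drop = FALSE] - AFz
    # radial diffusion between rings
    if (nr > 1L) {
      Dr <- (Ds[-nr, , drop = FALSE] + Ds[-1L, , drop = FALSE]) / 2
      Fr <- Dr * (Tm[-1L, , drop = FALSE] - Tm[-nr, , drop = FALSE]) / dr
      AFr <- Fr * (circ_in * rep(wz, each = nr - 1L))
      acc[-nr, ] <- acc[-nr, , drop = FALSE] + AFr
      acc[-1L, ] <- acc[-1L, , drop = FALSE] - AFr
    }
    # boundary fluxes: release over F2, SERCA over the outer ring (F3)
    acc[, 1L] <- acc[, 1L] + J_eff * ring_area
    acc[nr, ] <- acc[nr, ] + J_in * circ_out * wz
    list(c(as.vector(acc / V), -J_eff / L, 2 * J_in / R))
  }

  y0 <- c(initial_condition(params, casq, grid), 0, 0)
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsodes", rtol = config$rel_tol,
                      atol = config$abs_tol, maxsteps = 100000)
  .package_solution(out, config, params, geometry, grid, efflux, influx,
                    times, nstate)
}

.package_solution <- function(out, config, params, geometry, grid, efflux,
                              influx, times, nstate) {
  diagn <- attributes(out)
  if (nrow(out) < length(times))
    stop("integration failed at t = ", out[nrow(out), 1L],
         " s; inspect tolerances / step diagnostics")
  total <- unname(out[, 1L + seq_len(nstate), drop = FALSE])
  if (min(total) < -config$abs_tol)
    stop("negative concentrations beyond abs_tol: min = ", min(total))
  casq <- config$casq_enabled
  V_tot <- geometry$volume

  if (grid$mode == "axial_1d") {
    vol_w <- grid$volumes
    f_face <- .face_free(total[, 1L], casq, params$casq_total, params$Kd)
  } else {
    vol_w <- as.vector(grid$volumes)
    f_mat <- .face_free(total[, seq_len(grid$n_r), drop = FALSE], casq,
                        params$casq_total, params$Kd)
    f_face <- as.vector(f_mat %*% grid$ring_area) / geometry$area_F2
  }
  J_eff_t <- vapply(f_face, function(f)
    efflux_density(efflux, free_ca_at_F2 = max(f, 0)), numeric(1))
  fluxes <- data.frame(
    time = times,
    efflux_density = J_eff_t,
    influx_density = influx_density(influx),
    cumulative_out_mol = out[, nstate + 2L] * V_tot,
    cumulative_in_mol = out[, nstate + 3L] * V_tot,
    total_mol = as.vector(total %*% vol_w)
  )

  field <- structure(list(
    times = times, mode = grid$mode,
    x = if (grid$mode == "axial_1d") grid$x else NULL,
    r = if (grid$mode == "axisymmetric_2d") grid$r else NULL,
    z = if (grid$mode == "axisymmetric_2d") grid$z else NULL,
    total = total, casq_enabled = casq,
    casq_total = params$casq_total, Kd = params$Kd, grid = grid
  ), class = "sr_field")

  structure(list(field = field, fluxes = fluxes, config = config,
                 params = params, geometry = geometry, grid = grid,
                 efflux = efflux, influx = influx,
                 stats = list(istate = diagn$istate, rstate = diagn$rstate)),
            class = "sr_simulation")
}

#' @export
print.sr_simulation <- function(x, ...) {
  cat(sprintf(
    "SR Ca2+ diffusion run: %s, %.4g s, efflux %s, casq %s, SERCA %s\n",
    x$grid$mode, x$config$duration, x$efflux$mode,
    if (x$config$casq_enabled) "on" else "off",
    if (x$config$serca_enabled) "on" else "off"))
  s <- condition_summary(x)
  cat(sprintf("  efflux decline %.4g%%, CSR free decline %.4g%%, ",
              s$efflux_decline_pct, s$csr_free_decline_pct))
  cat(sprintf("LSR-CSR free difference %.4g uM\n", s$lsr_csr_diff_uM))
  invisible(x)
}

#' Free Ca2+ view of a concentration field
#'
#' @param field an `sr_field` (component of an [sr_simulate()] result).
#' @return Matrix of free Ca2+ (time x node), mol m^-3; identical to the
#'   total matrix when the run had calsequestrin disabled.
#' @export
free_field <- function(field) {
  stopifnot(inherits(field, "sr_field"))
  if (!field$casq_enabled) return(field$total)
  m <- ca_free_from_total(field$total, field$casq_total, field$Kd)
  dim(m) <- dim(field$total)
  m
}

#' Largest relative mass-balance violation of a run
#'
#' Compares, at every output time, the change in total moles inside the
#' domain with the integrated boundary throughput (release out through F2
#' minus SERCA uptake in through F3), relative to the initial content.
#'
#' @param sim an `sr_simulation`.
#' @return Maximal relative discrepancy (dimensionless).
#' @export
mass_balance_error <- function(sim) {
  stopifnot(inherits(sim, "sr_simulation"))
  fl <- sim$fluxes
  M0 <- fl$total_mol[1L]
  max(abs(fl$total_mol - M0 + fl$cumulative_out_mol -
            fl$cumulative_in_mol)) / M0
}

#' Well-mixed (single-compartment) limit of the SR element
#'
#' Solves the spatially lumped balance
#' `dC/dt = J_efflux(free(C)) / L + 2 * J_influx / r`
#' with the same buffer algebra and boundary models as the PDE; the
#' large-diffusivity limit of [sr_simulate()] and the natural oracle for
#' the diffusionally equilibrated regime. Closed forms exist for the
#' unbuffered cases: a linear decline for constant efflux and an
#' exponential decay (rate `|J0| / (L * free0)`) for decaying efflux
#' without influx.
#'
#' @inheritParams sr_simulate
#' @return Data frame with `time`, `total`, `free` (mol m^-3) and
#'   `efflux_density` (mol m^-2 s^-1).
#' @export
well_mixed_limit <- function(config = simulation_config(),
                             params = sr_parameters(),
                             geometry = sr_geometry(),
                             efflux = NULL, influx = NULL) {
  stopifnot(inherits(config, "sr_config"))
  if (is.null(efflux))
    efflux <- efflux_model(config$efflux_mode, params$J_efflux_0,
                           params$ca_free_initial)
  if (is.null(influx))
    influx <- influx_model(config$serca_enabled, params$J_serca_influx)
  L <- geometry$axial_length; r <- geometry$radius
  casq <- config$casq_enabled
  s_lat <- 2 * influx_density(influx) / r
  rhs <- function(t, y, parms) {
    f <- .face_free(y[1L], casq, params$casq_total, params$Kd)
    J <- efflux_density(efflux, t, free_ca_at_F2 = max(f, 0))
    list(J / L + s_lat)
  }
  times <- seq(0, config$duration, length.out = config$n_output_points)
  y0 <- initial_condition(params, casq)
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      rtol = config$rel_tol, atol = config$abs_tol)
  total <- out[, 2L]
  free <- if (casq) ca_free_from_total(total, params$casq_total, params$Kd)
          else total
  data.frame(time = times, total = total, free = free,
             efflux_density = vapply(free, function(f)
               efflux_density(efflux, free_ca_at_F2 = max(f, 0)),
               numeric(1)))
}
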
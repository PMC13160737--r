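#' Analytic solution of the constant-flux Neumann rod problem
#'
#' Classical Fourier-series solution of `dc/dt = D d2c/dx2` on `[0, L]`
#' with a constant boundary flux density `J` applied at `x = 0` (signed:
#' negative extracts material) and an insulated end at `x = L`, starting
#' from the uniform state `c0`:
#' \deqn{c(x,t) = c_0 + \frac{J L}{D}\Big[\frac{Dt}{L^2} +
#'   \frac{3\hat x^2 - 1}{6} - \frac{2}{\pi^2}\sum_{n\ge 1}
#'   \frac{(-1)^n}{n^2} e^{-n^2\pi^2 Dt/L^2}\cos(n\pi\hat x)\Big],}
#' with \eqn{\hat x = (L - x)/L}. This is the constant-diffusivity limit
#' of the buffered diffusion model and the independent reference for the
#' implicit solver. The spatial average is exactly `c0 + J t / L`, and the
#' quasi-steady face gradient is `|J|/D`.
#'
#' @param D diffusivity, m^2 s^-1.
#' @param J boundary flux density at x = 0, mol m^-2 s^-1 (negative =
#'   extraction).
#' @param c0 initial concentration, mol m^-3.
#' @param L rod length, m.
#' @param x positions, m.
#' @param t times, s.
#' @param tol series truncation: terms are added until their magnitude
#'   falls below `tol * c0` (at least 200 terms are available).
#' @return Matrix of concentrations, `length(t)` rows x `length(x)`
#'   columns.
#' @export
analytic_rod_solution <- function(D, J, c0, L, x, t, tol = 1e-16) {
  stopifnot(D > 0, L > 0, all(x >= 0), all(x <= L), all(t >= 0))
  xh <- (L - x) / L
  scale <- J * L / D
  out <- matrix(0, length(t), length(x))
  nmax <- 200L
  for (i in seq_along(t)) {
    tau <- D * t[i] / L^2
    series <- numeric(length(x))
    if (t[i] > 0) {
      for (n in seq_len(nmax)) {
        term <- ((-1)^n / n^2) * exp(-n^2 * pi^2 * tau) * cos(n * pi * xh)
        series <- series + term
        if (max(abs(term)) * abs(scale) * 2 / pi^2 < tol * max(c0, 1))
          break
      }
      out[i, ] <- c0 + scale * (tau + (3 * xh^2 - 1) / 6 -
                                  (2 / pi^2) * series)
    } else {
      out[i, ] <- c0
    }
  }
  out
}

#' Brute-force explicit reference solver (1D)
#'
#' Forward-Euler, conservative finite-volume integration of the same
#' semi-discrete system as [sr_simulate()] on the 1D axial grid, with a
#' fixed stability-bounded time step `dt <= safety * h^2 / (2 D_ca)`
#' (D* never exceeds the free diffusivity). Intended as an independent
#' cross-check of the implicit solver at small problem sizes; the
#' telescoping conservative update makes its mass balance an identity up
#' to round-off.
#'
#' @inheritParams sr_simulate
#' @param safety fraction of the explicit stability limit used for the
#'   step (default 0.4, i.e. dt = 0.2 h^2 / D_ca).
#' @return An object mimicking the `sr_simulation` contract: list with
#'   `field`, `fluxes` (cumulative moles accumulated by the same explicit
#'   quadrature), and the resolved inputs.
#' @export
explicit_reference_solver <- function(config = simulation_config(),
                                      params = sr_parameters(),
                                      geometry = sr_geometry(),
                                      efflux = NULL, influx = NULL,
                                      grid = NULL, safety = 0.4) {
  stopifnot(inherits(config, "sr_config"))
  if (config$discretization != "axial_1d")
    stop("the explicit reference solver is 1D only")
  if (is.null(efflux))
    efflux <- efflux_model(config$efflux_mode, params$J_efflux_0,
                           params$ca_free_initial)
  if (is.null(influx))
    influx <- influx_model(config$serca_enabled, params$J_serca_influx)
  if (is.null(grid)) grid <- axial_grid(geometry, config$spacing)

  nn <- grid$n_nodes; h <- grid$h
  r <- geometry$radius; L <- geometry$axial_length
  casq <- config$casq_enabled
  J_in <- influx_density(influx)
  s_lat <- 2 * J_in / r
  times <- seq(0, config$duration, length.out = config$n_output_points)
  dt <- safety * h^2 / (2 * params$D_ca)

  Tn <- initial_condition(params, casq, grid)
  qout <- 0; qin <- 0
  total <- matrix(0, length(times), nn)
  cum_out <- cum_in <- numeric(length(times))
  total[1L, ] <- Tn
  t_now <- 0
  for (k in 2L:length(times)) {
    t_target <- times[k]
    while (t_now < t_target - 1e-15 * t_target) {
      step <- min(dt, t_target - t_now)
      f_face <- .face_free(Tn[1L], casq, params$casq_total, params$Kd)
      J_eff <- efflux_density(efflux, t_now, free_ca_at_F2 = max(f_face, 0))
      Ds <- .node_diffusivity(Tn, casq, params)
      Dface <- (Ds[-nn] + Ds[-1L]) / 2
      Fi <- Dface * diff(Tn) / h
      dT <- numeric(nn)
      dT[1L] <- (Fi[1L] + J_eff) / (h / 2)
      if (nn > 2L) dT[2:(nn - 1L)] <- diff(Fi) / h
      dT[nn] <- -Fi[nn - 1L] / (h / 2)
      Tn <- Tn + step * (dT + s_lat)
      qout <- qout - step * J_eff / L
      qin <- qin + step * s_lat
      t_now <- t_now + step
    }
    total[k, ] <- Tn
    cum_out[k] <- qout; cum_in[k] <- qin
  }

  V_tot <- geometry$volume
  f_face_t <- .face_free(total[, 1L], casq, params$casq_total, params$Kd)
  fluxes <- data.frame(
    time = times,
    efflux_density = vapply(f_face_t, function(f)
      efflux_density(efflux, free_ca_at_F2 = max(f, 0)), numeric(1)),
    influx_density = J_in,
    cumulative_out_mol = cum_out * V_tot,
    cumulative_in_mol = cum_in * V_tot,
    total_mol = as.vector(total %*% grid$volumes)
  )
  field <- structure(list(times = times, mode = "axial_1d", x = grid$x,
                          r = NULL, z = NULL, total = total,
                          casq_enabled = casq,
                          casq_total = params$casq_total, Kd = params$Kd,
                          grid = grid), class = "sr_field")
  structure(list(field = field, fluxes = fluxes, config = config,
                 params = params, geometry = geometry, grid = grid,
                 efflux = efflux, influx = influx,
                 stats = list(dt = dt)),
            class = "sr_simulation")
}
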
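test_that("initial condition is uniform and consistent with the buffer algebra", {
  grid <- axial_grid(default_geom, 1e-7)
  ic_on <- initial_condition(default_params, TRUE, grid)
  expect_true(all(ic_on == ic_on[1L]))
  expect_equal(ic_on[1L], 8.2723, tolerance = 5e-5)
  ic_off <- initial_condition(default_params, FALSE, grid)
  expect_equal(unique(ic_off), 3.6)
  # free view of the buffered initial state recovers the resting free level
  expect_equal(ca_free_from_total(ic_on[1L], 6.1, 1.1), 3.6,
               tolerance = 1e-10)
})

test_that("with all boundary fluxes shut the field stays at equilibrium", {
  for (casq in c(TRUE, FALSE)) {
    cfg <- coarse_config(duration = 0.01, casq_enabled = casq,
                         n_output_points = 11L)
    sim <- sr_simulate(cfg, efflux = efflux_model("constant", J0 = 0),
                       influx = influx_model(FALSE))
    c0 <- initial_condition(default_params, casq)
    expect_lt(max(abs(sim$field$total - c0)), 1e-10)
    expect_true(all(sim$fluxes$efflux_density == 0))
  }
})

test_that("unbuffered constant-efflux run matches the analytic Fourier-series solution", {
  cfg <- simulation_config(duration = 0.02, n_output_points = 101L,
                           efflux_mode = "constant", casq_enabled = FALSE)
  sim <- sr_simulate(cfg)
  ana <- analytic_rod_solution(default_params$D_ca,
                               default_params$J_efflux_0,
                               default_params$ca_free_initial,
                               default_geom$axial_length,
                               sim$field$x, sim$field$times)
  expect_lt(max(abs(sim$field$total - ana)) /
              default_params$ca_free_initial, 1e-4)
})

test_that("mass balance closes to 1e-6 relative for every condition class", {
  combos <- expand.grid(casq = c(TRUE, FALSE), serca = c(TRUE, FALSE),
                        mode = c("decaying", "constant"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    cfg <- coarse_config(duration = 0.02, casq_enabled = combos$casq[i],
                         serca_enabled = combos$serca[i],
                         efflux_mode = combos$mode[i])
    expect_lt(mass_balance_error(sr_simulate(cfg)), 1e-6,
              label = paste("1D mass balance, combo", i))
  }
  cfg2 <- simulation_config(duration = 0.005, n_output_points = 21L,
                            serca_enabled = TRUE,
                            discretization = "axisymmetric_2d",
                            hmax = 1.5e-8)
  expect_lt(mass_balance_error(sr_simulate(cfg2)), 1e-6)
})

test_that("halving the grid spacing and output step leaves the 20-ms cisternal free level unchanged to 1e-4", {
  c1 <- simulation_config(duration = 0.02, n_output_points = 51L,
                          spacing = 1e-8)
  c2 <- simulation_config(duration = 0.02, n_output_points = 101L,
                          spacing = 5e-9)
  f1 <- free_field(sr_simulate(c1)$field)
  f2 <- free_field(sr_simulate(c2)$field)
  expect_lt(abs(f1[nrow(f1), 1L] - f2[nrow(f2), 1L]) / f2[nrow(f2), 1L],
            1e-4)
})

test_that("1D axial and 2D axisymmetric solutions coincide without radial forcing", {
  for (casq in c(TRUE, FALSE)) {
    c1 <- simulation_config(duration = 0.01, n_output_points = 21L,
                            casq_enabled = casq)
    c2 <- simulation_config(duration = 0.01, n_output_points = 21L,
                            casq_enabled = casq,
                            discretization = "axisymmetric_2d")
    a1 <- colormap_matrix(sr_simulate(c1)$field, "axial", "total")
    a2 <- colormap_matrix(sr_simulate(c2)$field, "axial", "total")
    expect_lt(max(abs(a1 - a2)) / max(a1), 1e-6)
  }
})

test_that("radial gradients stay orders of magnitude below axial gradients (full condition, 2D)", {
  cfg <- simulation_config(duration = 0.02, n_output_points = 101L,
                           efflux_mode = "decaying", casq_enabled = TRUE,
                           serca_enabled = TRUE,
                           discretization = "axisymmetric_2d")
  sp <- axial_radial_spread(sr_simulate(cfg)$field)
  expect_gte(sp$log10_ratio, 3)
})

test_that("calsequestrin slows both the efflux and the cisternal free-Ca2+ declines", {
  run <- function(casq) condition_summary(
    sr_simulate(coarse_config(duration = 0.02, casq_enabled = casq)))
  on <- run(TRUE); off <- run(FALSE)
  expect_lt(on$efflux_decline_pct, off$efflux_decline_pct)
  expect_lt(on$csr_free_decline_pct, off$csr_free_decline_pct)
})

test_that("background SERCA uptake barely moves the 20-ms cisternal free Ca2+", {
  # the lateral influx adds at most 2*J_in*t/r ~ 1e-3 mol m^-3 over the
  # twitch window, i.e. well under 0.1% of the resting free level
  run <- function(serca) {
    sim <- sr_simulate(coarse_config(duration = 0.02,
                                     serca_enabled = serca))
    fr <- free_field(sim$field)
    fr[nrow(fr), 1L]
  }
  expect_lt(abs(run(TRUE) - run(FALSE)) / run(FALSE), 1e-3)
})

test_that("well-mixed limit reproduces its closed forms", {
  p <- default_params; L <- default_geom$axial_length
  wm <- well_mixed_limit(simulation_config(duration = 2,
                                           efflux_mode = "constant",
                                           casq_enabled = FALSE,
                                           n_output_points = 21L))
  expect_equal(wm$total, 3.6 + p$J_efflux_0 * wm$time / L,
               tolerance = 1e-10)
  k <- abs(p$J_efflux_0) / (L * 3.6)
  wmd <- well_mixed_limit(simulation_config(duration = 2,
                                            casq_enabled = FALSE,
                                            n_output_points = 21L))
  expect_equal(wmd$total, 3.6 * exp(-k * wmd$time), tolerance = 1e-6)
})

test_that("a large diffusivity collapses the PDE onto the well-mixed trajectory", {
  pfast <- sr_parameters(D_ca = 3e-10 * 1e6)
  cfg <- coarse_config(duration = 0.02, casq_enabled = FALSE,
                       n_output_points = 21L)
  sim <- sr_simulate(cfg, params = pfast)
  wm <- well_mixed_limit(cfg, params = pfast)
  spread <- apply(sim$field$total, 1L, function(v) diff(range(v)))
  expect_lt(max(spread) / 3.6, 1e-6)
  mean_t <- as.vector(sim$field$total %*% sim$grid$volumes) /
    sum(sim$grid$volumes)
  expect_lt(max(abs(mean_t - wm$total)) / 3.6, 1e-5)
})

test_that("identical configurations reproduce identical trajectories", {
  cfg <- coarse_config(duration = 0.01, serca_enabled = TRUE,
                       n_output_points = 11L)
  s1 <- sr_simulate(cfg); s2 <- sr_simulate(cfg)
  expect_identical(s1$field$total, s2$field$total)
  expect_identical(s1$fluxes, s2$fluxes)
})

test_that("the nonconservative operator form is a close sensitivity variant", {
  # with constant diffusivity (no buffer) the two operator forms are the
  # same scheme; with the nonlinear coefficient they differ only mildly
  cfg_c <- coarse_config(duration = 0.01, casq_enabled = FALSE,
                         n_output_points = 11L)
  cfg_n <- coarse_config(duration = 0.01, casq_enabled = FALSE,
                         n_output_points = 11L,
                         operator_form = "nonconservative")
  expect_equal(sr_simulate(cfg_n)$field$total,
               sr_simulate(cfg_c)$field$total, tolerance = 1e-8)
  cfg_cb <- coarse_config(duration = 0.01, n_output_points = 11L)
  cfg_nb <- coarse_config(duration = 0.01, n_output_points = 11L,
                          operator_form = "nonconservative")
  expect_equal(sr_simulate(cfg_nb)$field$total,
               sr_simulate(cfg_cb)$field$total, tolerance = 1e-3)
  expect_error(sr_simulate(simulation_config(
    discretization = "axisymmetric_2d",
    operator_form = "nonconservative")), "1D")
})
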
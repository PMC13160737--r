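test_that("default registry carries the tabulated amphibian constants", {
  p <- default_params
  expect_equal(p$ca_free_initial, 3.6)
  expect_equal(p$Kd, 1.1)
  expect_equal(p$casq_total, 6.1)
  expect_equal(p$element_diameter, 3.00e-8)
  expect_equal(p$D_ca, 3e-10)
  expect_identical(p$D_casq, 0)
  expect_equal(p$J_efflux_0, -2.7375e-6)
  expect_equal(p$J_serca_influx, 3.688e-10)
  expect_equal(p$tubular_area, 5.733e-9)
  expect_equal(p$junctional_area, 1.720e-9)
  # the tabulated junctional area is xi * A_T at tabulated rounding
  expect_equal(p$junctional_area, p$junction_fraction * p$tubular_area,
               tolerance = 1e-4)
})

test_that("parameter validation rejects unphysical values", {
  expect_error(sr_parameters(Kd = -1), "positive")
  expect_error(sr_parameters(junction_fraction = 1.2), "0, 1")
  expect_error(sr_parameters(J_efflux_0 = 1e-6), "negative")
  expect_error(sr_parameters(D_casq = 1e-12), "anchored")
  expect_error(sr_parameters(nonsense = 1), "unknown parameter")
})

test_that("tubular and junctional areas follow both the tabulated and the capacitance-formula routes", {
  a <- tubular_areas(default_params)
  expect_equal(a[["A_TSR"]], 0.3 * 5.733e-9)
  expect_equal(a[["A_TSR"]], 1.720e-9, tolerance = 1e-4)  # printed rounding
  pf <- sr_parameters(use_formula_tubular_area = TRUE)
  af <- tubular_areas(pf)
  expect_equal(af[["A_T"]], 5 * pi * 100e-6 * 3.6e-6)
  expect_equal(af[["A_T"]], 5.654867e-9, tolerance = 1e-7)
  # A_TSR is proportional to the junction fraction
  for (xi in c(0.15, 0.45))
    expect_equal(tubular_areas(sr_parameters(junction_fraction = xi))[["A_TSR"]],
                 xi * 5.733e-9)
})

test_that("lumped SR diameter and cross-section follow the volume-fraction rule", {
  expect_equal(equivalent_sr_diameter(default_params), 100e-6 * sqrt(0.12))
  expect_equal(equivalent_sr_diameter(default_params) * 1e6, 34.641,
               tolerance = 1e-4)
  d <- sr_derived(default_params)
  expect_equal(d$lumped_sr_cross_section, 9.4248e-10, tolerance = 1e-4)
  expect_equal(d$element_count, (34.641e-6 / 3e-8)^2, tolerance = 1e-4)
  # near-unity volume fraction recovers (almost) the fibre diameter
  expect_equal(equivalent_sr_diameter(sr_parameters(sr_volume_fraction = 1 - 1e-12)),
               100e-6, tolerance = 1e-9)
})

test_that("element efflux density reproduces the tabulated value and is linear in its inputs", {
  p <- default_params
  j <- initial_efflux_density(-3.0e-6, p)
  expect_equal(j, -2.7375e-6, tolerance = 1e-4)
  expect_lt(j, 0)
  expect_identical(initial_efflux_density(0, p), 0)
  A <- p$junctional_area
  expect_equal(initial_efflux_density(-3.0e-6, p, A_tsr = 2 * A), 2 * j)
  expect_equal(initial_efflux_density(-1.5e-6, p), j / 2)
})

test_that("SERCA influx density reproduces the tabulated value and scales inversely with sarcomere length", {
  p <- default_params
  jin <- serca_influx_density(9.70e-8, p)
  expect_equal(jin, 3.6880e-10, tolerance = 1e-3)
  expect_equal(jin * 1e-18, 3.6880e-28, tolerance = 1e-3)
  expect_identical(serca_influx_density(0, p), 0)
  p2 <- sr_parameters(sarcomere_length = 3.6e-6 / 2)
  expect_equal(serca_influx_density(9.70e-8, p2,
                                    A_tsr = tubular_areas(p)[["A_TSR"]]),
               2 * jin)
})

test_that("SI and physiological display units round-trip to machine precision", {
  p <- default_params
  tab <- parameter_table(p)
  for (i in seq_len(nrow(tab))) {
    f <- tab$field[i]
    expect_identical(convert_units(convert_units(p[[f]], f, "phys"),
                                   f, "si"),
                     p[[f]], info = f)
  }
  # display values match the tabulated physiological column
  expect_equal(tab$value_phys[tab$symbol == "K_d"], 1100)   # uM
  expect_equal(tab$value_phys[tab$symbol == "A_T"], 5733)   # um^2
  expect_equal(tab$value_phys[tab$symbol == "J_efflux_0"], -2.7375e-24)
})

test_that("config files override parameters by symbol name; unknown keys error", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("K_d: 0.9", "D_Ca: 2.0e-10", "ca_free_initial: 3.0"), f)
  p <- load_parameters(f)
  expect_equal(p$Kd, 0.9)
  expect_equal(p$D_ca, 2e-10)
  expect_equal(p$ca_free_initial, 3.0)
  expect_equal(p$casq_total, 6.1)   # untouched default
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("mystery_knob: 1", f2)
  expect_error(load_parameters(f2), "unknown config key")
})

test_that("derived initial total is the buffer-equilibrium closed form", {
  d <- sr_derived(default_params)
  expect_equal(d$ca_total_initial,
               ca_total_from_free(3.6, 6.1, 1.1))
  tab <- parameter_table(default_params, derived = TRUE)
  expect_true("Ca_total_0" %in% tab$symbol)
})
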
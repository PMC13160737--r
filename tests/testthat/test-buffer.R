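test_that("total-from-free closed form matches the resting equilibrium and its trivial limits", {
  expect_equal(ca_total_from_free(3.6, 6.1, 1.1), 8.2723, tolerance = 5e-5)
  expect_equal(ca_total_from_free(2.5, 0, 1.1), 2.5)     # no buffer
  expect_equal(ca_total_from_free(0, 6.1, 1.1), 0)       # no calcium
  expect_error(ca_total_from_free(-1, 6.1, 1.1), ">= 0")
  expect_error(ca_total_from_free(1, 6.1, 0), "positive")
})

test_that("bound-from-total picks the physical quadratic root", {
  # frozen against the independent bracketing solve of the mass-action
  # equation: bound_by_bracketing(8.2723, 6.1, 1.1) = 4.672301...
  expect_equal(ca_bound_from_total(8.2723, 6.1, 1.1),
               bound_by_bracketing(8.2723, 6.1, 1.1), tolerance = 1e-10)
  expect_equal(ca_bound_from_total(8.2723, 6.1, 1.1), 4.6723,
               tolerance = 1e-4)
  expect_equal(ca_bound_from_total(5, 0, 1.1), 0)
  expect_equal(ca_bound_from_total(0, 6.1, 1.1), 0)
  b <- ca_bound_from_total(8.2723, 6.1, 1.1)
  expect_lte(b, 6.1)
  expect_lte(b, 8.2723)
})

test_that("quadratic root selection agrees with bracketing root-finding over random valid inputs", {
  set.seed(42)
  n <- 2000
  Kd <- 10^runif(n, -2, 1)
  Cq <- runif(n, 0, 50)
  f <- 10^runif(n, -6, 2)
  Tt <- ca_total_from_free(f, Cq, Kd)
  b_quad <- ca_bound_from_total(Tt, Cq, Kd)
  b_ref <- mapply(bound_by_bracketing, Tt, Cq, Kd)
  expect_equal(b_quad, b_ref, tolerance = 1e-8)
})

test_that("free/total conversions round-trip and conserve mass", {
  f <- 10^seq(-6, 2, length.out = 200)
  Tt <- ca_total_from_free(f, 6.1, 1.1)
  expect_equal(ca_free_from_total(Tt, 6.1, 1.1), f, tolerance = 1e-10)
  b <- ca_bound_from_total(Tt, 6.1, 1.1)
  expect_equal(b + ca_free_from_total(Tt, 6.1, 1.1), Tt,
               tolerance = 1e-10)
  # K_d relation holds pointwise
  fr <- ca_free_from_total(Tt, 6.1, 1.1)
  expect_equal(1.1 * b, fr * (6.1 - b), tolerance = 1e-10)
  # trivial limits
  expect_equal(ca_free_from_total(7.3, 0, 1.1), 7.3)
  expect_equal(ca_free_from_total(0, 6.1, 1.1), 0)
  expect_equal(ca_free_from_total(8.2723, 6.1, 1.1), 3.6000,
               tolerance = 1e-4)
})

test_that("free-from-total is strictly increasing with derivative in (0, 1]", {
  Tt <- seq(1e-4, 60, length.out = 4000)
  fr <- ca_free_from_total(Tt, 6.1, 1.1)
  d <- diff(fr) / diff(Tt)
  expect_true(all(d > 0))
  expect_true(all(d <= 1 + 1e-12))
})

test_that("effective diffusivity is the free fraction of the free-Ca2+ diffusivity", {
  D <- 3e-10
  expect_equal(effective_diffusivity(8.2723, 6.1, 1.1, D), 1.3056e-10,
               tolerance = 1e-4)
  expect_equal(effective_diffusivity(8.2723, 6.1, 1.1, D),
               D * ca_free_from_total(8.2723, 6.1, 1.1) / 8.2723)
  expect_equal(effective_diffusivity(5, 0, 1.1, D), D)   # no buffer
  # bounded in (0, D], equal to D only without buffer
  Tt <- 10^seq(-8, 2, length.out = 100)
  Ds <- effective_diffusivity(Tt, 6.1, 1.1, D)
  expect_true(all(Ds > 0 & Ds < D))
  # monotone decrease with buffer load at fixed total
  Cq <- seq(0, 100, length.out = 50)
  Ds2 <- effective_diffusivity(rep(8, 50), Cq, 1.1, D)
  expect_true(all(diff(Ds2) < 0))
  expect_lt(effective_diffusivity(8, 1e4, 1.1, D), 1e-12)
})

test_that("effective diffusivity extends continuously to zero total Ca2+", {
  D <- 3e-10
  lim <- D * 1.1 / (1.1 + 6.1)
  expect_equal(effective_diffusivity(0, 6.1, 1.1, D), lim)
  expect_equal(effective_diffusivity(1e-10, 6.1, 1.1, D), lim,
               tolerance = 1e-6)
})

test_that("buffer state assembles a consistent equilibrium from either side", {
  st <- buffer_state(ca_free = 3.6)
  expect_equal(st$ca_total, st$ca_free + st$casq_bound)
  expect_equal(st$casq_total, st$casq_free + st$casq_bound)
  expect_equal(st$Kd * st$casq_bound, st$ca_free * st$casq_free,
               tolerance = 1e-10)
  st2 <- buffer_state(ca_total = st$ca_total)
  expect_equal(st2$ca_free, 3.6, tolerance = 1e-10)
  expect_error(buffer_state(), "exactly one")
  expect_error(buffer_state(ca_free = 1, ca_total = 2), "exactly one")
})
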
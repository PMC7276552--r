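test_that("single-interface reflectance matches the Fresnel closed form", {
  st <- multilayer_stack(1.34, 1, n_ambient = 1, n_substrate = 1.34)
  r <- tmm_reflectance(st, 0, "TM", 500)
  expect_equal(r$R, (0.34 / 2.34)^2, tolerance = 1e-12)
  expect_equal(tmm_reflectance(st, 0, "TE", 500)$R, (0.34 / 2.34)^2,
               tolerance = 1e-12)
})

test_that("index-matched stacks are invisible", {
  st <- multilayer_stack(rep(1.34, 6), rep(120, 6), n_ambient = 1.34,
                         n_substrate = 1.34)
  r <- tmm_reflectance(st, 17, "TE", seq(300, 700, 50))
  expect_true(all(r$R < 1e-24))
})

test_that("energy is conserved and polarizations coincide at normal incidence", {
  st <- stack_from_lattice(395, 395, direction = "GK", repetitions = 41)
  for (th in c(0, 25, 50)) for (pol in c("TE", "TM")) {
    r <- tmm_reflectance(st, th, pol, seq(300, 700, 10))
    expect_lt(max(abs(r$R + r$T - 1)), 1e-10)
  }
  a <- tmm_reflectance(st, 0, "TE", seq(300, 700, 10))
  b <- tmm_reflectance(st, 0, "TM", seq(300, 700, 10))
  expect_lt(max(abs(a$R - b$R)), 1e-12)
})

test_that("effective-index stack has the lattice period and mean index", {
  stk <- stack_from_lattice(395, 395, direction = "GK")
  expect_equal(sum(stk$thickness), sqrt(3) * 395 / 2, tolerance = 1e-9)
  stm <- stack_from_lattice(395, 395, direction = "GM")
  expect_equal(sum(stm$thickness), 395 / 2, tolerance = 1e-9)
  # area-exact permittivity mixing: mean eps equals touching-disk filling
  f <- pi / (2 * sqrt(3))
  nbar <- sqrt(f * 1.38^2 + (1 - f) * 1.34^2)
  for (nsl in c(2, 8)) {
    st <- stack_from_lattice(395, 395, direction = "GK",
                             n_layers_per_period = nsl)
    expect_equal(sqrt(sum(st$n^2 * st$thickness) / sum(st$thickness)),
                 nbar, tolerance = 1e-3)
  }
  # empty lattice: homogeneous background
  st0 <- stack_from_lattice(395, 0, direction = "GK")
  expect_true(all(abs(st0$n - 1.34) < 1e-12))
})

test_that("41-period stack peaks at the m = 2 and m = 3 Bragg wavelengths", {
  st <- stack_from_lattice(395, 395, direction = "GK", repetitions = 41)
  sp <- tmm_reflectance(st, 0, "TM", seq(290, 700, 1))
  pk <- spectrum_peaks(sp$wavelength, sp$R, 0.2)
  f <- pi / (2 * sqrt(3))
  nbar <- sqrt(f * 1.38^2 + (1 - f) * 1.34^2)
  bragg <- 2 * nbar * sqrt(3) * 395 / 2 / c(2, 3)
  for (b in bragg) {
    near <- pk[abs(pk$lambda - b) < 8, ]
    expect_gte(nrow(near), 1)
    expect_lt(abs(near$lambda[1] - b), near$fwhm[1] + 1)
  }
})

test_that("peak wavelengths scale linearly with a uniform index scaling", {
  base <- stack_from_lattice(395, 395, direction = "GK", repetitions = 41,
                             n_ambient = 1.34, n_substrate = 1.34)
  peak_of <- function(st) {
    sp <- tmm_reflectance(st, 0, "TM", seq(380, 560, 0.5))
    sp$wavelength[which.max(sp$R)]
  }
  p0 <- peak_of(base)
  for (sc in c(0.95, 1.05)) {
    st <- multilayer_stack(base$n * sc, base$thickness,
                           n_ambient = 1.34 * sc, n_substrate = 1.34 * sc,
                           repetitions = base$repetitions)
    expect_equal(peak_of(st) / p0, sc, tolerance = 0.01)
  }
})

test_that("tilted stacks behave symmetrically and reduce to the flat case", {
  st <- stack_from_lattice(395, 395, direction = "GM", repetitions = 21)
  lam <- seq(300, 700, 5)
  t0 <- tilted_stack_response(st, 0, theta_in = c(-30, 0, 30),
                              wavelengths = lam)
  flat <- tmm_reflectance(st, 0, "TM", lam)
  expect_equal(t0$R[2, ], flat$R, tolerance = 1e-12)
  tp <- tilted_stack_response(st, 30, theta_in = 0, wavelengths = lam)
  tm <- tilted_stack_response(st, -30, theta_in = 0, wavelengths = lam)
  expect_equal(tp$R[1, ], tm$R[1, ], tolerance = 1e-12)
  # grazing effective incidence is marked missing
  tg <- tilted_stack_response(st, 30, theta_in = c(-65, 0), wavelengths = lam)
  expect_true(all(is.na(tg$R[1, ])))
})

test_that("angle sweep of the specular peak follows the dispersion relation", {
  # cross-module property: TMM peak shift vs specular_shift()
  st <- stack_from_lattice(395, 395, direction = "GK", repetitions = 41,
                           n_ambient = 1, n_substrate = 1.34)
  lam <- seq(380, 500, 0.5)
  peak_at <- sapply(c(0, 20, 35), function(th)
    lam[which.max(tmm_reflectance(st, th, "TM", lam)$R)])
  f <- pi / (2 * sqrt(3))
  nbar <- sqrt(f * 1.38^2 + (1 - f) * 1.34^2)
  pred <- specular_shift(peak_at[1], nbar, c(0, 20, 35))
  expect_lt(max(abs(peak_at - pred)), 2)
})
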
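test_that("hexagonal construction honours count, spacing and symmetry", {
  # particle count from the filling fraction at the reference volume
  spec5 <- lattice_spec(395, 375, box = c(5000, 5000), ff = 0.6)
  expect_equal(round(0.6 * 5000^2 / (pi * 187.5^2)), 136)
  ens5 <- make_hexagonal(spec5)
  expect_equal(nrow(ens5$positions), 136, tolerance = 0.04)
  # nearest-neighbour distance is exactly d by construction
  ens <- make_hexagonal(lattice_spec(395, 375, box = c(2500, 2370),
                                     ff = 0.6))
  expect_equal(min_pair_distance(ens), 395, tolerance = 1e-9)
  # 30-degree orientation is the same lattice rotated
  e30 <- make_hexagonal(lattice_spec(395, 375, box = c(2500, 2050),
                                     ff = 0.55, orientation = 30))
  expect_equal(min_pair_distance(e30), 395, tolerance = 1e-6)
  # overfilled request errors
  expect_error(lattice_spec(395, 375, ff = 0.9), "exceeds")
})

test_that("jitter preserves hard disks and obeys the Debye-Waller limit", {
  spec <- lattice_spec(395, 375, box = c(2500, 2370), ff = 0.6)
  ens0 <- make_hexagonal(spec)
  expect_equal(jitter_lattice(spec, 0)$positions, ens0$positions)
  q1 <- 4 * pi / (sqrt(3) * 395)
  qs <- cbind(q1 * cos(pi / 3 * (0:5)), q1 * sin(pi / 3 * (0:5)))
  S0 <- mean(photocolony:::sq_on_points(ens0$positions, qs))
  for (sig in c(5, 10)) {
    ratio <- mean(sapply(1:4, function(s) {
      ej <- jitter_lattice(spec, sig, seed = s)
      expect_gte(min_pair_distance(ej), 2 * ej$radius - 1e-6)
      mean(photocolony:::sq_on_points(ej$positions, qs))
    })) / S0
    expect_lt(abs(ratio - exp(-q1^2 * sig^2)), 0.15)
  }
  expect_error(jitter_lattice(spec, 60), "rejection rate")
})

test_that("analytic disorder targets have the stated geometry", {
  spec <- lattice_spec(395, 375, box = c(2500, 2370), ff = 0.6)
  # zero disorder: delta-like peaks at the first-shell radius
  t0 <- target_sq(spec, disorder_spec(0, 0))
  q1 <- 4 * pi / (sqrt(3) * 395)
  expect_equal(t0$q1, q1)
  expect_equal(q1, 0.0183678, tolerance = 1e-4)
  best <- t0$q[which.max(t0$S), ]
  expect_equal(sqrt(sum(best^2)), q1, tolerance = 1e-6)
  # isotropic limit: azimuthally uniform ring
  ti <- target_sq(spec, disorder_spec(0.02, Inf))
  Sm <- matrix(ti$S, 17, 72)
  ring <- Sm[which.max(rowSums(Sm)), ]
  expect_lt(var(ring) / mean(ring)^2, 0.01)
  # radial FWHM follows the Gaussian width
  t2 <- target_sq(spec, disorder_spec(0.02, 0), n_radial = 201)
  Sm2 <- matrix(t2$S, 201, 72)
  prof <- Sm2[, 1]  # azimuth 0 holds a peak
  qr <- seq(0.75, 1.25, length.out = 201) * q1
  fwhm <- diff(range(qr[prof > max(prof) / 2]))
  expect_equal(fwhm, 2.355 * 0.02 * q1, tolerance = 0.1)
})

test_that("inverse design approaches its target monotonically", {
  spec <- lattice_spec(395, 375, box = c(1600, 1580), ff = 0.55)
  ens <- suppressWarnings(
    generate_disordered(spec, disorder_spec(0.04, 0, seed = 1)))
  tr <- attr(ens, "objective_trace")
  expect_true(all(diff(tr) <= 1e-12))
  expect_gte(min_pair_distance(ens), 2 * ens$radius - 1e-6)
})

test_that("zero-disorder target relaxes to a near-perfect packing", {
  spec <- lattice_spec(395, 375, box = c(1600, 1580), ff = 0.55)
  ens0 <- make_hexagonal(spec)
  ens <- suppressWarnings(
    generate_disordered(spec, disorder_spec(0, 0, seed = 2)))
  q1 <- 4 * pi / (sqrt(3) * 395)
  qs <- cbind(q1 * cos(pi / 3 * (0:5)), q1 * sin(pi / 3 * (0:5)))
  S0 <- mean(photocolony:::sq_on_points(ens0$positions, qs))
  S1 <- mean(photocolony:::sq_on_points(ens$positions, qs))
  expect_gt(S1 / S0, 0.9)
})

test_that("isotropic target destroys bond-orientational order", {
  spec <- lattice_spec(395, 375, box = c(1600, 1580), ff = 0.55)
  ens0 <- make_hexagonal(spec)
  expect_equal(psi6(ens0), 1, tolerance = 1e-9)
  set.seed(7)
  pois <- matrix(c(runif(300, 0, 4000), runif(300, 0, 4000)), ncol = 2)
  pens <- particle_ensemble(pois, 1, c(4000, 4000), check = FALSE)
  expect_lt(psi6(pens, r_cut = 250), 0.1)
  ensi <- suppressWarnings(
    generate_disordered(spec, disorder_spec(0.05, Inf, seed = 3)))
  expect_lt(psi6(ensi), 0.3)
})
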
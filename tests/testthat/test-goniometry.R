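# frozen oracle values: direct evaluation of the grating equation and the
# specular-dispersion relation
test_that("grating equation matches closed-form evaluations", {
  expect_equal(grating_angle(0, 500, 395, -45), 45)
  expect_equal(grating_angle(1, 336, 395, 0), asin(336 / 395) * 180 / pi)
  expect_equal(grating_angle(1, 336, 395, 0), 58.2806, tolerance = 1e-4)
  expect_equal(grating_angle(-1, 500, 395, -60),
               asin(-500 / 395 + sin(pi / 3)) * 180 / pi)
  expect_equal(grating_angle(-1, 500, 395, -60), -23.5655, tolerance = 1e-4)
  expect_true(is.na(grating_angle(1, 450, 395, 0)))
})

test_that("grating equation satisfies reciprocity", {
  set.seed(1)
  for (i in 1:50) {
    m <- sample(c(-2, -1, 1, 2), 1)
    lam <- runif(1, 300, 700)
    d <- runif(1, 350, 450)
    ti <- runif(1, -80, 80)
    tm <- grating_angle(m, lam, d, ti)
    if (is.na(tm)) next
    expect_equal(grating_angle(-m, lam, d, -tm), -ti, tolerance = 1e-9)
  }
})

test_that("specular dispersion matches closed form and is monotone", {
  expect_equal(specular_shift(480, 1.4, 0), 480)
  expect_equal(specular_shift(480, 1.4, 45), 414.2759, tolerance = 1e-4)
  expect_equal(specular_shift(480, 1.4, 60), 377.1429, tolerance = 1e-4)
  th <- seq(0, 80, 5)
  expect_true(all(diff(specular_shift(480, 1.4, th)) < 0))
})

test_that("single-point grating fit reproduces the closed-form inversion", {
  pk <- data.frame(theta_out = asin(336 / 395) * 180 / pi, lambda = 336,
                   intensity = 1)
  m <- angle_map(0, c(-10, 0, 10), c(400, 500, 600), matrix(1, 3, 3))
  fit <- fit_grating(list(m), peaks = list(pk))
  expect_equal(fit$d_hat, 395, tolerance = 1e-12)
})

test_that("grating fit is exact on noiseless synthetic peak data", {
  # peaks placed exactly on the grating curves, several maps and orders
  maps <- list(); pks <- list()
  for (ti in c(0, -45, -60)) {
    lam <- c(330, 360, 390)
    rows <- NULL
    for (m in c(-2, -1, 1, 2)) {
      th <- grating_angle(m, lam, 425, ti)
      ok <- !is.na(th) & abs(th + ti) > 3
      if (any(ok))
        rows <- rbind(rows, data.frame(theta_out = th[ok], lambda = lam[ok],
                                       intensity = 1))
    }
    maps[[length(maps) + 1]] <- angle_map(ti, c(-10, 0, 10), c(400, 500, 600),
                                          matrix(1, 3, 3))
    pks[[length(pks) + 1]] <- rows
  }
  fit <- fit_grating(maps, peaks = pks)
  expect_lt(abs(fit$d_hat - 425) / 425, 1e-6)
  expect_lt(fit$residual_rms, 1e-6)
})

test_that("noiseless map pipeline recovers the generator lattice constant", {
  for (d_true in c(395, 425)) {
    maps <- lapply(c(0, -45, -60), function(t)
      synth_goniometer_map(zero_tilt(d = d_true), t))
    fit <- fit_grating(maps)
    expect_lt(abs(fit$d_hat - d_true), 0.01)
  }
})

test_that("specular fit inverts noiseless traces exactly", {
  th <- seq(-45, 45, 1)
  tr <- specular_trace(th, specular_shift(480, 1.4, th))
  fit <- fit_specular(tr)
  expect_equal(fit$lambda_p_hat, 480, tolerance = 1e-4)
  expect_equal(fit$n_avg_hat, 1.4, tolerance = 1e-3)
  expect_false(fit$lower_bound_flag)
})

test_that("flat specular trace flags the degenerate large-n limit", {
  tr <- specular_trace(seq(-45, 45, 1), rep(480, 91))
  fit <- fit_specular(tr)
  expect_true(fit$lower_bound_flag)
  expect_error(fit_specular(specular_trace(seq(-10, 10, 1),
                                           rep(480, 21))), "span")
  expect_error(fit_specular(specular_trace(seq(10, 45, 1),
                                           rep(480, 36))),
               "neighbourhood")
})

test_that("peak detection finds one spot per order and ignores noise", {
  map <- synth_goniometer_map(zero_tilt(395), 0)
  pk <- detect_diffraction_peaks(map)
  # theta_in = 0: m = +1 and m = -1 spots, symmetric
  expect_equal(nrow(pk), 2)
  expect_equal(sort(pk$theta_out), c(-1, 1) * max(pk$theta_out),
               tolerance = 1e-6)
  th_or <- grating_angle(1, pk$lambda[1], 395, 0)
  expect_lt(abs(abs(pk$theta_out[1]) - th_or), 0.1)
  # pure noise map: nothing above the prominence threshold
  set.seed(42)
  noise <- matrix(abs(rnorm(181 * 101, 0, 0.01)), 181, 101)
  nm <- angle_map(0, seq(-90, 90, 1), seq(300, 700, 4), noise)
  expect_warning(pk0 <- detect_diffraction_peaks(nm), "no diffraction peak")
  expect_equal(nrow(pk0), 0)
})
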
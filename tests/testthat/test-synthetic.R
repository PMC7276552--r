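test_that("zero-tilt noiseless maps place spots on the grating curve", {
  map <- synth_goniometer_map(zero_tilt(395), 0)
  # every intensity ridge maximum lies on the m = +/-1 curve to < 0.01 deg
  jw <- which(map$wavelength >= 320 & map$wavelength <= 360)
  for (j in jw) {
    col <- map$intensity[, j]
    col[is.na(col)] <- 0
    i <- which.max(col)
    if (col[i] < 0.05) next
    # log-parabola refined angular centre
    lr <- log(col[(i - 1):(i + 1)] + 1e-300)
    off <- 0.5 * (lr[1] - lr[3]) / (lr[1] - 2 * lr[2] + lr[3])
    th <- map$theta_out[i] + off * (map$theta_out[2] - map$theta_out[1])
    th_or <- grating_angle(sign(th), map$wavelength[j], 395, 0)
    expect_lt(abs(th - th_or), 0.01)
  }
})

test_that("maps are non-negative with the blind region flagged missing", {
  map <- synth_goniometer_map(day2_model(noise_sigma = 0.02), -45, seed = 3)
  expect_true(all(map$intensity >= 0, na.rm = TRUE))
  blind <- abs(map$theta_out - map$theta_in) <= map$blind_halfwidth
  expect_true(all(is.na(map$intensity[blind, ])))
  expect_true(all(!is.na(map$intensity[!blind, ])))
})

test_that("tilt spread turns spots into a streak crossing the specular line", {
  # uniform tilts: intensity at the specular angle well off the spot
  # wavelengths, even at normal incidence
  mu <- colony_model(d = 395, tilt = tilt_distribution(0, 1, 20))
  map <- synth_goniometer_map(mu, 0)
  i0 <- which.min(abs(map$theta_out - 20))
  spread_u <- sum(map$intensity[i0, map$wavelength < 420], na.rm = TRUE)
  m0 <- synth_goniometer_map(zero_tilt(395), 0)
  spread_0 <- sum(m0$intensity[i0, m0$wavelength < 420], na.rm = TRUE)
  expect_gt(spread_u, 10 * max(spread_0, 1e-9))
})

test_that("tail weight monotonically increases streak-to-spot ratio", {
  ratio <- sapply(c(0.05, 0.2, 0.5), function(w) {
    m <- colony_model(d = 395, tilt = tilt_distribution(5, w, 60))
    map <- synth_goniometer_map(m, -45)
    spot <- max(map$intensity, na.rm = TRUE)
    # streak sampled away from the spot and specular
    i <- which.min(abs(map$theta_out - (-70)))
    streak <- max(map$intensity[i, ], na.rm = TRUE)
    streak / spot
  })
  expect_true(all(diff(ratio) > 0))
})

test_that("synthetic image autocorrelation recovers the generator truth", {
  r <- synth_em_image(396, 356, pixel_nm = 8, n_cells = 12, seed = 1)
  a <- autocorr_lattice(r$image, 8)
  expect_lt(abs(a$d_hat - 396), 8)          # within one pixel
  expect_false(a$anisotropy_flag)
  expect_equal(r$rejections, 0L)
})

test_that("jittered noisy images still recover the lattice within 10 nm", {
  dh <- sapply(1:5, function(s)
    autocorr_lattice(synth_em_image(396, 356, pixel_nm = 8, n_cells = 12,
                                    jitter_nm = 20, noise_sigma = 10 / 255,
                                    seed = s)$image, 8)$d_hat)
  expect_lt(abs(mean(dh) - 396), 10)
})

test_that("touching disks keep the row spacing readable", {
  r <- synth_em_image(350, 350, pixel_nm = 8, n_cells = 10, seed = 4)
  lp <- lineprofile_spacing(r$image, c(400, 350, 3200, 350), 8,
                            min_level = 0.75)
  expect_lt(abs(lp$d_hat - 350), 4)
})
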
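test_that("perfect lattice shows six first-shell peaks at 4 pi/(sqrt(3) d)", {
  ens <- make_hexagonal(lattice_spec(395, 375, box = c(2500, 2370),
                                     ff = 0.6))
  sq <- sq_points(ens)
  q1 <- 4 * pi / (sqrt(3) * 395)
  expect_lt(abs(sq$q1_hat - q1), diff(sq$radial$q[1:2]) + 1e-9)
  az <- sq$azimuthal[is.finite(sq$azimuthal$S), ]
  top <- az[order(-az$S), ][1:6, "phi_deg"]
  expect_equal(sort(round(top / 60) * 60 %% 360),
               sort(c(0, 60, 120, 180, 240, 300)), tolerance = 1e-9)
})

test_that("Poisson points have a flat structure factor near 1", {
  set.seed(3)
  pp <- particle_ensemble(cbind(runif(500, 0, 5000), runif(500, 0, 5000)),
                          1, c(5000, 5000), check = FALSE)
  sp <- sq_points(pp, q_max = 0.03)
  away <- sp$radial$S[sp$radial$q > 0.006]
  expect_lt(abs(mean(away) - 1), 3 / sqrt(500))
})

test_that("direct-sum and image-FFT estimators agree on the first shell", {
  r <- synth_em_image(395, 356, pixel_nm = 6, n_cells = 12, seed = 3)
  si <- suppressWarnings(sq_image(r$image, 6))
  sp <- sq_points(r$truth)
  step <- max(diff(si$radial$q[1:2]), diff(sp$radial$q[1:2]))
  expect_lt(abs(si$q1_hat - sp$q1_hat), step + 1e-9)
})

test_that("image spectrum of a constant image vanishes off-centre", {
  si <- sq_image(matrix(1, 64, 64), 6)
  expect_lt(max(si$S[sqrt(outer(si$qx^2, si$qy^2, "+")) > 0.01]), 1e-20)
})

test_that("jittered images keep azimuthal peaks at reduced height", {
  s0 <- suppressWarnings(
    sq_image(synth_em_image(395, 356, 6, 12, seed = 5)$image, 6))
  sj <- suppressWarnings(
    sq_image(synth_em_image(395, 356, 6, 12, jitter_nm = 20,
                            seed = 5)$image, 6))
  a0 <- s0$azimuthal$S; aj <- sj$azimuthal$S
  contrast <- function(a) (max(a, na.rm = TRUE) - median(a, na.rm = TRUE))
  expect_gt(contrast(aj), 0)            # peaks persist
  expect_lt(contrast(aj), contrast(a0)) # but are reduced
})

test_that("white-noise images raise the no-lattice error", {
  set.seed(2)
  wn <- matrix(runif(200 * 200), 200)
  expect_error(autocorr_lattice(wn, 8), "no lattice")
})

test_that("line-profile spacing depends on direction as hexagonal geometry", {
  img <- memo("lp_img", synth_em_image(395, 356, pixel_nm = 6,
                                       n_cells = 12, seed = 2))
  along <- lineprofile_spacing(img$image, c(450, 395, 4200, 395), 6)
  expect_lt(abs(along$d_hat - 395), 2)
  expect_lt(along$se, 1)
  normal <- lineprofile_spacing(img$image, c(494, 300, 494, 3800), 6)
  expect_lt(abs(normal$d_hat - sqrt(3) / 2 * 395), 2)
  expect_equal(normal$direction_deg, 90)
})

test_that("blur leaves the line-profile spacing unchanged", {
  blurred <- synth_em_image(395, 356, pixel_nm = 6, n_cells = 12,
                            blur_sigma_px = 2, seed = 2)
  lp <- lineprofile_spacing(blurred$image, c(450, 395, 4200, 395), 6)
  expect_lt(abs(lp$d_hat - 395), 2)
})

test_that("autocorrelation and line-profile estimates are consistent", {
  img <- memo("lp_img", synth_em_image(395, 356, pixel_nm = 6,
                                       n_cells = 12, seed = 2))
  ac <- autocorr_lattice(img$image, 6)
  lp <- lineprofile_spacing(img$image, c(450, 395, 4200, 395), 6)
  expect_lt(abs(ac$d_hat - lp$d_hat), 2 * (ac$se + lp$se) + 4)
})

test_that("anisotropic pixel scaling raises the anisotropy flag", {
  img <- memo("lp_img", synth_em_image(395, 356, pixel_nm = 6,
                                       n_cells = 12, seed = 2))$image
  xs <- seq(1, ncol(img) - 1, by = 1.1)
  x0 <- floor(xs); fx <- xs - x0
  im2 <- img[, x0] * (1 - rep(fx, each = nrow(img))) +
    img[, x0 + 1] * rep(fx, each = nrow(img))
  im2 <- matrix(im2, nrow(img))
  a <- autocorr_lattice(im2, 6)
  expect_true(a$anisotropy_flag)
})
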
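# small commensurate fixtures keep these solver checks fast; the
# paper-scale experiments live in the acceptance suite
empty_box_run <- function() memo("fdtd_empty", {
  e0 <- particle_ensemble(matrix(numeric(), 0, 2), 187.5, c(1200, 790),
                         periodic_y = TRUE)
  run_fdtd(e0, config = fast_cfg())
})

tiny_run <- function() memo("fdtd_tiny", {
  run_fdtd(make_hexagonal(tiny_lattice()), config = fast_cfg())
})

test_that("an empty background reflects nothing", {
  ir <- empty_box_run()
  expect_lt(max(abs(ir$R_total)), 1e-3)
  expect_equal(ir$transmission, rep(1, length(ir$wavelength)),
               tolerance = 0.02)
})

test_that("energy is conserved to the numerical-dispersion allowance", {
  ir <- tiny_run()
  expect_lt(ir$energy_balance, 0.02)
  expect_true(all(ir$R_total + ir$transmission > 0.98))
  expect_true(all(ir$R_total + ir$transmission < 1.02))
})

test_that("identical structure and config give bit-identical spectra", {
  ir1 <- tiny_run()
  ir2 <- run_fdtd(make_hexagonal(tiny_lattice()), config = fast_cfg())
  expect_identical(ir1$R_total, ir2$R_total)
  expect_identical(ir1$R_specular, ir2$R_specular)
})

test_that("specular and diffracted channels sum to the total", {
  ir <- tiny_run()
  resid <- abs(ir$R_specular + ir$R_diffracted - ir$R_total)
  expect_lt(max(resid), 0.01 * max(ir$R_total))
  # evanescent-order noise can leave tiny negative diffracted flux
  expect_lt(max(ir$R_specular - ir$R_total), 0.01 * max(ir$R_total))
})

test_that("no diffracted power beyond the first-order cutoff", {
  ir <- tiny_run()
  # lateral period 395 in n_env = 1.34: orders evanescent above 529 nm
  beyond <- ir$wavelength > 1.05 * 1.34 * 395
  expect_lt(max(abs(ir$R_diffracted[beyond])), 1e-3)
  dec <- decompose_specular(ir)
  expect_true(any(dec$near_cutoff))
})

test_that("flat multilayers agree with the transfer-matrix solver", {
  n_bi <- 8
  st <- multilayer_stack(rep(c(1.38, 1.34), n_bi), rep(c(90, 80), n_bi),
                         n_ambient = 1.34, n_substrate = 1.34)
  lam <- seq(300, 700, by = 4)
  sp <- tmm_reflectance(st, 0, "TM", lam)
  widths <- rep(c(90, 80), n_bi)
  cells <- rep(rep(c(TRUE, FALSE), n_bi), times = widths / 10)
  img <- matrix(rep(as.numeric(cells), each = 32), nrow = 32)
  ir <- run_fdtd_image(img, pixel_nm = 10,
                       config = fdtd_config(n_steps = 16384,
                                            wavelengths = lam))
  rms <- sqrt(mean((ir$R_total - sp$R)^2))
  expect_lt(rms / max(sp$R), 0.03)
  expect_equal(lam[which.max(ir$R_total)], lam[which.max(sp$R)],
               tolerance = 4.1)
})

test_that("image-rendered and ensemble-rasterized lattices agree", {
  ens <- make_hexagonal(tiny_lattice())
  ir1 <- tiny_run()
  # render the same ensemble as a 5 nm binary image (rows = y)
  px <- 5
  nyp <- round(ens$box[2] / px); nxp <- round(ens$box[1] / px)
  xs <- (seq_len(nxp) - 0.5) * px
  ys <- (seq_len(nyp) - 0.5) * px
  img <- matrix(0, nyp, nxp)
  for (k in seq_len(nrow(ens$positions))) {
    dy <- ys - ens$positions[k, 2]
    dy <- dy - round(dy / ens$box[2]) * ens$box[2]
    hit <- outer(dy^2, (xs - ens$positions[k, 1])^2, "+") <= ens$radius^2
    img[hit] <- 1
  }
  ir2 <- run_fdtd_image(img, pixel_nm = px, config = fast_cfg())
  rms <- sqrt(mean((ir1$R_total - ir2$R_total)^2))
  expect_lt(rms / max(ir1$R_total), 0.2)
  i1 <- which.max(ir1$R_total); i2 <- which.max(ir2$R_total)
  expect_lt(abs(ir1$wavelength[i1] - ir2$wavelength[i2]), 11)
})

test_that("peak positions are stable under grid refinement", {
  spec <- lattice_spec(395, 375, box = c(1600, 1580), ff = 0.55)
  lam <- seq(430, 520, 2)
  ir10 <- run_fdtd(make_hexagonal(spec),
                   config = fdtd_config(grid_step = 10, n_steps = 8192,
                                        wavelengths = lam))
  ir5 <- run_fdtd(make_hexagonal(spec),
                  config = fdtd_config(grid_step = 5, n_steps = 16384,
                                       wavelengths = lam))
  p10 <- peak_metrics(ir10$wavelength, ir10$R_total, c(430, 520))
  p5 <- peak_metrics(ir5$wavelength, ir5$R_total, c(430, 520))
  expect_lt(abs(p10["lambda"] - p5["lambda"]), 3)
})

test_that("energy violations abort with diagnostics", {
  e0 <- particle_ensemble(matrix(numeric(), 0, 2), 187.5, c(1200, 790),
                          periodic_y = TRUE)
  cfg <- fast_cfg()
  cfg$energy_tol <- 1e-9
  st <- make_hexagonal(tiny_lattice())
  expect_error(run_fdtd(st, config = cfg), "energy conservation")
})
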
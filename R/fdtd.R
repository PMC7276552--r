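#' FDTD run configuration
#'
#' 2D TM Yee grid, periodic in the lateral (y) direction, CPML-terminated
#' along the propagation (x) direction. A uniform soft line source behind
#' the structure launches a broadband differentiated-Gaussian plane-wave
#' pulse at normal incidence; reflectance is obtained from running discrete
#' Fourier transforms at monitor lines via a matched reference run on the
#' empty background (the air-sample interface is not included: the
#' background is the matrix index everywhere outside the disks).
#'
#' @param grid_step Yee cell size in nm (default 10; should satisfy
#'   `grid_step <= a / 15` for disk diameter `a` -- callers are warned
#'   otherwise).
#' @param n_steps time steps (default 16384; the Courant factor is 0.5 so
#'   one step advances `0.5 * grid_step / c`).
#' @param npml CPML thickness in cells (>= 10; default 20).
#' @param pad_nm free background between PML and structure on each side.
#' @param wavelengths spectral grid in nm for the running DFTs.
#' @param pulse_center_nm centre wavelength of the source pulse (sets the
#'   pulse width; the default 430 covers 280-740 nm).
#' @param energy_tol maximum tolerated `|R + T - 1|` (numerical-dispersion
#'   allowance, default 0.02); a run violating it aborts with diagnostics.
#' @param courant Courant factor (<= 1/sqrt(2)).
#' @return object of class `fdtd_config`.
#' @export
fdtd_config <- function(grid_step = 10, n_steps = 16384, npml = 20,
                        pad_nm = 400, wavelengths = seq(280, 740, by = 2),
                        pulse_center_nm = 430, energy_tol = 0.02,
                        courant = 0.5) {
  stopifnot(grid_step > 0, npml >= 10, courant <= 1 / sqrt(2) + 1e-12)
  structure(list(grid_step = grid_step, n_steps = n_steps, npml = npml,
                 pad_nm = pad_nm, wavelengths = wavelengths,
                 pulse_center_nm = pulse_center_nm,
                 energy_tol = energy_tol, courant = courant),
            class = "fdtd_config")
}

.fdtd_cache <- new.env(parent = emptyenv())

# raw solver wrapper: returns monitor DFTs for a given permittivity map
fdtd_fields <- function(eps, config, n_env) {
  dx <- config$grid_step
  dt <- config$courant * dx
  nx <- nrow(eps); ny <- ncol(eps)
  npml <- config$npml
  isrc <- npml + 6
  imon_r <- npml + 12
  imon_t <- nx - npml - 6
  tt <- seq_len(config$n_steps) * dt
  tau <- config$pulse_center_nm / (2 * pi)
  t0 <- 6 * tau
  src <- -(tt - t0) / tau^2 * exp(-(tt - t0)^2 / (2 * tau^2))
  om <- 2 * pi / config$wavelengths
  out <- fdtd_core(eps, dx, dt, config$n_steps, npml,
                   isrc - 1L, imon_r - 1L, imon_t - 1L, src, om, n_env)
  out$ny <- ny
  out
}

fdtd_reference <- function(nx, ny, config, n_env) {
  key <- paste(nx, ny, config$grid_step, config$n_steps, config$npml,
               n_env, config$pulse_center_nm,
               length(config$wavelengths), min(config$wavelengths),
               max(config$wavelengths), sep = "|")
  if (!is.null(.fdtd_cache[[key]])) return(.fdtd_cache[[key]])
  ref <- fdtd_fields(matrix(n_env^2, nx, ny), config, n_env)
  .fdtd_cache[[key]] <- ref
  ref
}

# flux through a monitor line, per wavelength: +x direction positive
fdtd_flux <- function(E, H, dy) -0.5 * rowSums(Re(E * Conj(H))) * dy

#' Run the FDTD solver on a particle ensemble
#'
#' Rasterizes the disks onto the Yee grid with sub-pixel area-fraction
#' smoothing of boundary cells, embeds the ensemble box between padding and
#' CPML along x, runs reference and scattering simulations, and returns
#' angle-integrated total reflectance (total backward flux through the
#' monitor line, equivalent to the -90..90 degree angular integration for a
#' line spanning the periodic cell), the zero-order (specular) component,
#' and the per-order decomposition.
#'
#' @param ensemble a [particle_ensemble()]; its box y-extent must be an
#'   integer number of grid cells (the periodic cell).
#' @param n_bac,n_env disk and background refractive indices.
#' @param config an [fdtd_config()].
#' @return object of class `integrated_reflectance`: `wavelength`,
#'   `R_total`, `R_specular`, `R_diffracted`, `transmission`,
#'   `energy_balance` (max |R+T-1|), `orders` (per-order reflected power
#'   matrix), `cutoff_flag` (wavelengths within 3 percent of a diffraction
#'   onset).
#' @export
run_fdtd <- function(ensemble, n_bac = 1.38, n_env = 1.34,
                     config = fdtd_config()) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  dx <- config$grid_step
  if (dx > 2 * ensemble$radius / 15)
    warning("grid step coarser than diameter/15; staircasing may shift peaks")
  ny <- round(ensemble$box[2] / dx)
  if (abs(ny * dx - ensemble$box[2]) > 0.005 * ensemble$box[2])
    stop("box y-extent must be commensurate with the grid step")
  pad <- ceiling(config$pad_nm / dx)
  nx <- 2 * (config$npml + pad) + ceiling(ensemble$box[1] / dx) + 12
  x_off <- (config$npml + pad + 12) * dx
  eps <- rasterize_disks(nx, ny, dx, ensemble$positions, x_off,
                         ensemble$radius, n_bac^2, n_env^2)
  fdtd_postprocess(eps, nx, ny, config, n_env)
}

#' Run the FDTD solver on a binarized cross-section image
#'
#' Foreground pixels become cell material (`n_bac`), background the matrix
#' (`n_env`). The image is resampled onto the Yee grid (nearest neighbour),
#' its y-extent forming the periodic cell, and the [run_fdtd()] machinery
#' is applied. Non-binary images are thresholded as in [sq_image()].
#'
#' @param img matrix in \[0, 1\] (rows = y; x is the propagation
#'   direction).
#' @param pixel_nm image pixel size in nm.
#' @param n_bac,n_env material indices.
#' @param config an [fdtd_config()].
#' @return an `integrated_reflectance` (see [run_fdtd()]).
#' @export
run_fdtd_image <- function(img, pixel_nm, n_bac = 1.38, n_env = 1.34,
                           config = fdtd_config()) {
  if (length(unique(as.vector(img))) > 2)
    img <- img > otsu_threshold(img)
  dx <- config$grid_step
  ny <- max(1, round(nrow(img) * pixel_nm / dx))
  nx_img <- max(1, round(ncol(img) * pixel_nm / dx))
  iy <- pmin(pmax(round((seq_len(ny) - 0.5) * dx / pixel_nm + 0.5), 1),
             nrow(img))
  ix <- pmin(pmax(round((seq_len(nx_img) - 0.5) * dx / pixel_nm + 0.5), 1),
             ncol(img))
  block <- img[iy, ix, drop = FALSE] > 0.5
  pad <- ceiling(config$pad_nm / dx)
  nx <- 2 * (config$npml + pad) + nx_img + 12
  eps <- matrix(n_env^2, nx, ny)
  x0 <- config$npml + pad + 12
  # image rows = y, columns = x; eps rows = x, columns = y
  eps[x0 + seq_len(nx_img) - 1, ] <-
    t(ifelse(block, n_bac^2, n_env^2))
  fdtd_postprocess(eps, nx, ny, config, n_env)
}

# area-fraction rasterization of disks (periodic in y)
rasterize_disks <- function(nx, ny, dx, pos, x_off, R, eps_in, eps_out,
                            ss = 4) {
  eps <- matrix(eps_out, nx, ny)
  Ly <- ny * dx
  xs <- (seq_len(nx) - 0.5) * dx
  ys <- (seq_len(ny) - 0.5) * dx
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  for (p in seq_len(nrow(pos))) {
    cx <- pos[p, 1] + x_off
    cy <- pos[p, 2]
    for (i in which(abs(xs - cx) <= R + dx)) {
      dyv <- ys - cy
      dyv <- dyv - round(dyv / Ly) * Ly
      for (j in which(abs(dyv) <= R + dx)) {
        rc <- sqrt((xs[i] - cx)^2 + dyv[j]^2)
        if (rc < R - 1.5 * dx) eps[i, j] <- eps_in
        else {
          f <- mean(outer(off * dx + (xs[i] - cx), off * dx + dyv[j],
                          function(aa, bb) aa^2 + bb^2 < R^2))
          eps[i, j] <- eps[i, j] + f * (eps_in - eps_out)
        }
      }
    }
  }
  eps
}

# shared post-processing: reference run, flux normalization, order split
fdtd_postprocess <- function(eps, nx, ny, config, n_env) {
  dx <- config$grid_step
  ref <- fdtd_reference(nx, ny, config, n_env)
  tot <- fdtd_fields(eps, config, n_env)
  lam <- config$wavelengths
  P_inc <- fdtd_flux(ref$EzR, ref$HyR, dx)
  Es <- tot$EzR - ref$EzR
  Hs <- tot$HyR - ref$HyR
  P_r <- -fdtd_flux(Es, Hs, dx)
  P_t <- fdtd_flux(tot$EzT, tot$HyT, dx)
  R_total <- P_r / P_inc
  Tr <- P_t / P_inc
  # lateral Fourier split of the scattered field
  Em <- t(apply(Es, 1, fft)) / ny
  Hm <- t(apply(Hs, 1, fft)) / ny
  P_orders <- -(-0.5 * Re(Em * Conj(Hm)) * ny * dx)
  R_orders <- sweep(P_orders, 1, P_inc, "/")
  R_spec <- R_orders[, 1]
  R_diff <- rowSums(R_orders[, -1, drop = FALSE])
  # diffraction-onset flags: order m propagates in the background when
  # |2 pi m / Ly| < n_env * omega
  Ly <- ny * dx
  m_ord <- seq_len(ny) - 1
  m_ord[m_ord > ny / 2] <- m_ord[m_ord > ny / 2] - ny
  cutoff_flag <- vapply(lam, function(l) {
    kyn <- abs(m_ord[-1]) * l / (n_env * Ly)
    any(abs(kyn - 1) < 0.03)
  }, logical(1))
  bal <- abs(R_total + Tr - 1)
  if (max(bal) > config$energy_tol)
    stop(sprintf(paste0("energy conservation violated: max |R+T-1| = %.3g",
                        " at %g nm (residual field energy %.3g);",
                        " increase n_steps"),
                 max(bal), lam[which.max(bal)], tot$residual_energy))
  structure(list(wavelength = lam, R_total = R_total, R_specular = R_spec,
                 R_diffracted = R_diff, transmission = Tr,
                 energy_balance = max(bal), orders = R_orders,
                 order_index = m_ord, cutoff_flag = cutoff_flag,
                 polarization = "TM"),
            class = "integrated_reflectance")
}

#' @export
print.integrated_reflectance <- function(x, ...) {
  cat(sprintf("<integrated_reflectance> %d wavelengths (%g-%g nm); max R_total = %.4g; energy balance %.2g\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              max(x$R_total), x$energy_balance))
  invisible(x)
}

#' Specular / diffracted decomposition of an FDTD result
#'
#' The lateral Fourier split computed by [run_fdtd()]: zero order is the
#' specular channel, the remaining propagating orders the diffracted
#' channel; their sum equals the total reflectance to numerical precision.
#' Wavelengths within 3 percent of a diffraction onset (an order turning
#' evanescent, where the split is ambiguous) are flagged.
#'
#' @param ir an `integrated_reflectance`.
#' @return data frame: `wavelength`, `R_specular`, `R_diffracted`,
#'   `R_total`, `near_cutoff`.
#' @export
decompose_specular <- function(ir) {
  stopifnot(inherits(ir, "integrated_reflectance"))
  data.frame(wavelength = ir$wavelength, R_specular = ir$R_specular,
             R_diffracted = ir$R_diffracted, R_total = ir$R_total,
             near_cutoff = ir$cutoff_flag)
}

#' Peaks of a reflectance spectrum
#'
#' Local maxima with prominence above `min_prominence` (fraction of the
#' spectrum maximum), sub-grid positions by quadratic interpolation, and
#' full width at half the prominence-referenced height.
#'
#' @param wavelength,y spectrum.
#' @param min_prominence prominence threshold relative to `max(y)`.
#' @return data frame: `lambda`, `height`, `prominence`, `fwhm`.
#' @export
spectrum_peaks <- function(wavelength, y, min_prominence = 0.05) {
  n <- length(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  out <- NULL
  for (i in idx) {
    # prominence: drop to the highest of the two bracketing minima
    l <- i; while (l > 1 && y[l - 1] <= y[l]) l <- l - 1
    r <- i; while (r < n && y[r + 1] <= y[r]) r <- r + 1
    base <- max(min(y[l:i]), min(y[i:r]))
    prom <- y[i] - base
    if (prom < min_prominence * max(y)) next
    den <- y[i - 1] - 2 * y[i] + y[i + 1]
    offs <- if (abs(den) < 1e-18) 0 else 0.5 * (y[i - 1] - y[i + 1]) / den
    lam0 <- wavelength[i] + offs * (wavelength[2] - wavelength[1])
    half <- base + prom / 2
    il <- i; while (il > 1 && y[il] > half) il <- il - 1
    ir_ <- i; while (ir_ < n && y[ir_] > half) ir_ <- ir_ + 1
    xl <- if (y[il] <= half && il < i)
      approx(y[il:(il + 1)], wavelength[il:(il + 1)], half)$y
    else wavelength[il]
    xr <- if (y[ir_] <= half && ir_ > i)
      approx(y[(ir_ - 1):ir_], wavelength[(ir_ - 1):ir_], half)$y
    else wavelength[ir_]
    out <- rbind(out, data.frame(lambda = lam0, height = y[i],
                                 prominence = prom, fwhm = xr - xl))
  }
  if (is.null(out))
    out <- data.frame(lambda = numeric(), height = numeric(),
                      prominence = numeric(), fwhm = numeric())
  out[order(-out$prominence), ]
}

#' Peak height and width against a diffuse baseline
#'
#' Tracks a Bragg peak inside a wavelength window on spectra where the
#' peak may sit on (or sink into) a diffuse-scattering background: height
#' is measured above the lower-quantile baseline of the window, and the
#' width at half that height, interpolated outward from the window
#' maximum. Used by [disorder_sweep()] for the 473 nm-analogue metrics.
#'
#' @param wavelength,y spectrum.
#' @param window wavelength window `c(lo, hi)`.
#' @param baseline_q baseline quantile (default 0.15).
#' @return named vector `c(lambda, height, fwhm)`.
#' @export
peak_metrics <- function(wavelength, y, window = c(420, 540),
                         baseline_q = 0.15) {
  w <- wavelength >= window[1] & wavelength <= window[2]
  x <- wavelength[w]; yy <- y[w]
  i <- which.max(yy)
  base <- unname(quantile(yy, baseline_q))
  half <- base + (yy[i] - base) / 2
  il <- i; while (il > 1 && yy[il] > half) il <- il - 1
  ir <- i; while (ir < length(yy) && yy[ir] > half) ir <- ir + 1
  xl <- if (yy[il] <= half && il < i)
    approx(yy[il:(il + 1)], x[il:(il + 1)], half)$y else x[1]
  xr <- if (yy[ir] <= half && ir > i)
    approx(yy[(ir - 1):ir], x[(ir - 1):ir], half)$y else x[length(x)]
  c(lambda = x[i], height = yy[i] - base, fwhm = xr - xl)
}

#' Disorder sweep of the integrated reflectance
#'
#' For each disorder specification, generates `n_realizations` independent
#' ensembles by structure-factor-targeted inverse design
#' ([generate_disordered()]), runs the FDTD solver on each, and averages
#' the spectra. Peak metrics (height and FWHM of the long-wavelength
#' Bragg-peak analogue) are tabulated per disorder level.
#'
#' @param spec a [lattice_spec()].
#' @param disorders list of [disorder_spec()]s (their `seed`s orchestrate
#'   the realizations: realization `r` uses `seed + r - 1`).
#' @param n_bac,n_env material indices.
#' @param config an [fdtd_config()].
#' @param peak_window wavelength window of the tracked peak (default
#'   `c(420, 540)`, the 473 nm analogue).
#' @param anneal_iter annealing move budget forwarded to
#'   [generate_disordered()].
#' @return list with `spectra` (list of mean `integrated_reflectance`-like
#'   lists with realization spread), and `peaks` (data frame: sigma_k,
#'   sigma_phi, and height/fwhm of the tracked peak in the total and in
#'   the specular channel; see the methods vignette for which channel
#'   resolves which disorder trend).
#' @export
disorder_sweep <- function(spec, disorders, n_bac = 1.38, n_env = 1.34,
                           config = fdtd_config(), peak_window = c(420, 540),
                           anneal_iter = NULL) {
  spectra <- list()
  peaks <- NULL
  for (k in seq_along(disorders)) {
    ds <- disorders[[k]]
    runs <- vector("list", ds$n_realizations)
    failed <- 0L
    for (r in seq_len(ds$n_realizations)) {
      ens <- if (ds$sigma_k == 0 && ds$sigma_phi == 0)
        make_hexagonal(spec)
      else
        generate_disordered(spec,
                            disorder_spec(ds$sigma_k, ds$sigma_phi,
                                          seed = ds$seed + r - 1,
                                          n_realizations = 1),
                            n_iter = anneal_iter)
      # strongly scattering samples can trap slowly decaying modes; on an
      # energy-balance abort, retry once with a doubled run time
      run_once <- function(cf) tryCatch(run_fdtd(ens, n_bac, n_env, cf),
                                        error = function(e) e)
      res <- run_once(config)
      if (inherits(res, "error")) {
        cfg2 <- config
        cfg2$n_steps <- 2L * config$n_steps
        res <- run_once(cfg2)
      }
      if (inherits(res, "error")) {
        warning("realization ", r, " failed: ", conditionMessage(res))
        res <- NULL
      }
      runs[r] <- list(res)
      if (is.null(runs[[r]])) failed <- failed + 1L
      if (ds$sigma_k == 0 && ds$sigma_phi == 0) {
        runs <- runs[1]
        break  # deterministic perfect lattice: one run suffices
      }
    }
    runs <- runs[!vapply(runs, is.null, logical(1))]
    if (!length(runs)) stop("all realizations failed for disorder level ", k)
    Rmat <- sapply(runs, function(x) x$R_total)
    Rmean <- rowMeans(Rmat)
    Rspec <- rowMeans(sapply(runs, function(x) x$R_specular))
    lam <- runs[[1]]$wavelength
    met <- peak_metrics(lam, Rmean, peak_window)
    met_s <- peak_metrics(lam, Rspec, peak_window)
    height <- met["height"]
    fwhm <- met["fwhm"]
    spectra[[k]] <- list(wavelength = lam, R_total = Rmean,
                         R_specular = Rspec,
                         R_spread = apply(Rmat, 1, sd),
                         n_realizations = length(runs), failed = failed)
    peaks <- rbind(peaks, data.frame(sigma_k = ds$sigma_k,
                                     sigma_phi = ds$sigma_phi,
                                     height = height, fwhm = fwhm,
                                     height_spec = met_s["height"],
                                     fwhm_spec = met_s["fwhm"],
                                     n_ok = length(runs)))
  }
  list(spectra = spectra, peaks = peaks)
}
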
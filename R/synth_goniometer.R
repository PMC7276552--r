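#' Synthesize an angle-resolved goniometer map
#'
#' Forward model of the scattering response of a polycrystalline colony for
#' one incidence angle. Domains tilted by alpha see an effective incidence
#' `theta_in - alpha` and their diffracted directions are rotated back by
#' `+alpha`, so order `m` of a domain at tilt alpha appears at
#' `theta_m(alpha) = alpha + asin(m lambda / d - sin(theta_in - alpha))`.
#' The map is the tilt-density-weighted sum of Gaussian spot kernels along
#' these curves for all propagating orders (order weight `1/m^2`), each
#' order carrying a spectral envelope centred on the tilt-dependent
#' diffraction resonance `lambda_res(beta)` (see below), plus the specular
#' ridge at
#' `theta_out = 2 alpha - theta_in` with wavelength given by the specular
#' dispersion of the effective incidence, plus optional i.i.d. Gaussian
#' intensity noise clipped at zero. The blind region around `theta_in` is
#' blanked to `NA`.
#'
#' The diffraction resonance of a domain depends on its effective
#' incidence `beta`: at normal incidence the first-order peak sits at
#' `lambda_d` (~0.85 d), while obliquely lit domains resonate at longer
#' wavelengths (the green large-angle spots). This is modelled by the
#' strictly monotone dispersion
#' `lambda_res(beta) = lambda_d / cos(c * beta_med)` with
#' `beta_med = asin(sin beta / n_avg)` the refracted angle and `c` an
#' effective dispersion exponent. The locus of spots over tilts is then
#' exactly invariant under the incidence correction of
#' [extract_and_correct_streak()], which is the observed overlay
#' behaviour.
#'
#' @param model a [colony_model()].
#' @param theta_in incidence angle in degrees.
#' @param theta_out,wavelength output grids (defaults: 0.5 deg over
#'   \[-90, 90\]; 2 nm over 300-700 nm).
#' @param orders diffraction orders to include (default `c(-2,-1,1,2)`).
#' @param kernel_theta,kernel_lambda Gaussian spot widths (1.5 deg, 5 nm):
#'   instrument-like smoothing. The angular kernel applies to every
#'   feature; the wavelength kernel sets the specular ridge width (the
#'   diffraction curves are already smooth in wavelength through the
#'   resonance envelope).
#' @param specular_strength intensity of the specular ridge relative to the
#'   first diffraction order (default 2; measured specular lines are
#'   stronger than the diffraction spots, absolute intensities are not
#'   quantitative).
#' @param envelope_sigma spectral width of the diffraction resonance
#'   envelope in nm (default 15).
#' @param resonance_dispersion dispersion exponent `c` (default 1.25,
#'   which places the oblique resonance near 500 nm at 60 degrees
#'   effective incidence for the day-2 lattice).
#' @param n_tilt number of tilt quadrature samples over +/- tail_range.
#' @param seed RNG seed for the noise and pointing jitter (optional).
#' @return an [angle_map()]; the per-order pointing offsets actually used
#'   are attached as attribute `"jitter"`.
#' @export
synth_goniometer_map <- function(model, theta_in,
                                 theta_out = seq(-90, 90, by = 0.5),
                                 wavelength = seq(300, 700, by = 2),
                                 orders = c(-2, -1, 1, 2),
                                 kernel_theta = 1.5, kernel_lambda = 5,
                                 specular_strength = 2,
                                 envelope_sigma = 15,
                                 resonance_dispersion = 1.25,
                                 n_tilt = 121, seed = NULL) {
  stopifnot(inherits(model, "colony_model"), abs(theta_in) <= 90)
  if (!is.null(seed)) set.seed(seed)
  tl <- model$tilt
  if (tl$core_halfwidth == 0 && tl$tail_weight == 0) {
    alphas <- 0
    wts <- 1
  } else {
    rng <- max(tl$tail_range, 4 * tl$core_halfwidth)
    alphas <- seq(-rng, rng, length.out = n_tilt)
    wts <- tilt_density(tl, alphas)
    wts <- wts / sum(wts)
  }
  jitter <- if (model$angle_jitter > 0)
    rnorm(length(orders), 0, model$angle_jitter)
  else rep(0, length(orders))
  names(jitter) <- as.character(orders)

  I <- matrix(0, length(theta_out), length(wavelength))
  n_avg <- n_average(model)
  for (ia in seq_along(alphas)) {
    al <- alphas[ia]
    w_al <- wts[ia]
    if (w_al < 1e-9) next
    th_eff <- theta_in - al
    if (abs(th_eff) >= 90) next
    # diffraction orders; resonance follows the tilt-dependent Bragg
    # condition of the domain
    b_med <- asin(abs(sin(th_eff * pi / 180)) / n_avg)
    lam_res <- model$lambda_d / cos(pmin(resonance_dispersion * b_med, 1.45))
    for (io in seq_along(orders)) {
      m <- orders[io]
      th_m <- grating_angle(m, wavelength, model$d, th_eff) + al + jitter[io]
      prop <- !is.na(th_m)
      if (!any(prop)) next
      env <- exp(-(wavelength - lam_res)^2 / (2 * envelope_sigma^2))
      amp <- w_al / m^2 * env
      for (j in which(prop)) {
        if (amp[j] < 1e-8) next
        I[, j] <- I[, j] + amp[j] *
          exp(-(theta_out - th_m[j])^2 / (2 * kernel_theta^2))
      }
    }
    # specular ridge of the tilted domain
    th_s <- 2 * al - theta_in
    if (abs(th_s) <= 90) {
      lam_s <- specular_shift(model$lambda_p, n_avg, th_eff)
      spot <- exp(-(theta_out - th_s)^2 / (2 * kernel_theta^2)) %o%
        exp(-(wavelength - lam_s)^2 / (2 * kernel_lambda^2))
      I <- I + specular_strength * w_al * spot
    }
  }
  I <- I / max(I)
  if (model$noise_sigma > 0)
    I <- pmax(I + matrix(rnorm(length(I), 0, model$noise_sigma),
                         nrow(I)), 0)
  out <- angle_map(theta_in, theta_out, wavelength, I)
  attr(out, "jitter") <- jitter
  out
}

#' Synthesize a specular goniometry trace
#'
#' Evaluates the specular dispersion relation of the model on an
#' incidence-angle grid and adds Gaussian wavelength noise, emulating the
#' specular configuration in which the detector mirrors the source.
#'
#' @param model a [colony_model()].
#' @param theta_in incidence-angle grid (default 1 deg over \[-45, 45\]).
#' @param noise_sigma_nm Gaussian noise on the ridge wavelength, nm.
#' @param seed RNG seed (optional).
#' @return a [specular_trace()].
#' @export
synth_specular_trace <- function(model, theta_in = seq(-45, 45, by = 1),
                                 noise_sigma_nm = 0, seed = NULL) {
  stopifnot(inherits(model, "colony_model"))
  if (!is.null(seed)) set.seed(seed)
  lam <- specular_shift(model$lambda_p, n_average(model), theta_in)
  if (noise_sigma_nm > 0)
    lam <- lam + rnorm(length(lam), 0, noise_sigma_nm)
  specular_trace(theta_in, lam)
}
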
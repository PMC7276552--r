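#' Domain-tilt distribution of a colony
#'
#' Most crystalline domains grow flat on the agar surface, with a spread of
#' small tilts of about +/-10 degrees; a minority of domains is tilted much
#' more strongly, which is what stretches the diffraction spot into a streak
#' across the whole angular range. The density is a zero-mode mixture of a
#' Gaussian core and a uniform tail:
#' `(1 - tail_weight) * N(0, core_halfwidth^2) + tail_weight * U(-tail_range, tail_range)`.
#'
#' @param core_halfwidth standard deviation of the Gaussian core in degrees
#'   (default 5, giving ~ +/-10 degrees of support for the dominant flat
#'   domains).
#' @param tail_weight fraction of domains in the broad tail, in \[0, 1\]
#'   (default 0.1).
#' @param tail_range half-range of the uniform tail in degrees (default 60).
#' @return object of class `tilt_distribution`.
#' @export
tilt_distribution <- function(core_halfwidth = 5, tail_weight = 0.1,
                              tail_range = 60) {
  stopifnot(core_halfwidth >= 0, tail_weight >= 0, tail_weight <= 1,
            tail_range >= 0)
  structure(list(core_halfwidth = core_halfwidth, tail_weight = tail_weight,
                 tail_range = tail_range),
            class = "tilt_distribution")
}

#' @rdname tilt_distribution
#' @param tilt a `tilt_distribution`.
#' @param alpha tilt angles in degrees.
#' @return `tilt_density()`: density values (integrates to 1 over alpha).
#' @export
tilt_density <- function(tilt, alpha) {
  core <- if (tilt$core_halfwidth > 0)
    dnorm(alpha, 0, tilt$core_halfwidth)
  else as.numeric(alpha == 0)
  tail <- ifelse(abs(alpha) <= tilt$tail_range,
                 1 / (2 * tilt$tail_range), 0)
  (1 - tilt$tail_weight) * core + tilt$tail_weight * tail
}

#' Optical ground-truth model of a colony
#'
#' Collects the structural and optical parameters that the synthetic
#' goniometer forward model needs: the hexagonal lattice constant `d`
#' (inter-cell distance), cell diameter `a` (the packing satisfies
#' a/d = 0.9 +/- 0.05), refractive indices of cells and matrix, the
#' normal-incidence specular peak wavelength `lambda_p`, the domain-tilt
#' distribution, and noise levels.
#'
#' `lambda_d` is the wavelength at which the diffraction efficiency peaks
#' (the first-order diffraction resonance of the crystal); it sets where the
#' bright spot sits on the grating-equation curve and defaults to `0.85 * d`,
#' the ratio observed for the 395 nm lattice.
#'
#' @param d lattice constant in nm (day-2 colonies: 395; day-1: 425).
#' @param a cell diameter in nm; default `0.9 * d`.
#' @param n_bac,n_env refractive indices of the cells (1.38) and of the
#'   surrounding matrix (1.34); their volume average is what the specular
#'   fit recovers.
#' @param lambda_p normal-incidence specular peak in nm (default 480).
#' @param lambda_d diffraction-resonance wavelength in nm.
#' @param tilt a [tilt_distribution()].
#' @param noise_sigma additive intensity noise (relative to the unit spot
#'   amplitude).
#' @param angle_jitter per-order angular pointing error, degrees (1 sigma).
#' @return object of class `colony_model`.
#' @export
colony_model <- function(d = 395, a = 0.9 * d, n_bac = 1.38, n_env = 1.34,
                         lambda_p = 480, lambda_d = 0.85 * d,
                         tilt = tilt_distribution(),
                         noise_sigma = 0, angle_jitter = 0) {
  stopifnot(a <= d, n_bac > n_env, n_env > 1,
            a / d >= 0.8, a / d <= 1)
  structure(list(d = d, a = a, n_bac = n_bac, n_env = n_env,
                 lambda_p = lambda_p, lambda_d = lambda_d, tilt = tilt,
                 noise_sigma = noise_sigma, angle_jitter = angle_jitter),
            class = "colony_model")
}

#' Volume-average refractive index of the packing
#'
#' Square-root of the area-weighted mean permittivity of touching-disk rows:
#' `f = pi/(2*sqrt(3)) * (a/d)^2` of cell material in the crystal region.
#'
#' @param model a [colony_model()], or missing to use explicit arguments.
#' @param d,a,n_bac,n_env scalars, used when `model` is missing.
#' @return dimensionless average index.
#' @export
n_average <- function(model, d, a, n_bac, n_env) {
  if (!missing(model)) {
    d <- model$d; a <- model$a; n_bac <- model$n_bac; n_env <- model$n_env
  }
  f <- pi / (2 * sqrt(3)) * (a / d)^2
  sqrt(f * n_bac^2 + (1 - f) * n_env^2)
}
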
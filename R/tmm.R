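#' Multilayer stack
#'
#' Ordered list of homogeneous slabs between an ambient and a substrate
#' half-space, the 1D effective-medium approximation of the hexagonal
#' colony used by the transfer-matrix solver.
#'
#' @param n refractive indices of the slabs (>= 1).
#' @param thickness slab thicknesses in nm (> 0), recycled against `n`.
#' @param n_ambient,n_substrate half-space indices (defaults 1 and 1.34,
#'   air above and agar below).
#' @param repetitions number of times the slab sequence repeats.
#' @return object of class `multilayer_stack`.
#' @export
multilayer_stack <- function(n, thickness, n_ambient = 1,
                             n_substrate = 1.34, repetitions = 1) {
  stopifnot(all(n >= 1), all(thickness > 0), repetitions >= 1)
  len <- max(length(n), length(thickness))
  n <- rep_len(n, len); thickness <- rep_len(thickness, len)
  structure(list(n = n, thickness = thickness, n_ambient = n_ambient,
                 n_substrate = n_substrate, repetitions = repetitions),
            class = "multilayer_stack")
}

#' Effective-index stack of a hexagonal disk lattice
#'
#' One period is the row spacing of the lattice along the chosen
#' propagation direction (`"GK"`, normal incidence: `sqrt(3) d / 2`;
#' `"GM"`: `d / 2`), discretized into `n_layers_per_period` slabs whose
#' index is the row-resolved, area-weighted effective index of the disk
#' lattice (permittivity mixing of the chord coverage of the staggered
#' rows). The slab-average permittivity equals the lattice filling fraction
#' by construction.
#'
#' @param d lattice constant in nm.
#' @param a disk diameter in nm.
#' @param n_bac,n_env disk and matrix refractive indices.
#' @param direction `"GK"` or `"GM"`.
#' @param n_layers_per_period slabs per period (default 8; 2 gives the
#'   coarse two-slab approximation).
#' @param repetitions periods in the stack (default 41).
#' @param n_ambient,n_substrate half-space indices.
#' @return a [multilayer_stack()].
#' @export
stack_from_lattice <- function(d, a, n_bac = 1.38, n_env = 1.34,
                               direction = c("GK", "GM"),
                               n_layers_per_period = 8, repetitions = 41,
                               n_ambient = 1, n_substrate = 1.34) {
  direction <- match.arg(direction)
  stopifnot(a <= d, a >= 0)
  R <- a / 2
  if (direction == "GK") {
    period <- sqrt(3) * d / 2   # row spacing, rows have lateral period d
    lat <- d
  } else {
    period <- d / 2             # column spacing, lateral period sqrt(3) d
    lat <- sqrt(3) * d
  }
  # chord coverage of a row of disks (centres at x = 0 mod period, lateral
  # spacing lat) evaluated at depth x in [0, period)
  coverage <- function(x) {
    if (R == 0) return(0 * x)
    cov <- function(dist) ifelse(abs(dist) < R,
                                 2 * sqrt(pmax(R^2 - dist^2, 0)) / lat, 0)
    # rows at 0 and +/- period contribute (disks can span a full period)
    cov(x) + cov(x - period) + cov(x + period)
  }
  # integrate coverage over each slab for the area-exact effective index
  edges <- seq(0, period, length.out = n_layers_per_period + 1)
  n_sub <- 64
  nvals <- vapply(seq_len(n_layers_per_period), function(k) {
    xs <- seq(edges[k], edges[k + 1], length.out = n_sub)
    f <- mean(pmin(coverage(xs), 1))
    sqrt(f * n_bac^2 + (1 - f) * n_env^2)
  }, numeric(1))
  multilayer_stack(nvals, diff(edges), n_ambient = n_ambient,
                   n_substrate = n_substrate, repetitions = repetitions)
}

#' Transfer-matrix reflectance of a multilayer
#'
#' Standard characteristic-matrix recursion per wavelength and incidence
#' angle, including all multiple internal reflections and interference.
#' For lossless stacks `R + T = 1` to machine precision.
#'
#' @param stack a [multilayer_stack()].
#' @param theta_in incidence angle in degrees (in the ambient).
#' @param polarization `"TE"` (s), `"TM"` (p) or `"unpolarized"` (mean).
#' @param wavelengths wavelength grid in nm.
#' @return object of class `reflectance_spectrum`: data frame-like list
#'   with `wavelength`, `R`, `T`, plus `theta_in` and `polarization`.
#' @export
tmm_reflectance <- function(stack, theta_in = 0,
                            polarization = c("TM", "TE", "unpolarized"),
                            wavelengths = seq(300, 700, by = 2)) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(stack, "multilayer_stack"), abs(theta_in) < 90)
  if (polarization == "unpolarized") {
    a <- tmm_reflectance(stack, theta_in, "TE", wavelengths)
    b <- tmm_reflectance(stack, theta_in, "TM", wavelengths)
    return(structure(list(wavelength = wavelengths, R = (a$R + b$R) / 2,
                          T = (a$T + b$T) / 2, theta_in = theta_in,
                          polarization = "unpolarized"),
                     class = "reflectance_spectrum"))
  }
  nl <- c(rep(stack$n, stack$repetitions))
  tl <- c(rep(stack$thickness, stack$repetitions))
  n0 <- stack$n_ambient; ns <- stack$n_substrate
  s0 <- n0 * sin(theta_in * pi / 180)
  Rv <- Tv <- numeric(length(wavelengths))
  for (iw in seq_along(wavelengths)) {
    k0 <- 2 * pi / wavelengths[iw]
    kz <- function(n) k0 * sqrt(as.complex(n^2 - s0^2))
    eta <- function(n) {
      kzn <- kz(n)
      if (polarization == "TE") kzn / k0 else n^2 * k0 / kzn
    }
    M <- diag(2) + 0i
    for (j in seq_along(nl)) {
      delta <- kz(nl[j]) * tl[j]
      e <- eta(nl[j])
      Mj <- matrix(c(cos(delta), 1i * e * sin(delta),
                     1i * sin(delta) / e, cos(delta)), 2, 2)
      M <- M %*% Mj
    }
    e0 <- eta(n0); es <- eta(ns)
    den <- (M[1, 1] + M[1, 2] * es) * e0 + (M[2, 1] + M[2, 2] * es)
    r <- ((M[1, 1] + M[1, 2] * es) * e0 - (M[2, 1] + M[2, 2] * es)) / den
    t <- 2 * e0 / den
    Rv[iw] <- Mod(r)^2
    Tv[iw] <- Re(es) / Re(e0) * Mod(t)^2
  }
  structure(list(wavelength = wavelengths, R = Rv, T = Tv,
                 theta_in = theta_in, polarization = polarization),
            class = "reflectance_spectrum")
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  cat(sprintf("<reflectance_spectrum> %d wavelengths (%g-%g nm), theta_in = %g deg, %s; max R = %.4g\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$theta_in, x$polarization, max(x$R)))
  invisible(x)
}

#' Reflectance of a tilted multilayer
#'
#' Domains tilted by `tilt` degrees see an effective incidence
#' `theta_in - tilt`; the response is evaluated there and reported against
#' the lab-frame incidence grid. Grazing effective incidence
#' (`|theta_in - tilt| >= 90`) is marked missing. Tilts of +30 and -30
#' degrees approximate the obliquely oriented crystal planes whose gap
#' produces the weak lines crossing the main specular feature.
#'
#' @param stack a [multilayer_stack()].
#' @param tilt tilt angle in degrees.
#' @param theta_in incidence grid in degrees.
#' @param polarization,wavelengths as in [tmm_reflectance()].
#' @return list with `theta_in`, `wavelength`, and matrix `R`
#'   (angle x wavelength; `NA` rows where grazing).
#' @export
tilted_stack_response <- function(stack, tilt, theta_in = seq(-45, 45, 5),
                                  polarization = "TM",
                                  wavelengths = seq(300, 700, by = 2)) {
  R <- matrix(NA_real_, length(theta_in), length(wavelengths))
  for (i in seq_along(theta_in)) {
    te <- theta_in[i] - tilt
    if (abs(te) >= 90) next
    R[i, ] <- tmm_reflectance(stack, te, polarization, wavelengths)$R
  }
  list(theta_in = theta_in, wavelength = wavelengths, R = R, tilt = tilt)
}
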
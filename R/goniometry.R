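#' Grating equation
#'
#' Angle of constructive interference for diffraction order `m` of a grating
#' of period `d`: `theta_m = asin(m * lambda / d - sin(theta_i))`, angles in
#' degrees measured from the sample normal (the source sits at negative
#' angles, so `m = 0` gives the specular direction `-theta_i`). Orders with
#' `|m lambda / d - sin theta_i| > 1` are evanescent and return `NA`.
#'
#' @param m diffraction order (integer, may be negative).
#' @param lambda wavelength in nm.
#' @param d grating period in nm.
#' @param theta_i incidence angle in degrees.
#' @return diffraction angle in degrees, or `NA` where evanescent.
#'   Arguments recycle as usual.
#' @examples
#' grating_angle(1, 336, 395, 0)     # 58.29 deg
#' grating_angle(1, 450, 395, 0)     # NA: evanescent
#' @export
grating_angle <- function(m, lambda, d, theta_i) {
  stopifnot(all(d > 0), all(lambda > 0))
  s <- m * lambda / d - sin(theta_i * pi / 180)
  out <- ifelse(abs(s) <= 1, asin(pmin(pmax(s, -1), 1)) * 180 / pi, NA_real_)
  out
}

#' Angular dispersion of the specular reflection
#'
#' The specular peak wavelength shifts with incidence angle because the
#' constructive-interference condition involves the cosine projection of the
#' optical path inside the medium:
#' `lambda_s = lambda_p * cos(asin(sin(theta_in) / n_avg))`.
#' Fitting this dispersion to a measured specular trace recovers the
#' volume-average refractive index of cells plus matrix.
#'
#' @param lambda_p normal-incidence peak wavelength in nm.
#' @param n_avg average refractive index (>= 1).
#' @param theta_in incidence angle(s) in degrees, |theta_in| < 90.
#' @return shifted peak wavelength(s) in nm.
#' @examples
#' specular_shift(480, 1.4, 0)    # 480
#' specular_shift(480, 1.4, 45)   # 414.3
#' @export
specular_shift <- function(lambda_p, n_avg, theta_in) {
  stopifnot(all(n_avg >= 1), all(abs(theta_in) < 90))
  lambda_p * cos(asin(sin(theta_in * pi / 180) / n_avg))
}

#' Detect diffraction peaks in an angle-resolved map
#'
#' Local 2D maxima above a robust prominence threshold
#' (`prominence` x the median absolute deviation of the map above its
#' median), excluding the blind region and a `exclude_specular`-degree
#' neighbourhood of the specular direction `-theta_in`. Peak positions are
#' refined to sub-grid angular accuracy by log-parabola interpolation
#' (exact for Gaussian spot kernels); the wavelength is reported on-grid so
#' that detected points stay on the grating curve.
#'
#' @param map an [angle_map()].
#' @param prominence threshold in MAD units (default 10; high enough that
#'   a pure-noise map yields an empty list).
#' @param exclude_specular half-width in degrees of the specular exclusion
#'   zone (default 3).
#' @param min_height minimum peak height as a fraction of the map maximum
#'   (default 0.15): diffraction spots are dominant features, and this
#'   keeps threshold-grazing noise maxima out of the order assignment.
#' @return data frame with columns `theta_out`, `lambda`, `intensity`,
#'   possibly empty (with a warning when nothing is found).
#' @export
detect_diffraction_peaks <- function(map, prominence = 10,
                                     exclude_specular = 3,
                                     min_height = 0.15) {
  stopifnot(inherits(map, "angle_map"))
  I <- map$intensity
  I[abs(map$theta_out + map$theta_in) <= exclude_specular, ] <- NA
  med <- median(I, na.rm = TRUE)
  madv <- median(abs(I - med), na.rm = TRUE)
  thr <- max(med + prominence * max(madv, 1e-12),
             min_height * max(I, na.rm = TRUE))
  nt <- nrow(I); nl <- ncol(I)
  peaks <- NULL
  for (i in 2:(nt - 1)) for (j in 2:(nl - 1)) {
    v <- I[i, j]
    if (is.na(v) || v < thr) next
    nb <- I[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (any(is.na(nb))) next
    if (v < max(nb[-5])) next
    # quadratic sub-grid refinement along each axis
    refine <- function(ym, y0, yp, x0, h) {
      # log-parabola: exact centring for Gaussian spot kernels
      if (ym > 0 && yp > 0) { ym <- log(ym); y0 <- log(y0); yp <- log(yp) }
      den <- ym - 2 * y0 + yp
      if (abs(den) < 1e-15) return(x0)
      off <- 0.5 * (ym - yp) / den
      x0 + max(min(off, 1), -1) * h
    }
    th <- refine(I[i - 1, j], v, I[i + 1, j], map$theta_out[i],
                 map$theta_out[i + 1] - map$theta_out[i])
    # the wavelength stays on-grid: refining it would move the point off
    # the grating curve, which is what the period fit consumes
    peaks <- rbind(peaks, data.frame(theta_out = th,
                                     lambda = map$wavelength[j],
                                     intensity = v))
  }
  if (is.null(peaks)) {
    warning("no diffraction peak found")
    return(data.frame(theta_out = numeric(), lambda = numeric(),
                      intensity = numeric()))
  }
  peaks <- peaks[order(-peaks$intensity), ]
  # non-maximum suppression: digitization can split one spot into close
  # maxima; keep the strongest within a kernel-sized neighbourhood
  keep <- rep(TRUE, nrow(peaks))
  for (k in seq_len(nrow(peaks))) {
    if (!keep[k]) next
    close_by <- abs(peaks$theta_out - peaks$theta_out[k]) < 3 &
      abs(peaks$lambda - peaks$lambda[k]) < 12
    close_by[seq_len(k)] <- FALSE
    keep[close_by] <- FALSE
  }
  peaks[keep, ]
}

#' Fit the lattice constant to detected diffraction peaks
#'
#' Joint least squares of the grating equation over the peaks of one or more
#' angle-resolved maps. Each peak is assigned the diffraction order
#' `m` in `orders` that is most consistent with the ensemble: a consensus
#' period is found over all single-peak closed-form inversions
#' `d = m * lambda / (sin(theta_out) + sin(theta_in))`, orders are assigned
#' by proximity to the consensus, and the final `d` minimizes the summed
#' squared angular residual. With a single peak the closed form is returned
#' exactly.
#'
#' @param maps an `angle_map` or list of them.
#' @param orders candidate orders (default `c(-2, -1, 1, 2)`).
#' @param peaks optional pre-detected peak tables (list parallel to `maps`);
#'   by default [detect_diffraction_peaks()] is called.
#' @param d_range admissible period range in nm for order assignment.
#' @return object of class `grating_fit`: `d_hat`, `d_se`, `orders_used`,
#'   `residual_rms` (degrees), and the point table.
#' @export
fit_grating <- function(maps, orders = c(-2, -1, 1, 2), peaks = NULL,
                        d_range = c(150, 1000)) {
  if (inherits(maps, "angle_map")) maps <- list(maps)
  pts <- NULL
  for (k in seq_along(maps)) {
    pk <- if (is.null(peaks)) detect_diffraction_peaks(maps[[k]]) else peaks[[k]]
    if (!nrow(pk)) next
    pts <- rbind(pts, data.frame(theta_in = maps[[k]]$theta_in,
                                 theta_out = pk$theta_out, lambda = pk$lambda))
  }
  if (is.null(pts) || !nrow(pts)) stop("no diffraction peaks to fit")
  # candidate periods for every (peak, order)
  ssum <- sin(pts$theta_out * pi / 180) + sin(pts$theta_in * pi / 180)
  cand <- lapply(orders, function(m) m * pts$lambda / ssum)
  cand <- do.call(cbind, cand)
  cand[cand < d_range[1] | cand > d_range[2]] <- NA
  if (all(is.na(cand))) stop("no admissible order assignment; candidates all outside d_range")
  # consensus: the candidate value minimizing summed per-peak best-order deviation
  vals <- sort(unique(na.omit(as.vector(cand))))
  cost <- vapply(vals, function(d0)
    sum(apply(abs(cand - d0), 1, min, na.rm = TRUE)), numeric(1))
  d0 <- vals[which.min(cost)]
  m_idx <- apply(abs(cand - d0), 1, function(r) {
    r[is.na(r)] <- Inf
    which.min(r)
  })
  pts$m <- orders[m_idx]
  conflict <- abs(cand[cbind(seq_len(nrow(pts)), m_idx)] - d0) > 0.25 * d0
  if (any(conflict))
    stop("conflicting order assignments for peaks: ",
         paste(which(conflict), collapse = ", "),
         " (candidate periods ",
         paste(round(cand[conflict, ], 1), collapse = ", "), ")")
  # angular residual with a continuous evanescent penalty, so the
  # optimizer cannot profit from pushing points past the horizon
  resid_fun <- function(d) {
    s <- pts$m * pts$lambda / d - sin(pts$theta_in * pi / 180)
    th <- asin(pmin(pmax(s, -1), 1)) * 180 / pi
    th + pmax(abs(s) - 1, 0) * 180 * sign(s) - pts$theta_out
  }
  if (nrow(pts) == 1) {
    d_hat <- cand[1, m_idx[1]]
  } else {
    # exact sin-space closed form (regression through the origin of
    # sin(theta_out) + sin(theta_in) on m * lambda), then angular refine
    x <- pts$m * pts$lambda
    y <- sin(pts$theta_out * pi / 180) + sin(pts$theta_in * pi / 180)
    d_lin <- sum(x^2) / sum(x * y)
    obj <- function(d) sum(resid_fun(d)^2)
    d_hat <- optimize(obj, interval = d_lin * c(0.97, 1.03),
                      tol = 1e-10)$minimum
  }
  res <- resid_fun(d_hat)
  rms <- sqrt(mean(res^2))
  # 1-sigma from linearized least squares
  h <- 1e-4 * d_hat
  jac <- (resid_fun(d_hat + h) - resid_fun(d_hat - h)) / (2 * h)
  dof <- max(nrow(pts) - 1, 1)
  sigma2 <- sum(res^2) / dof
  d_se <- if (nrow(pts) > 1) sqrt(sigma2 / sum(jac^2)) else NA_real_
  structure(list(d_hat = d_hat, d_se = d_se,
                 orders_used = sort(unique(pts$m)),
                 residual_rms = rms, points = pts),
            class = "grating_fit")
}

#' @export
print.grating_fit <- function(x, ...) {
  cat(sprintf("<grating_fit> d = %.2f +/- %.2f nm (orders %s, %d peaks, residual RMS %.3g deg)\n",
              x$d_hat, x$d_se, paste(x$orders_used, collapse = ","),
              nrow(x$points), x$residual_rms))
  invisible(x)
}

#' Fit the average refractive index to a specular trace
#'
#' `lambda_p` is read off at the 0-degree crossing of the ridge (local
#' quadratic interpolation), then `n_avg` is fitted by 1D least squares of
#' the specular-dispersion relation ([specular_shift()]) to the whole trace.
#' A trace flat to within the noise gives no leverage on `n_avg`; the fit
#' then returns the search upper bound with `lower_bound_flag = TRUE`.
#'
#' @param trace a [specular_trace()] spanning at least 30 degrees and
#'   containing a neighbourhood of 0 degrees.
#' @param n_max upper search bound for the index (default 3).
#' @return object of class `specular_fit`: `lambda_p_hat`, `n_avg_hat`,
#'   `n_se`, `residual_rms` (nm), `lower_bound_flag`.
#' @export
fit_specular <- function(trace, n_max = 3) {
  stopifnot(inherits(trace, "specular_trace"))
  th <- trace$theta_in; ls <- trace$lambda_s
  if (diff(range(th)) < 30) stop("trace must span at least 30 degrees")
  if (min(abs(th)) > 5) stop("trace has no neighbourhood of 0 degrees")
  # lambda_p: quadratic fit around 0 degrees
  w <- abs(th) <= max(10, 2 * median(diff(sort(th))))
  q <- lm(ls[w] ~ th[w] + I(th[w]^2))
  lambda_p <- unname(coef(q)[1])
  obj <- function(n) sum((ls - specular_shift(lambda_p, n, th))^2)
  opt <- optimize(obj, interval = c(1, n_max), tol = 1e-9)
  n_hat <- opt$minimum
  res <- ls - specular_shift(lambda_p, n_hat, trace$theta_in)
  rms <- sqrt(mean(res^2))
  at_bound <- n_hat > n_max - 1e-3
  # curvature-based standard error
  h <- 1e-4
  curv <- (obj(n_hat + h) - 2 * obj(n_hat) + obj(max(n_hat - h, 1))) / h^2
  dof <- max(length(ls) - 2, 1)
  n_se <- if (curv > 0) sqrt(2 * sum(res^2) / dof / curv) else NA_real_
  structure(list(lambda_p_hat = lambda_p, n_avg_hat = n_hat, n_se = n_se,
                 residual_rms = rms, lower_bound_flag = at_bound),
            class = "specular_fit")
}

#' @export
print.specular_fit <- function(x, ...) {
  cat(sprintf("<specular_fit> lambda_p = %.1f nm, n_avg = %.3f +/- %.3f (residual RMS %.2f nm)%s\n",
              x$lambda_p_hat, x$n_avg_hat, x$n_se, x$residual_rms,
              if (x$lower_bound_flag) " [flat trace: n at search bound]" else ""))
  invisible(x)
}

#' Extract the domain-tilt streak and correct it for incidence angle
#'
#' The low-wavelength scattering streak is traced as the ridge wavelength
#' (sub-grid argmax, log-parabola refined) within `lambda_window` for every
#' detection angle, after masking the specular-reflection family (the
#' specular spots of tilted domains follow `theta_out = 2 alpha - theta_in`
#' with the specular-dispersion wavelength, and would contaminate the
#' short-wavelength window at large tilts). Correcting the abscissa by the
#' incidence angle, `theta_out_corrected = theta_out - theta_in` (the
#' 0-degree reference convention), makes streaks recorded at different
#' incidence angles overlay if they originate from tilted domains: a domain
#' at tilt alpha contributes at `theta_out = alpha + f(theta_in - alpha)`,
#' `lambda = g(theta_in - alpha)`, so the traced locus depends on
#' `theta_out - theta_in` only.
#'
#' @param map an [angle_map()].
#' @param lambda_window wavelength window in nm containing the streak
#'   (default `c(300, 520)`: from the short-wavelength side of the
#'   normal-incidence resonance up to the oblique green resonances).
#' @param snr_min ridge points weaker than `snr_min` times the window
#'   maximum are dropped (partial traces with gaps are allowed).
#' @param specular_mask parameters `c(lambda_p, n_avg, halfwidth_nm)` of
#'   the specular family to mask (defaults 480, 1.37, 20).
#' @return object of class `streak_trace` with `theta_in`, `ridge`
#'   (theta_out, lambda, intensity) and `corrected`
#'   (theta_out_corrected, lambda).
#' @export
extract_and_correct_streak <- function(map, lambda_window = c(300, 520),
                                       snr_min = 0.05,
                                       specular_mask = c(480, 1.37, 20)) {
  stopifnot(inherits(map, "angle_map"))
  jw <- which(map$wavelength >= lambda_window[1] &
              map$wavelength <= lambda_window[2])
  if (length(jw) < 3) stop("lambda_window too narrow for this map")
  I <- map$intensity[, jw, drop = FALSE]
  lam <- map$wavelength[jw]
  # mask the specular family of tilted domains
  alpha <- (map$theta_out + map$theta_in) / 2
  th_eff <- map$theta_in - alpha
  lam_spec <- rep(NA_real_, length(alpha))
  ok <- abs(th_eff) < 89
  lam_spec[ok] <- specular_shift(specular_mask[1], specular_mask[2],
                                 th_eff[ok])
  for (i in seq_along(alpha)) {
    if (!is.na(lam_spec[i]))
      I[i, abs(lam - lam_spec[i]) < specular_mask[3]] <- NA
  }
  thr <- snr_min * max(I, na.rm = TRUE)
  ridge <- vapply(seq_along(map$theta_out), function(i) {
    row <- I[i, ]
    if (all(is.na(row))) return(c(NA, NA))
    j <- which.max(row)
    if (row[j] < thr) return(c(NA, NA))
    lam_j <- lam[j]
    if (j > 1 && j < length(lam) && !anyNA(row[(j - 1):(j + 1)]) &&
        all(row[(j - 1):(j + 1)] > 0)) {
      lr <- log(row[(j - 1):(j + 1)])
      den <- lr[1] - 2 * lr[2] + lr[3]
      if (abs(den) > 1e-15) {
        off <- min(max(0.5 * (lr[1] - lr[3]) / den, -1), 1)
        lam_j <- lam[j] + off * (lam[2] - lam[1])
      }
    }
    c(lam_j, row[j])
  }, numeric(2))
  keep <- !is.na(ridge[1, ])
  structure(list(
    theta_in = map$theta_in,
    ridge = data.frame(theta_out = map$theta_out[keep],
                       lambda = ridge[1, keep],
                       intensity = ridge[2, keep]),
    corrected = data.frame(
      theta_out_corrected = map$theta_out[keep] - map$theta_in,
      lambda = ridge[1, keep])),
    class = "streak_trace")
}

#' RMS angular spread of corrected streaks
#'
#' Restricts each corrected streak to one branch (corrected angles in
#' `theta_c_range`; the default negative arm is the one inside the tilt
#' support of all incidence angles), interpolates the corrected
#' angle as a function of wavelength on a common grid, and returns the
#' root-mean-square deviation of the per-trace angles from their pointwise
#' mean: the overlay criterion for the tilt-streak interpretation.
#' Returns `Inf` when fewer than two traces share any wavelength support
#' (e.g. under a wrong correction sign).
#'
#' @param traces list of [extract_and_correct_streak()] results.
#' @param theta_c_range corrected-angle window selecting the branch
#'   (default `c(-45, -6)` degrees).
#' @param n_grid number of wavelength samples for the comparison.
#' @return RMS in degrees (`Inf` if the traces share no support).
#' @export
streak_overlay_rms <- function(traces, theta_c_range = c(-45, -6),
                               n_grid = 40) {
  stopifnot(length(traces) >= 2)
  br <- lapply(traces, function(t) {
    sel <- t$corrected$theta_out_corrected >= theta_c_range[1] &
      t$corrected$theta_out_corrected <= theta_c_range[2]
    t$corrected[sel, ]
  })
  br <- br[vapply(br, nrow, integer(1)) >= 3]
  if (length(br) < 2) return(Inf)
  rng <- range(unlist(lapply(br, function(b) range(b$lambda))))
  lam <- seq(rng[1], rng[2], length.out = n_grid)
  th <- sapply(br, function(b) {
    o <- order(b$lambda)
    approx(b$lambda[o], b$theta_out_corrected[o], xout = lam,
           ties = mean)$y
  })
  ok <- rowSums(!is.na(th)) >= 2
  if (!any(ok)) return(Inf)
  dev <- th[ok, , drop = FALSE] - rowMeans(th[ok, , drop = FALSE],
                                           na.rm = TRUE)
  sqrt(mean(dev^2, na.rm = TRUE))
}
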
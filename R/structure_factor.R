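#' Structure factor of a point ensemble
#'
#' Direct evaluation of `S(q) = |sum_j exp(i q . r_j)|^2 / N` on a square
#' q grid, with radial and first-shell azimuthal reductions attached. For a
#' Poisson point set `S ~ 1` away from the origin; hexagonal packings show
#' six first-shell peaks at `|q1| = 4 pi / (sqrt(3) d)`, 60 degrees apart.
#'
#' @param ens a [particle_ensemble()].
#' @param q_max grid half-width in 1/nm (default `2.2 * 4 pi / (sqrt(3) d)`
#'   estimated from the minimum pair distance).
#' @param n_q grid points per axis (odd; default 121).
#' @return object of class `sq_map`: `qx`, `qy`, `S` (matrix), `radial`
#'   (data frame q, S), `azimuthal` (data frame phi_deg, S at the first
#'   shell), `q1_hat` (location of the first-shell radial peak).
#' @export
sq_points <- function(ens, q_max = NULL, n_q = 121) {
  stopifnot(inherits(ens, "particle_ensemble"), nrow(ens$positions) >= 2)
  if (is.null(q_max)) {
    d_guess <- min_pair_distance(ens)
    q_max <- 2.2 * 4 * pi / (sqrt(3) * d_guess)
  }
  if (n_q %% 2 == 0) n_q <- n_q + 1
  qs <- seq(-q_max, q_max, length.out = n_q)
  grid <- as.matrix(expand.grid(qx = qs, qy = qs))
  S <- matrix(sq_on_points(ens$positions, grid), n_q, n_q)
  if (2 * q_max / (n_q - 1) > 0.25 * 4 * pi / (sqrt(3) * min_pair_distance(ens)))
    warning("q grid too coarse to resolve the first shell")
  out <- structure(list(qx = qs, qy = qs, S = S), class = "sq_map")
  attach_profiles(out, n_particles = nrow(ens$positions))
}

#' Structure factor of a (binary) image
#'
#' Power spectrum of the mean-subtracted foreground indicator, normalized by
#' the number of foreground pixels, with axes in 1/nm. A non-binary image is
#' auto-binarized (with a warning) at the threshold maximizing the
#' between-class variance.
#'
#' @param img matrix in \[0, 1\] (rows = y).
#' @param pixel_nm pixel size in nm.
#' @return an `sq_map` (see [sq_points()]).
#' @export
sq_image <- function(img, pixel_nm) {
  vals <- sort(unique(as.vector(img)))
  if (length(vals) > 2) {
    warning("non-binary image: auto-binarizing (between-class variance threshold)")
    img <- img > otsu_threshold(img)
  } else img <- img > mean(vals)
  ind <- img - mean(img)
  P <- Mod(fft(ind))^2 / max(sum(img), 1)
  ny <- nrow(ind); nx <- ncol(ind)
  # centre the spectrum
  P <- P[c((floor(ny / 2) + 1):ny, 1:floor(ny / 2)),
         c((floor(nx / 2) + 1):nx, 1:floor(nx / 2))]
  qy <- 2 * pi * (seq_len(ny) - floor(ny / 2) - 1) / (ny * pixel_nm)
  qx <- 2 * pi * (seq_len(nx) - floor(nx / 2) - 1) / (nx * pixel_nm)
  # transpose so first axis is qx, matching sq_points
  out <- structure(list(qx = qx, qy = qy, S = t(P)), class = "sq_map")
  attach_profiles(out, n_particles = NULL)
}

# Otsu's threshold on a [0,1] image
otsu_threshold <- function(img, n_breaks = 256) {
  h <- tabulate(pmin(pmax(ceiling(as.vector(img) * n_breaks), 1), n_breaks),
                nbins = n_breaks)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_breaks))
  mu_t <- mu[n_breaks]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  which.max(sigma_b) / n_breaks
}

# radial + first-shell azimuthal profiles
attach_profiles <- function(map, n_particles = NULL) {
  qr <- sqrt(outer(map$qx^2, map$qy^2, "+"))
  qmax <- max(map$qx)
  n_bin <- 80
  br <- seq(0, qmax, length.out = n_bin + 1)
  bin <- findInterval(qr, br, all.inside = TRUE)
  rad <- data.frame(
    q = (br[-1] + br[-(n_bin + 1)]) / 2,
    S = vapply(seq_len(n_bin), function(b)
      mean(map$S[bin == b & qr > 0]), numeric(1)))
  rad <- rad[is.finite(rad$S), ]
  # skip the forward-scattering lobe: first local minimum, then the
  # strongest local maximum beyond it
  i_min <- which(diff(rad$S) > 0)[1]
  i1 <- local_peak_indices(rad$S)
  if (!is.na(i_min)) i1 <- i1[i1 > i_min]
  q1_hat <- if (length(i1)) rad$q[i1[which.max(rad$S[i1])]] else NA_real_
  azim <- NULL
  if (is.finite(q1_hat)) {
    ann <- qr >= 0.85 * q1_hat & qr <= 1.15 * q1_hat
    phi <- atan2(rep(map$qy, each = length(map$qx)),
                 rep(map$qx, times = length(map$qy)))
    phi_deg <- (phi * 180 / pi) %% 360
    bb <- findInterval(phi_deg[ann], seq(0, 360, by = 5), all.inside = TRUE)
    azim <- data.frame(
      phi_deg = seq(2.5, 357.5, by = 5),
      S = vapply(1:72, function(b) {
        v <- map$S[ann][bb == b]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1)))
  }
  map$radial <- rad
  map$azimuthal <- azim
  map$q1_hat <- q1_hat
  map$n_particles <- n_particles
  map
}

local_peak_indices <- function(y) {
  n <- length(y)
  if (n < 3) return(integer())
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' @export
print.sq_map <- function(x, ...) {
  cat(sprintf("<sq_map> %d x %d grid, |q| <= %.4g 1/nm; first shell at %.5g 1/nm\n",
              length(x$qx), length(x$qy), max(x$qx), x$q1_hat))
  invisible(x)
}

#' Lattice constant from image autocorrelation
#'
#' 2D autocorrelation of the mean-subtracted image (via FFT, periodic
#' wrap); the lattice constant is the radial distance of the nearest
#' off-centre peak, refined to sub-pixel accuracy by a centroid over the
#' peak neighbourhood. The standard error follows from the spread of the
#' symmetric peak set; an anisotropy flag is raised when the nearest-peak radii
#' spread exceeds 6 percent of their median across directions (e.g.
#' non-square pixel calibration; the discrete-grid spread of an isotropic
#' image stays below ~4 percent).
#'
#' @param img matrix in \[0, 1\].
#' @param pixel_nm pixel size in nm (applies to both axes).
#' @param peak_snr minimum peak height in units of the autocorrelation
#'   noise floor.
#' @return list: `d_hat`, `se`, `n_peaks`, `anisotropy`, `anisotropy_flag`.
#' @export
autocorr_lattice <- function(img, pixel_nm, peak_snr = 4) {
  x <- img - mean(img)
  F <- fft(x)
  ac <- Re(fft(F * Conj(F), inverse = TRUE)) / length(x)
  ny <- nrow(ac); nx <- ncol(ac)
  ac <- ac[c((floor(ny / 2) + 1):ny, 1:floor(ny / 2)),
           c((floor(nx / 2) + 1):nx, 1:floor(nx / 2))]
  cy <- floor(ny / 2) + 1; cx <- floor(nx / 2) + 1
  ac <- ac / ac[cy, cx]
  ry <- (seq_len(ny) - cy); rx <- (seq_len(nx) - cx)
  rr <- sqrt(outer(ry^2, rx^2, "+"))
  # radial profile to find the first off-centre ring
  rbin <- round(rr)
  prof <- vapply(1:max(rbin), function(b) mean(ac[rbin == b]), numeric(1))
  # skip the central peak: first local minimum, then first local max
  i_min <- which(diff(prof) > 0)[1]
  if (is.na(i_min)) stop("no lattice detected")
  pk <- local_peak_indices(prof)
  pk <- pk[pk > i_min]
  noise <- sd(prof[max(1, length(prof) - 20):length(prof)])
  pk <- pk[prof[pk] > peak_snr * max(noise, 1e-12)]
  if (!length(pk)) stop("no lattice detected")
  r1 <- pk[1]
  # all 2D peaks near radius r1
  cand <- which(rr > 0.7 * r1 & rr < 1.3 * r1 &
                ac > 0.5 * prof[r1], arr.ind = TRUE)
  if (!nrow(cand)) stop("no lattice detected")
  # cluster candidates into peaks by local maxima
  keep <- vapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (i < 2 || j < 2 || i > ny - 1 || j > nx - 1) return(FALSE)
    ac[i, j] == max(ac[(i - 1):(i + 1), (j - 1):(j + 1)])
  }, logical(1))
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) stop("no lattice detected")
  # sub-pixel refinement: parabolic interpolation along each axis
  radii <- numeric(nrow(cand)); angles <- numeric(nrow(cand))
  par1 <- function(ym, y0, yp) {
    den <- ym - 2 * y0 + yp
    if (abs(den) < 1e-15) 0 else max(min(0.5 * (ym - yp) / den, 0.5), -0.5)
  }
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    yy <- ry[i] + if (i > 1 && i < ny) par1(ac[i - 1, j], ac[i, j], ac[i + 1, j]) else 0
    xx <- rx[j] + if (j > 1 && j < nx) par1(ac[i, j - 1], ac[i, j], ac[i, j + 1]) else 0
    radii[k] <- sqrt(xx^2 + yy^2)
    angles[k] <- atan2(yy, xx)
  }
  d_hat <- median(radii) * pixel_nm
  se <- if (length(radii) > 1) sd(radii) * pixel_nm / sqrt(length(radii))
        else pixel_nm
  aniso <- (max(radii) - min(radii)) / median(radii)
  list(d_hat = d_hat, se = se, n_peaks = length(radii),
       anisotropy = aniso, anisotropy_flag = aniso > 0.06)
}

#' Lattice spacing from a line profile
#'
#' Samples the image intensity along a segment (bilinear interpolation),
#' finds profile peaks, and returns the mean peak-to-peak distance. In a
#' hexagonal lattice the result depends on direction: `d` along the
#' nearest-neighbour rows, `d sqrt(3)/2` along the row normal; the direction
#' used is reported.
#'
#' @param img matrix in \[0, 1\] (rows = y).
#' @param line `c(x0, y0, x1, y1)` in nm.
#' @param pixel_nm pixel size in nm.
#' @param min_level peaks must exceed this fraction of the profile range.
#' @return list: `d_hat`, `se`, `n_peaks`, `direction_deg`.
#' @export
lineprofile_spacing <- function(img, line, pixel_nm, min_level = 0.5) {
  stopifnot(length(line) == 4)
  p0 <- line[1:2]; p1 <- line[3:4]
  len <- sqrt(sum((p1 - p0)^2))
  n_s <- max(32, ceiling(len / (pixel_nm / 3)))
  tt <- seq(0, 1, length.out = n_s)
  xs <- (p0[1] + tt * (p1[1] - p0[1])) / pixel_nm + 0.5
  ys <- (p0[2] + tt * (p1[2] - p0[2])) / pixel_nm + 0.5
  prof <- bilinear_sample(img, xs, ys)
  lev <- min(prof) + min_level * diff(range(prof))
  # each contiguous above-level run is one disk crossing; its position is
  # the intensity-weighted centroid of the run (robust to flat-top disks)
  above <- prof >= lev
  rl <- rle(above)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  runs <- which(rl$values)
  # drop disk crossings truncated by the segment ends
  runs <- runs[starts[runs] > 1 & ends[runs] < n_s]
  if (length(runs) < 3) stop("fewer than 3 profile peaks along the line")
  pos <- vapply(runs, function(r) {
    i <- starts[r]:ends[r]
    w <- prof[i] - lev
    sum(tt[i] * w) / sum(w) * len
  }, numeric(1))
  sp <- diff(pos)
  list(d_hat = mean(sp), se = sd(sp) / sqrt(length(sp)),
       n_peaks = length(runs),
       direction_deg = atan2(p1[2] - p0[2], p1[1] - p0[1]) * 180 / pi)
}

bilinear_sample <- function(img, xs, ys) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- pmin(pmax(floor(xs), 1), nx - 1)
  y0 <- pmin(pmax(floor(ys), 1), ny - 1)
  fx <- pmin(pmax(xs - x0, 0), 1)
  fy <- pmin(pmax(ys - y0, 0), 1)
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1, x0 + 1)] * fx * fy
}
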
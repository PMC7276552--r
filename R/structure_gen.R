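#' Specification of a hexagonal disk lattice
#'
#' @param d lattice constant (nearest-neighbour distance) in nm.
#' @param a disk diameter in nm (`a <= d`; touching allowed).
#' @param box box `c(Lx, Ly)` in nm; x is the propagation direction of the
#'   FDTD cell, y the (periodic) lateral direction.
#' @param ff target area fraction of disks in the whole box. The lattice
#'   fills a centred slab of the box so that the overall fraction is `ff`;
#'   `ff` may not exceed the hexagonal maximum `pi/(2 sqrt(3)) (a/d)^2`.
#' @param orientation crystal orientation in degrees relative to the
#'   incidence (x) axis. `0` is the normal-incidence ("KG") orientation:
#'   close-packed rows run along y with lateral period `d` and row spacing
#'   `sqrt(3) d / 2` along x. `30` is the "MG" orientation: lateral period
#'   `sqrt(3) d`, column spacing `d / 2`.
#' @return object of class `lattice_spec`.
#' @export
lattice_spec <- function(d = 395, a = 375, box = c(2500, 2370), ff = 0.6,
                         orientation = 0) {
  stopifnot(a <= d, d > 0, length(box) == 2, ff > 0)
  ff_max <- pi / (2 * sqrt(3)) * (a / d)^2
  if (ff > ff_max + 1e-9)
    stop(sprintf("ff = %.3f exceeds hexagonal maximum %.3f for a/d = %.3f",
                 ff, ff_max, a / d))
  structure(list(d = d, a = a, box = as.numeric(box), ff = ff,
                 orientation = orientation),
            class = "lattice_spec")
}

#' Disorder specification for inverse design
#'
#' `sigma_k` is the relative radial broadening (standard deviation of the
#' modulus of the first-shell Bragg wavevector); `sigma_phi` the azimuthal
#' broadening in degrees of the angle relative to the incident wavevector.
#' `sigma_phi = Inf` (or >= 60) denotes the isotropic limit: a uniform ring.
#'
#' @param sigma_k relative radial broadening (>= 0).
#' @param sigma_phi azimuthal broadening in degrees.
#' @param seed RNG seed recorded with the spec.
#' @param n_realizations number of independent samples to average over in
#'   sweeps (default 7).
#' @return object of class `disorder_spec`.
#' @export
disorder_spec <- function(sigma_k = 0, sigma_phi = 0, seed = 1,
                          n_realizations = 7) {
  stopifnot(sigma_k >= 0, sigma_phi >= 0, n_realizations >= 1)
  structure(list(sigma_k = sigma_k, sigma_phi = sigma_phi, seed = seed,
                 n_realizations = n_realizations),
            class = "disorder_spec")
}

# lattice sites for a spec, centred slab in x, wrapped-consistent in y
hex_sites <- function(spec) {
  d <- spec$d; box <- spec$box
  if (spec$orientation %% 60 == 0) {
    lat_period <- d
    colsp <- sqrt(3) * d / 2
    stagger <- d / 2
  } else if (spec$orientation %% 60 == 30) {
    lat_period <- sqrt(3) * d
    colsp <- d / 2
    stagger <- lat_period / 2
  } else {
    # generic orientation: rotate the 0-degree lattice (not y-periodic)
    s0 <- hex_sites(lattice_spec(d, spec$a, box = rep(2 * max(spec$box), 2),
                                 ff = spec$ff, orientation = 0))
    th <- spec$orientation * pi / 180
    rot <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    ctr <- max(spec$box)
    p <- sweep(s0$sites, 2, c(ctr, ctr)) %*% t(rot)
    p <- sweep(p, 2, spec$box / 2, "+")
    keep <- p[, 1] > 0 & p[, 1] < box[1] & p[, 2] > 0 & p[, 2] < box[2]
    return(list(sites = p[keep, , drop = FALSE], lat_period = NA,
                n_per_col = NA))
  }
  n_lat <- max(1, round(box[2] / lat_period))
  commensurate <- abs(box[2] / lat_period - n_lat) < 1e-6
  # disks per lateral column; y positions wrap consistently if the box is
  # commensurate with the lateral period
  area <- pi * spec$a^2 / 4
  n_target <- round(spec$ff * box[1] * box[2] / area)
  n_cols <- max(1, if (commensurate) round(n_target / n_lat)
                else ceiling(n_target / n_lat))
  slab_w <- (n_cols - 1) * colsp
  x0 <- (box[1] - slab_w) / 2
  sites <- NULL
  for (ic in 0:(n_cols - 1)) {
    yoff <- if (ic %% 2 == 0) 0 else stagger
    ys <- (0:(n_lat - 1)) * lat_period + yoff
    ys <- ys %% box[2]
    sites <- rbind(sites, cbind(x0 + ic * colsp, ys))
  }
  if (!commensurate && nrow(sites) > n_target) {
    # exact count: drop the sites farthest from the slab centre
    ctr <- c(mean(range(sites[, 1])), box[2] / 2)
    dist2 <- (sites[, 1] - ctr[1])^2 + 1e-6 * (sites[, 2] - ctr[2])^2
    sites <- sites[order(dist2)[seq_len(n_target)], , drop = FALSE]
  }
  list(sites = sites, lat_period = if (commensurate) lat_period else NA,
       n_per_col = n_lat)
}

#' Construct a (finite) perfect hexagonal packing
#'
#' Disks at hexagonal sites of spacing `d` fill a centred slab of the box
#' such that the overall area fraction is `ff`; the particle count is
#' `N = round(ff * Lx * Ly / (pi a^2 / 4))` (trimmed to whole lateral
#' columns for orientations 0 and 30 so that the ensemble is y-periodic
#' when the box is commensurate).
#'
#' @param spec a [lattice_spec()].
#' @return a [particle_ensemble()] with attribute `"achieved_ff"`.
#' @export
make_hexagonal <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  hs <- hex_sites(spec)
  periodic <- !is.na(hs$lat_period) &&
    abs(spec$box[2] / hs$lat_period - round(spec$box[2] / hs$lat_period)) < 1e-6
  ens <- particle_ensemble(hs$sites, spec$a / 2, spec$box,
                           periodic_y = periodic, check = FALSE)
  attr(ens, "achieved_ff") <-
    nrow(hs$sites) * pi * spec$a^2 / 4 / prod(spec$box)
  ens
}

#' Jittered lattice (fast approximate disorder)
#'
#' Adds i.i.d. Gaussian displacements to the perfect lattice sites with
#' hard-disk rejection resampling. This is the quick alternative to the
#' structure-factor-targeted annealing of [generate_disordered()]: the
#' displacement sigma maps onto a Debye-Waller-type reduction of the Bragg
#' peak height, `S_peak ~ exp(-q1^2 sigma^2) S_perfect`.
#'
#' @param spec a [lattice_spec()].
#' @param displacement_sigma Gaussian displacement in nm.
#' @param seed RNG seed.
#' @param max_reject error out when the overall rejection rate exceeds 50
#'   percent.
#' @return a [particle_ensemble()]; attribute `"rejections"` counts
#'   resampled draws.
#' @export
jitter_lattice <- function(spec, displacement_sigma, seed = 1,
                           max_reject = 0.5) {
  ens0 <- make_hexagonal(spec)
  if (displacement_sigma == 0) return(ens0)
  set.seed(seed)
  p <- ens0$positions
  a <- 2 * ens0$radius
  rej <- 0L
  for (i in seq_len(nrow(p))) {
    base <- p[i, ]
    repeat {
      cand <- base + rnorm(2, 0, displacement_sigma)
      cand <- pmin(pmax(cand, 0), ens0$box)
      dxv <- p[-i, 1] - cand[1]
      dyv <- p[-i, 2] - cand[2]
      if (ens0$periodic_y)
        dyv <- dyv - round(dyv / ens0$box[2]) * ens0$box[2]
      if (all(dxv^2 + dyv^2 >= a^2)) break
      rej <- rej + 1L
      if (rej > max_reject * 2 * nrow(p))
        stop("rejection rate above 50 percent; reduce displacement_sigma")
    }
    p[i, ] <- cand
  }
  out <- particle_ensemble(p, ens0$radius, ens0$box,
                           periodic_y = ens0$periodic_y, check = FALSE)
  attr(out, "rejections") <- rej
  out
}

#' Target structure factor for inverse design
#'
#' Hexagonal Bragg peaks of the first reciprocal shell
#' (`|q1| = 4 pi / (sqrt(3) d)`), broadened radially by a Gaussian of width
#' `sigma_k * |q1|` and azimuthally by `sigma_phi`; at the isotropic limit
#' the six peaks merge into a uniform ring. Defined on a polar grid around
#' the first shell, which is where the inverse-design objective is
#' evaluated. When `finite_size_q > 0` (set automatically by
#' [generate_disordered()] from the box size) the target widths are
#' convolved with the finite-sample peak width, so that `sigma = 0`
#' reproduces the finite perfect lattice rather than an unattainable
#' delta peak.
#'
#' @param spec a [lattice_spec()].
#' @param disorder a [disorder_spec()].
#' @param n_radial,n_azimuthal polar grid resolution.
#' @param radial_span first-shell window as a fraction of `|q1|`.
#' @return object of class `target_sq`: `q` (two-column matrix), `S`
#'   (target values, max 1), `weight`, `q1`, polar axes.
#' @export
target_sq <- function(spec, disorder, n_radial = 17, n_azimuthal = 72,
                      radial_span = c(0.75, 1.25), finite_size_q = 0) {
  q1 <- 4 * pi / (sqrt(3) * spec$d)
  qr <- seq(radial_span[1], radial_span[2], length.out = n_radial) * q1
  phi <- seq(0, 2 * pi, length.out = n_azimuthal + 1)[-(n_azimuthal + 1)]
  grid <- expand.grid(qr = qr, phi = phi)
  sig_r <- sqrt((disorder$sigma_k * q1)^2 + finite_size_q^2 + (0.002 * q1)^2)
  radial <- exp(-(grid$qr - q1)^2 / (2 * sig_r^2))
  iso <- !is.finite(disorder$sigma_phi) || disorder$sigma_phi >= 60
  if (iso) {
    azim <- rep(1, nrow(grid))
  } else {
    sig_p <- sqrt((disorder$sigma_phi * pi / 180)^2 +
                  (finite_size_q / q1)^2 + 1e-4)
    # orientation 0 (rows along y, stacked along x): first-shell peaks at
    # 0, 60, ... degrees from the incidence axis x
    peaks <- (spec$orientation + seq(0, 300, by = 60)) * pi / 180
    azim <- rep(0, nrow(grid))
    for (p0 in peaks) {
      dphi <- (grid$phi - p0 + pi) %% (2 * pi) - pi
      azim <- azim + exp(-dphi^2 / (2 * sig_p^2))
    }
    azim <- azim / max(azim)
  }
  S <- radial * azim
  structure(list(q = cbind(grid$qr * cos(grid$phi), grid$qr * sin(grid$phi)),
                 S = S / max(S), weight = rep(1, nrow(grid)), q1 = q1,
                 qr = qr, phi = phi, isotropic = iso),
            class = "target_sq")
}

# normalized structure factor of an ensemble on arbitrary q points,
# max-normalized over the point set
sq_on_points <- function(pos, q) {
  n <- nrow(pos)
  ph <- q %*% t(pos)
  Fre <- rowSums(cos(ph)); Fim <- rowSums(sin(ph))
  (Fre^2 + Fim^2) / n
}

#' Generate a disordered hard-disk ensemble by inverse design
#'
#' Starting from a configuration matched to the requested disorder level
#' (cumulative row-stacking noise of `sigma_k * d` per row plus particle
#' jitter for positional disorder; slab-wise lattice rotations of standard
#' deviation `sigma_phi` for orientational disorder; both heavy plus
#' uniform rotations for the isotropic limit), particle positions are then
#' gradually changed by single-particle Gaussian moves (step `a/10`, with
#' occasional larger kicks when the target is isotropic) with hard-disk
#' overlap rejection, accepting moves by quasi-greedy simulated annealing
#' on the weighted squared deviation between the ensemble structure factor
#' and the target on the first-shell polar grid. The default target is the
#' perfect finite lattice's own structure factor convolved radially with
#' `sigma_k * q1` and azimuthally with `sigma_phi`
#' ([target_sq_empirical()]), so the zero-disorder limit is exactly
#' attainable and the optimizer only broadens the Bragg peaks as far as
#' the disorder specification demands. The
#' objective history is returned; if it stagnates above `tol` the best
#' configuration so far is returned with a warning.
#'
#' @param spec a [lattice_spec()].
#' @param disorder a [disorder_spec()].
#' @param target optional [target_sq()] (built from `spec`/`disorder` by
#'   default).
#' @param n_iter total single-particle move attempts (default `400 * N`).
#' @param t_start,t_factor initial annealing temperature (relative to the
#'   initial objective; the low default keeps the optimizer quasi-greedy,
#'   so disorder enters only as far as the broadened target demands) and
#'   geometric cooling factor per sweep.
#' @param tol objective value considered converged.
#' @return a [particle_ensemble()] with attributes `"objective"` (final),
#'   `"objective_trace"` (per sweep) and `"target"`.
#' @export
generate_disordered <- function(spec, disorder, target = NULL,
                                n_iter = NULL, t_start = 0.01,
                                t_factor = 0.9, tol = 5e-3) {
  if (is.null(target)) target <- target_sq_empirical(spec, disorder)
  set.seed(disorder$seed)
  ens0 <- disorder_start(spec, disorder)
  p <- ens0$positions
  n <- nrow(p)
  a <- 2 * ens0$radius
  box <- ens0$box
  periodic <- ens0$periodic_y
  if (is.null(n_iter)) n_iter <- (if (target$isotropic) 1000L else 150L) * n
  q <- target$q
  w <- target$weight
  # running complex amplitudes F(q) = sum_j exp(i q.r_j)
  ph <- q %*% t(p)
  Fre <- rowSums(cos(ph)); Fim <- rowSums(sin(ph))
  Starget <- target$S
  objective <- function(Fre, Fim) {
    S <- (Fre^2 + Fim^2) / n
    S <- S / max(S)
    sum(w * (S - Starget)^2) / sum(w)
  }
  obj <- objective(Fre, Fim)
  obj0 <- max(obj, 1e-12)
  best <- list(p = p, obj = obj)
  temp <- t_start * obj0
  step <- a / 10
  sweep_len <- max(n, 50L)
  trace <- obj
  for (it in seq_len(n_iter)) {
    i <- sample.int(n, 1)
    kick <- if (target$isotropic && it %% 7 == 0) 4 * step else step
    cand <- p[i, ] + rnorm(2, 0, kick)
    cand[1] <- min(max(cand[1], 0), box[1])
    cand[2] <- if (periodic) cand[2] %% box[2] else min(max(cand[2], 0), box[2])
    dxv <- p[-i, 1] - cand[1]
    dyv <- p[-i, 2] - cand[2]
    if (periodic) dyv <- dyv - round(dyv / box[2]) * box[2]
    if (any(dxv^2 + dyv^2 < a^2)) next
    ph_old <- q %*% p[i, ]
    ph_new <- q %*% cand
    Fre2 <- Fre - cos(ph_old) + cos(ph_new)
    Fim2 <- Fim - sin(ph_old) + sin(ph_new)
    obj2 <- objective(Fre2, Fim2)
    if (obj2 <= obj || runif(1) < exp(-(obj2 - obj) / max(temp, 1e-15))) {
      p[i, ] <- cand
      Fre <- Fre2; Fim <- Fim2
      obj <- obj2
      if (obj < best$obj) best <- list(p = p, obj = obj)
    }
    if (it %% sweep_len == 0) {
      temp <- temp * t_factor
      trace <- c(trace, best$obj)
      if (best$obj < tol) break
    }
  }
  if (best$obj >= tol)
    warning(sprintf("inverse design stagnated at objective %.4g (tol %.4g); returning best-so-far",
                    best$obj, tol))
  out <- particle_ensemble(best$p, ens0$radius, box, periodic_y = periodic,
                           check = FALSE)
  attr(out, "objective") <- best$obj
  attr(out, "objective_trace") <- trace
  attr(out, "target") <- target
  out
}

#' Empirical disorder target: the finite lattice's S(q), broadened
#'
#' Measures the structure factor of the perfect finite packing of `spec`
#' on the first-shell polar grid and convolves it radially with a Gaussian
#' of width `sigma_k * q1` and azimuthally with `sigma_phi` (uniformized
#' at the isotropic limit). Unlike the analytic [target_sq()], this target
#' carries the finite-size peak shape, so it is exactly attainable at zero
#' disorder; it is the default objective of [generate_disordered()].
#'
#' @param spec a [lattice_spec()].
#' @param disorder a [disorder_spec()].
#' @param n_radial,n_azimuthal polar grid resolution.
#' @return a `target_sq` object.
#' @export
target_sq_empirical <- function(spec, disorder, n_radial = 17,
                                n_azimuthal = 72) {
  base <- target_sq(spec, disorder, n_radial = n_radial,
                    n_azimuthal = n_azimuthal)
  ens0 <- make_hexagonal(spec)
  S0 <- matrix(sq_on_points(ens0$positions, base$q),
               n_radial, n_azimuthal)
  q1 <- base$q1
  # radial blur
  if (disorder$sigma_k > 0) {
    sig <- disorder$sigma_k * q1
    dq <- outer(base$qr, base$qr, "-")
    K <- exp(-dq^2 / (2 * sig^2))
    K <- K / rowSums(K)
    S0 <- K %*% S0
  }
  # azimuthal blur (circular)
  iso <- base$isotropic
  if (iso) {
    S0 <- matrix(rowMeans(S0), n_radial, n_azimuthal)
  } else if (disorder$sigma_phi > 0) {
    sig <- disorder$sigma_phi * pi / 180
    dphi <- outer(base$phi, base$phi, "-")
    dphi <- (dphi + pi) %% (2 * pi) - pi
    K <- exp(-dphi^2 / (2 * sig^2))
    K <- K / rowSums(K)
    S0 <- S0 %*% t(K)
  }
  base$S <- as.vector(S0) / max(S0)
  base
}

# disorder-matched initial configuration for the inverse design:
# cumulative row-stacking noise + particle jitter realize sigma_k;
# slab-wise lattice rotations realize sigma_phi; overlaps are resolved by
# rejection resampling around the displaced sites.
disorder_start <- function(spec, disorder, max_tries = 200) {
  ens0 <- make_hexagonal(spec)
  sites <- ens0$positions
  a <- spec$a
  iso <- !is.finite(disorder$sigma_phi) || disorder$sigma_phi >= 60
  # grain-wise rotations about the grain centres: a 2D block partition of
  # roughly 600-700 nm grains, each rotated independently; misaligned
  # grains both detune the Bragg condition and cut the coherent stack
  sig_phi <- if (iso) 30 else disorder$sigma_phi
  if (sig_phi > 0) {
    ngx <- max(2, round(spec$box[1] / 650))
    ngy <- max(2, round(spec$box[2] / 650))
    gx <- findInterval(sites[, 1],
                       quantile(sites[, 1], seq(0, 1, length.out = ngx + 1)),
                       all.inside = TRUE)
    gy <- findInterval(sites[, 2],
                       quantile(sites[, 2], seq(0, 1, length.out = ngy + 1)),
                       all.inside = TRUE)
    grain <- gx + ngx * (gy - 1)
    for (g in unique(grain)) {
      idx <- grain == g
      ang <- if (iso) runif(1, -90, 90) * pi / 180
             else rnorm(1, 0, sig_phi) * pi / 180
      ctr <- colMeans(sites[idx, , drop = FALSE])
      rel <- sweep(sites[idx, , drop = FALSE], 2, ctr)
      rot <- cbind(c(cos(ang), sin(ang)), c(-sin(ang), cos(ang)))
      sites[idx, ] <- sweep(rel %*% rot, 2, ctr, "+")
    }
  }
  # cumulative row-stacking (paracrystalline) noise along x
  if (disorder$sigma_k > 0) {
    xr <- sort(unique(round(ens0$positions[, 1], 6)))
    shift <- cumsum(rnorm(length(xr), 0, disorder$sigma_k * spec$d))
    row_of <- match(round(ens0$positions[, 1], 6), xr)
    sites[, 1] <- sites[, 1] + shift[row_of]
  }
  jit <- max(disorder$sigma_k * spec$d / 2, if (iso) 15 else 0.5)
  # rejection resampling around displaced sites, honouring hard disks
  box <- spec$box
  p <- matrix(NA_real_, nrow(sites), 2)
  for (i in seq_len(nrow(sites))) {
    for (t in seq_len(max_tries)) {
      cand <- sites[i, ] + rnorm(2, 0, jit) * min(t, 10)
      cand[1] <- min(max(cand[1], a / 2), box[1] - a / 2)
      cand[2] <- cand[2] %% box[2]
      placed <- which(!is.na(p[, 1]))
      if (length(placed)) {
        dxv <- p[placed, 1] - cand[1]
        dyv <- p[placed, 2] - cand[2]
        dyv <- dyv - round(dyv / box[2]) * box[2]
        if (any(dxv^2 + dyv^2 < a^2)) next
      }
      p[i, ] <- cand
      break
    }
  }
  ok <- !is.na(p[, 1])
  particle_ensemble(p[ok, , drop = FALSE], a / 2, box, periodic_y = TRUE,
                    check = FALSE)
}

#' Bond-orientational order parameter psi-6
#'
#' `psi6 = | mean_i (1/n_i) sum_j exp(6 i theta_ij) |` over neighbours
#' within `r_cut` (default 1.35 nearest-neighbour estimates). 1 for a
#' perfect hexagonal lattice, near 0 for an isotropic packing.
#'
#' @param ens a [particle_ensemble()].
#' @param r_cut neighbour cutoff in nm (default 1.35 x the minimum pair
#'   distance).
#' @return scalar in \[0, 1\].
#' @export
psi6 <- function(ens, r_cut = NULL) {
  p <- ens$positions
  n <- nrow(p)
  if (is.null(r_cut)) r_cut <- 1.35 * min_pair_distance(ens)
  dxm <- outer(p[, 1], p[, 1], "-")
  dym <- outer(p[, 2], p[, 2], "-")
  if (ens$periodic_y) dym <- dym - round(dym / ens$box[2]) * ens$box[2]
  dm <- sqrt(dxm^2 + dym^2)
  vals <- complex(real = 0, imaginary = 0)
  cnt <- 0
  for (i in seq_len(n)) {
    nb <- which(dm[i, ] > 0 & dm[i, ] <= r_cut)
    if (length(nb) < 2) next
    ang <- atan2(dym[nb, i], dxm[nb, i])
    vals <- vals + mean(exp(6i * ang))
    cnt <- cnt + 1
  }
  if (cnt == 0) return(0)
  Mod(vals / cnt)
}
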
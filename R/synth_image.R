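#' Synthesize an electron-microscopy style cross-section image
#'
#' Bright disks (cell cross-sections, diameter `a`) on a dark background at
#' hexagonal lattice sites (spacing `d`), each displaced by i.i.d. Gaussian
#' jitter, then Gaussian-blurred and corrupted with pixel noise. The exact
#' generating ensemble is returned as ground truth so lattice-recovery
#' estimators can be validated. Jitter draws that would overlap disks are
#' rejected and redrawn; the count of rejections is reported.
#'
#' @param d lattice constant in nm.
#' @param a disk diameter in nm (`a <= d`).
#' @param pixel_nm pixel size in nm; must resolve the disks
#'   (`pixel_nm <= a / 10`).
#' @param n_cells number of lattice sites along each axis (image spans
#'   roughly `n_cells * d` square).
#' @param jitter_nm standard deviation of the site displacement in nm.
#' @param blur_sigma_px Gaussian blur in pixels.
#' @param noise_sigma additive Gaussian pixel noise in gray levels
#'   (image scale 0..1, so e.g. `10/255`); clipped to \[0, 1\].
#' @param seed RNG seed (optional).
#' @return list: `image` (matrix in \[0,1\], rows = y), `pixel_nm`,
#'   `truth` (a [particle_ensemble()]), `rejections`.
#' @export
synth_em_image <- function(d, a, pixel_nm, n_cells = 12, jitter_nm = 0,
                           blur_sigma_px = 0, noise_sigma = 0, seed = NULL) {
  stopifnot(a <= d, pixel_nm <= a / 10)
  if (!is.null(seed)) set.seed(seed)
  rowsp <- sqrt(3) / 2 * d
  nrows <- max(3, round(n_cells * d / rowsp))
  margin <- d
  Lx <- (n_cells - 1) * d + 2 * margin
  Ly <- (nrows - 1) * rowsp + 2 * margin
  sites <- NULL
  for (ir in 0:(nrows - 1)) {
    off <- if (ir %% 2 == 0) 0 else d / 2
    sites <- rbind(sites, cbind(margin + (0:(n_cells - 1)) * d + off,
                                margin + ir * rowsp))
  }
  rejections <- 0L
  pos <- sites
  if (jitter_nm > 0) {
    if (jitter_nm > d) stop("jitter too large for rejection sampling")
    for (i in seq_len(nrow(sites))) {
      for (try in 1:200) {
        cand <- sites[i, ] + rnorm(2, 0, jitter_nm)
        dd <- sqrt(colSums((t(pos[-i, , drop = FALSE]) - cand)^2))
        if (all(dd >= a)) break
        rejections <- rejections + 1L
        if (try == 200) stop("jitter rejection rate too high; reduce jitter_nm")
      }
      pos[i, ] <- cand
    }
  }
  nx <- ceiling(Lx / pixel_nm); ny <- ceiling(Ly / pixel_nm)
  xs <- (seq_len(nx) - 0.5) * pixel_nm
  ys <- (seq_len(ny) - 0.5) * pixel_nm
  img <- matrix(0, ny, nx)
  R <- a / 2
  for (i in seq_len(nrow(pos))) {
    jx <- which(abs(xs - pos[i, 1]) <= R + pixel_nm)
    jy <- which(abs(ys - pos[i, 2]) <= R + pixel_nm)
    if (!length(jx) || !length(jy)) next
    r2 <- outer(ys[jy] - pos[i, 2], xs[jx] - pos[i, 1],
                function(dy, dx) dy^2 + dx^2)
    # soft edge over one pixel for sub-pixel accuracy
    v <- pmin(pmax((R - sqrt(r2)) / pixel_nm + 0.5, 0), 1)
    img[jy, jx] <- pmax(img[jy, jx], v)
  }
  if (blur_sigma_px > 0) img <- gaussian_blur(img, blur_sigma_px)
  if (noise_sigma > 0)
    img <- pmin(pmax(img + matrix(rnorm(length(img), 0, noise_sigma),
                                  nrow(img)), 0), 1)
  truth <- particle_ensemble(pos, R, c(Lx, Ly), check = FALSE)
  list(image = img, pixel_nm = pixel_nm, truth = truth,
       rejections = rejections)
}

# separable Gaussian blur with edge replication
gaussian_blur <- function(img, sigma_px) {
  half <- max(1, ceiling(3 * sigma_px))
  ker <- dnorm(seq(-half, half), 0, sigma_px)
  ker <- ker / sum(ker)
  conv1 <- function(v) {
    padded <- c(rep(v[1], half), v, rep(v[length(v)], half))
    stats::filter(padded, ker, sides = 2)[(half + 1):(half + length(v))]
  }
  img <- apply(img, 2, conv1)
  t(apply(img, 1, conv1))
}

#' Read / write grayscale PNG images
#'
#' Thin wrappers over the `png` package mapping to/from plain matrices in
#' \[0, 1\] (rows = y, columns = x). RGB input is converted to luminance.
#'
#' @param path file path.
#' @return [read_image_png()]: numeric matrix; [write_image_png()]: `path`.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1] * 0.299 + a[, , 2] * 0.587 + a[, , 3] * 0.114
  a
}

#' @rdname read_image_png
#' @param img matrix in \[0, 1\].
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
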
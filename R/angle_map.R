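#' Angle-resolved scattering map
#'
#' The central experimental object of scattering goniometry: scattered
#' intensity on a (detection angle, wavelength) grid for a single incidence
#' angle. A region of about `blind_halfwidth` degrees around the incidence
#' angle carries no signal (the detector arm occludes the source there);
#' those cells are stored as `NA`, never as zero.
#'
#' @param theta_in incidence angle in degrees (signed; the source sits at
#'   negative angles, so the specular direction is `-theta_in`).
#' @param theta_out detection-angle grid in degrees, strictly increasing,
#'   within \[-90, 90\].
#' @param wavelength wavelength grid in nm, strictly increasing.
#' @param intensity matrix of non-negative intensities,
#'   `length(theta_out)` x `length(wavelength)`; `NA` marks missing cells.
#' @param blind_halfwidth half-width in degrees of the blind region around
#'   `theta_in` (default 5).
#' @return object of class `angle_map`.
#' @seealso [read_angle_map()], [synth_goniometer_map()]
#' @export
angle_map <- function(theta_in, theta_out, wavelength, intensity,
                      blind_halfwidth = 5) {
  stopifnot(length(theta_in) == 1, is.finite(theta_in))
  if (length(theta_out) < 2 || any(diff(theta_out) <= 0))
    stop("theta_out grid must be strictly increasing")
  if (any(theta_out < -90) || any(theta_out > 90))
    stop("theta_out must lie within [-90, 90]")
  if (length(wavelength) < 2 || any(diff(wavelength) <= 0))
    stop("wavelength grid must be strictly increasing")
  intensity <- as.matrix(intensity)
  if (!all(dim(intensity) == c(length(theta_out), length(wavelength))))
    stop("intensity must be a length(theta_out) x length(wavelength) matrix")
  if (any(intensity < 0, na.rm = TRUE))
    stop("negative intensity")
  blind <- abs(theta_out - theta_in) <= blind_halfwidth
  intensity[blind, ] <- NA_real_
  structure(
    list(theta_in = theta_in, theta_out = theta_out,
         wavelength = wavelength, intensity = intensity,
         blind_halfwidth = blind_halfwidth),
    class = "angle_map")
}

#' @export
print.angle_map <- function(x, ...) {
  cat(sprintf(
    "<angle_map> theta_in = %g deg; %d theta_out x %d wavelengths (%g-%g nm); blind +/-%g deg\n",
    x$theta_in, length(x$theta_out), length(x$wavelength),
    min(x$wavelength), max(x$wavelength), x$blind_halfwidth))
  invisible(x)
}

#' Read / write angle-resolved maps as TSV
#'
#' Plain-text format: `#`-prefixed metadata lines (`theta_in`,
#' `blind_halfwidth`), then a header row `theta_out` followed by the
#' wavelength grid, then one row per detection angle. Missing cells are the
#' literal string `NA`.
#'
#' @param path file path.
#' @return [read_angle_map()] returns an `angle_map`; [write_angle_map()]
#'   returns `path` invisibly.
#' @export
read_angle_map <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default = NULL) {
    m <- grep(sprintf("^#\\s*%s:", key), meta, value = TRUE)
    if (!length(m)) {
      if (is.null(default)) stop("missing metadata line: ", key)
      return(default)
    }
    as.numeric(trimws(sub(".*:", "", m[1])))
  }
  theta_in <- get_meta("theta_in")
  blind <- get_meta("blind_halfwidth", 5)
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "theta_out") stop("malformed map file: no theta_out header")
  wavelength <- as.numeric(header[-1])
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  dat <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                nrow = length(rows), byrow = TRUE)
  theta_out <- dat[, 1]
  if (any(diff(theta_out) <= 0) || any(diff(wavelength) <= 0))
    stop("non-monotonic grid in map file")
  angle_map(theta_in, theta_out, wavelength, dat[, -1, drop = FALSE],
            blind_halfwidth = blind)
}

#' @rdname read_angle_map
#' @param map an `angle_map`.
#' @export
write_angle_map <- function(map, path) {
  stopifnot(inherits(map, "angle_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# theta_in: %.10g", map$theta_in),
               sprintf("# blind_halfwidth: %.10g", map$blind_halfwidth)), con)
  writeLines(paste(c("theta_out", format(map$wavelength, digits = 10,
                                         trim = TRUE)), collapse = "\t"), con)
  body <- cbind(map$theta_out, map$intensity)
  writeLines(apply(body, 1, function(r)
    paste(ifelse(is.na(r), "NA", format(r, digits = 10, trim = TRUE)),
          collapse = "\t")), con)
  invisible(path)
}

#' Specular reflection trace
#'
#' Ridge wavelength of the specular reflection as a function of incidence
#' angle, the object fitted by [fit_specular()].
#'
#' @param theta_in incidence-angle grid in degrees.
#' @param lambda_s ridge wavelength in nm, one value per angle.
#' @param intensity optional non-negative ridge intensity.
#' @return object of class `specular_trace`.
#' @export
specular_trace <- function(theta_in, lambda_s, intensity = NULL) {
  stopifnot(length(theta_in) == length(lambda_s))
  if (is.null(intensity)) intensity <- rep(1, length(theta_in))
  if (any(intensity < 0, na.rm = TRUE)) stop("negative intensity")
  o <- order(theta_in)
  structure(list(theta_in = theta_in[o], lambda_s = lambda_s[o],
                 intensity = intensity[o]),
            class = "specular_trace")
}
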
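#' Hard-disk particle ensemble
#'
#' 2D disk centres with a common radius inside a rectangular box, the
#' cross-section representation of packed cells used by the FDTD and
#' structure-factor modules. Disks are hard: centre separations below one
#' diameter are a validation error (touching is allowed).
#'
#' @param positions two-column matrix of centres (x, y) in nm.
#' @param radius disk radius in nm (single value).
#' @param box box dimensions `c(Lx, Ly)` in nm.
#' @param periodic_y logical; if `TRUE`, distances wrap in y (the lateral
#'   direction of the FDTD cell).
#' @param check if `FALSE`, skip the O(N^2) overlap validation.
#' @return object of class `particle_ensemble`.
#' @export
particle_ensemble <- function(positions, radius, box, periodic_y = FALSE,
                              check = TRUE) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2, radius > 0, length(box) == 2)
  colnames(positions) <- c("x", "y")
  if (nrow(positions)) {
    inx <- positions[, 1] >= -1e-9 & positions[, 1] <= box[1] + 1e-9
    iny <- positions[, 2] >= -1e-9 & positions[, 2] <= box[2] + 1e-9
    if (!all(inx & iny))
      stop("particle centre outside box (first offender: row ",
           which(!(inx & iny))[1], ")")
  }
  ens <- structure(list(positions = positions, radius = radius,
                        box = as.numeric(box), periodic_y = periodic_y),
                   class = "particle_ensemble")
  if (check && nrow(positions) > 1) {
    bad <- find_overlap(ens)
    if (!is.null(bad))
      stop(sprintf("overlapping disks: particles %d and %d at distance %.6g < diameter %.6g",
                   min(bad[1:2]), max(bad[1:2]), bad[3], 2 * radius))
  }
  ens
}

#' @export
print.particle_ensemble <- function(x, ...) {
  cat(sprintf("<particle_ensemble> N = %d disks, radius %g nm, box %g x %g nm%s\n",
              nrow(x$positions), x$radius, x$box[1], x$box[2],
              if (x$periodic_y) ", periodic in y" else ""))
  invisible(x)
}

# pairwise minimum-image distances; returns c(i, j, dist) of first violating
# pair or NULL. tol absorbs floating-point touching.
find_overlap <- function(ens, tol = 1e-6) {
  p <- ens$positions
  n <- nrow(p)
  dxm <- outer(p[, 1], p[, 1], "-")
  dym <- outer(p[, 2], p[, 2], "-")
  if (ens$periodic_y) dym <- dym - round(dym / ens$box[2]) * ens$box[2]
  dm <- sqrt(dxm^2 + dym^2)
  dm[upper.tri(dm, diag = TRUE)] <- Inf
  i <- which(dm < 2 * ens$radius - tol, arr.ind = TRUE)
  if (!nrow(i)) return(NULL)
  k <- which.min(dm[i])
  c(i[k, 1], i[k, 2], dm[i[k, 1], i[k, 2]])
}

#' Minimum pairwise centre distance
#' @param ens a [particle_ensemble()].
#' @return smallest centre-to-centre distance in nm (minimum-image in y if
#'   the ensemble is y-periodic).
#' @export
min_pair_distance <- function(ens) {
  p <- ens$positions
  if (nrow(p) < 2) return(Inf)
  dxm <- outer(p[, 1], p[, 1], "-")
  dym <- outer(p[, 2], p[, 2], "-")
  if (ens$periodic_y) dym <- dym - round(dym / ens$box[2]) * ens$box[2]
  dm <- sqrt(dxm^2 + dym^2)
  min(dm[lower.tri(dm)])
}

#' Read / write particle ensembles as TSV
#'
#' Format: `#`-prefixed metadata (`radius_nm`, `box_nm`, `periodic_y`),
#' then a `x_nm<TAB>y_nm` header and one row per disk.
#'
#' @param path file path.
#' @return [read_particles()] returns a `particle_ensemble`;
#'   [write_particles()] returns `path` invisibly.
#' @export
read_particles <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  val <- function(key) {
    m <- grep(sprintf("^#\\s*%s:", key), meta, value = TRUE)
    if (!length(m)) stop("missing metadata line: ", key)
    trimws(sub(".*:", "", m[1]))
  }
  radius <- as.numeric(val("radius_nm"))
  box <- as.numeric(strsplit(val("box_nm"), "\\s+")[[1]])
  periodic <- toupper(val("periodic_y")) %in% c("TRUE", "1", "YES")
  body <- lines[!grepl("^#", lines)]
  stopifnot(grepl("^x_nm\ty_nm", body[1]))
  if (length(body) > 1) {
    dat <- matrix(as.numeric(unlist(strsplit(body[-1], "\t", fixed = TRUE))),
                  ncol = 2, byrow = TRUE)
  } else dat <- matrix(numeric(), 0, 2)
  particle_ensemble(dat, radius, box, periodic_y = periodic)
}

#' @rdname read_particles
#' @param ens a `particle_ensemble`.
#' @export
write_particles <- function(ens, path) {
  stopifnot(inherits(ens, "particle_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# radius_nm: %.10g", ens$radius),
               sprintf("# box_nm: %.10g %.10g", ens$box[1], ens$box[2]),
               sprintf("# periodic_y: %s", ens$periodic_y),
               "x_nm\ty_nm"), con)
  if (nrow(ens$positions))
    writeLines(apply(ens$positions, 1, function(r)
      paste(format(r, digits = 10, trim = TRUE), collapse = "\t")), con)
  invisible(path)
}
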
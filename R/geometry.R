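#' Geometry objects and internal coordinates
#'
#' A `geometry` holds element symbols and Cartesian coordinates (Angstrom)
#' for one conformer. Internal-coordinate helpers compute distances, bond
#' angles and dihedral (torsion) angles with the IUPAC sign convention.
#'
#' @name geometry
NULL

#' Construct a geometry
#'
#' @param atoms character vector of element symbols.
#' @param coords numeric N x 3 matrix of Cartesian coordinates in Angstrom.
#' @param conformer_id identifier string, unique within an ensemble.
#' @return An object of class `geometry` with fields `atoms`, `coords`,
#'   `conformer_id`.
#' @export
geometry <- function(atoms, coords, conformer_id = "conf") {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L)
    stop("`coords` must be a numeric N x 3 matrix")
  if (length(atoms) != nrow(coords))
    stop("length(atoms) must equal nrow(coords)")
  if (!all(is.finite(coords)))
    stop("coordinates must be finite")
  structure(
    list(atoms = as.character(atoms), coords = unname(coords),
         conformer_id = as.character(conformer_id)),
    class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry '%s': %d atoms>\n", x$conformer_id, length(x$atoms)))
  invisible(x)
}

#' Read a (multi-frame) XYZ file
#'
#' Standard XYZ: an atom-count line, a comment line (used as the conformer
#' id when non-empty, otherwise the 0-based frame index), then one
#' `element x y z` record per atom.
#'
#' @param path path to an XYZ file, possibly holding several frames.
#' @return List of [geometry()] objects, one per frame.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  ## drop trailing blank lines only; blanks inside a frame are malformed
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop(sprintf("XYZ parse error in frame %d: bad atom count at line %d",
                   frame, i))
    if (i + 1L + n > length(lines))
      stop(sprintf(
        "XYZ parse error in frame %d: %d atoms declared but file ends early",
        frame, n))
    comment <- trimws(lines[i + 1L])
    id <- if (nzchar(comment)) comment else as.character(frame)
    rec <- lines[(i + 2L):(i + 1L + n)]
    atoms <- character(n)
    coords <- matrix(NA_real_, n, 3L)
    for (k in seq_len(n)) {
      f <- strsplit(trimws(rec[k]), "\\s+")[[1]]
      if (length(f) < 4L)
        stop(sprintf("XYZ parse error in frame %d, line %d: expected 'El x y z'",
                     frame, i + 1L + k))
      xyz <- suppressWarnings(as.numeric(f[2:4]))
      if (anyNA(xyz))
        stop(sprintf("XYZ parse error in frame %d, line %d: non-numeric coordinate",
                     frame, i + 1L + k))
      atoms[k] <- f[1]
      coords[k, ] <- xyz
    }
    out[[length(out) + 1L]] <- geometry(atoms, coords, id)
    i <- i + 2L + n
    frame <- frame + 1L
  }
  out
}

#' Write geometries to a multi-frame XYZ file
#'
#' @param geoms a [geometry()] or list of geometries.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geoms, path) {
  if (inherits(geoms, "geometry")) geoms <- list(geoms)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in geoms) {
    writeLines(as.character(length(g$atoms)), con)
    writeLines(g$conformer_id, con)
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f",
                       g$atoms, g$coords[, 1], g$coords[, 2], g$coords[, 3]),
               con)
  }
  invisible(path)
}

`%cross%` <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate geometry: zero-length vector")
  v / n
}

#' Interatomic distance
#'
#' @param geom a [geometry()].
#' @param i,j 1-based atom indices.
#' @return Distance in Angstrom.
#' @export
atom_distance <- function(geom, i, j) {
  sqrt(sum((geom$coords[i, ] - geom$coords[j, ])^2))
}

#' Bond angle
#'
#' @param geom a [geometry()].
#' @param i,j,k 1-based atom indices; `j` is the vertex.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
bond_angle <- function(geom, i, j, k) {
  u <- .unit(geom$coords[i, ] - geom$coords[j, ])
  v <- .unit(geom$coords[k, ] - geom$coords[j, ])
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Dihedral (torsion) angle
#'
#' IUPAC sign convention: looking down the j -> k bond, the angle is
#' positive when the far bond k -> l is rotated clockwise from the near
#' bond j -> i. Range is `(-180, 180]`. The identity
#' `dihedral(l,k,j,i) == dihedral(i,j,k,l)` holds (sign preserved on
#' reversal).
#'
#' @param geom a [geometry()].
#' @param i,j,k,l four distinct 1-based atom indices.
#' @return Torsion angle in degrees.
#' @export
dihedral <- function(geom, i, j, k, l) {
  idx <- c(i, j, k, l)
  if (anyDuplicated(idx) || any(idx < 1L) || any(idx > nrow(geom$coords)))
    stop("dihedral needs four distinct valid atom indices")
  p <- geom$coords
  b1 <- p[j, ] - p[i, ]
  b2 <- p[k, ] - p[j, ]
  b3 <- p[l, ] - p[k, ]
  n1 <- b1 %cross% b2
  n2 <- b2 %cross% b3
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("degenerate geometry: collinear atoms in dihedral")
  m1 <- n1 %cross% .unit(b2)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

#' Wrap an angle into (-180, 180]
#'
#' @param angle angle(s) in degrees.
#' @return Equivalent angle(s) in `(-180, 180]`.
#' @export
wrap_angle <- function(angle) {
  a <- ((angle + 180) %% 360) - 180
  a[a <= -180] <- a[a <= -180] + 360  # fold the closed end: -180 -> 180
  a
}

#' Place an atom from internal coordinates
#'
#' Returns the Cartesian position of an atom at distance `bond` from `c`,
#' with angle `angle` at `c` relative to `b`, and torsion `torsion` about
#' the b->c axis relative to `a` (so that `dihedral(a, b, c, new)` equals
#' `torsion` under the package's sign convention). This is the standard
#' sequential internal-to-Cartesian (Z-matrix / NeRF) placement.
#'
#' @param a,b,c length-3 numeric reference positions.
#' @param bond bond length, Angstrom.
#' @param angle bond angle at `c`, degrees.
#' @param torsion dihedral angle, degrees.
#' @return Length-3 numeric position.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit((b - a) %cross% bc)
  m <- bc %cross% n
  d2 <- c(-bond * cos(ang),
          -bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
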
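#' Torsion-state classification and conformer naming
#'
#' Rotamer states of the classifiable torsions are labelled `G+`, `G-` or
#' `T` (upper-case role) and `g+`, `g-` or `t` (lower-case role) for
#' torsion angles near +60, -60 and 180 degrees respectively. A systematic
#' conformer name joins, with slashes: the ring hydroxymethyl pair (e.g.
#' `G-g+`), the OH...O contact-network direction (`cc` or `c`), the phenyl
#' torsion label, and for gastrodin-like molecules the phenyl
#' hydroxymethyl pair (e.g. `G+g-`).
#'
#' @name conformer_naming
NULL

.canonical_angles <- c(60, -60, 180)
.upper_labels <- c("G+", "G-", "T")
.lower_labels <- c("g+", "g-", "t")

#' Classify a torsion angle into a rotamer label
#'
#' Assigns the nearest of the canonical angles +60, -60 and 180 degrees
#' under the circular (wrap-around) metric. The rule is total and
#' parameter-free; at the exact decision boundaries (0 and +/-120 degrees,
#' equidistant from two canonical angles) the lexicographically first
#' candidate label is chosen and a warning is emitted.
#'
#' @param angle torsion angle in degrees; any real value is accepted and
#'   wrapped into `(-180, 180]` first.
#' @param case `"upper"` for `G+`/`G-`/`T`, `"lower"` for `g+`/`g-`/`t`.
#' @return An object of class `torsion_label` with fields `value` (the
#'   label) and `angle` (the wrapped input angle).
#' @export
classify_torsion <- function(angle, case = c("upper", "lower")) {
  case <- match.arg(case)
  a <- wrap_angle(angle)
  d <- abs(wrap_angle(a - .canonical_angles))
  labels <- if (case == "upper") .upper_labels else .lower_labels
  tied <- which(abs(d - min(d)) < 1e-9)
  if (length(tied) > 1L) {
    pick <- tied[order(labels[tied])][1]
    warning(sprintf(
      "torsion angle %.6g deg lies on a classification boundary; assigning '%s'",
      a, labels[pick]))
  } else {
    pick <- tied
  }
  structure(list(value = labels[pick], angle = a), class = "torsion_label")
}

#' @export
print.torsion_label <- function(x, ...) {
  cat(sprintf("%s (%.1f deg)\n", x$value, x$angle))
  invisible(x)
}

#' @export
format.torsion_label <- function(x, ...) x$value

#' Detect intramolecular OH...O contacts
#'
#' Scans every ring hydroxyl (O, H) donor pair in the atom map against the
#' scaffold oxygen acceptors and records a contact wherever the H...O
#' distance is at or below `cutoff`. The donor's own oxygen is excluded.
#' The default cutoff of 2.7 Angstrom is a configuration knob: cooperative
#' OH...O contacts in these glycosides sit near 2.5 Angstrom, and the
#' slightly looser default tolerates thermal distortion. An optional
#' donor-angle filter (O-H...O angle >= `min_angle`) is available but off
#' by default.
#'
#' @param geom a [geometry()].
#' @param map an [atom_map()].
#' @param cutoff maximum H...O distance in Angstrom (default 2.7).
#' @param min_angle optional minimum O-H...O angle in degrees; `NULL`
#'   (default) disables the angle criterion.
#' @return Data frame with columns `donor` (hydroxyl site, e.g. `"O2"`),
#'   `acceptor` (scaffold oxygen label), `distance` (H...O, Angstrom).
#' @export
detect_contacts <- function(geom, map, cutoff = 2.7, min_angle = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  acceptors <- c("O1", "O5", "O6", "O2", "O3", "O4")
  if (map$molecule_class == "gastrodin") acceptors <- c(acceptors, "O7")
  out <- data.frame(donor = character(), acceptor = character(),
                    distance = numeric(), stringsAsFactors = FALSE)
  for (site in c("C2", "C3", "C4")) {
    pair <- map$hydroxyls[[site]]
    if (is.null(pair)) stop("atom map missing hydroxyl indices for ", site)
    o_i <- pair[1]; h_i <- pair[2]
    donor_lab <- sub("C", "O", site)
    for (acc in acceptors) {
      if (acc == donor_lab) next
      a_i <- map_index(map, acc)
      d <- atom_distance(geom, h_i, a_i)
      if (d <= cutoff) {
        if (!is.null(min_angle) &&
            bond_angle(geom, o_i, h_i, a_i) < min_angle) next
        out <- rbind(out, data.frame(donor = donor_lab, acceptor = acc,
                                     distance = d, stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Classify the ring-hydroxyl contact network as cc, c or none
#'
#' Only contacts among the ring hydroxyls at C2/C3/C4 (donors `O2`, `O3`,
#' `O4`; acceptors the same set of oxygens) count towards the chain. By
#' this package's convention the chain is counter-clockwise (`cc`) when
#' donor-to-acceptor links run in increasing ring position
#' (O2H -> O3, O3H -> O4) and clockwise (`c`) when decreasing
#' (O4H -> O3, O3H -> O2); set `invert_convention = TRUE` to swap the two
#' labels if reference structures indicate the opposite mapping. A
#' consistent chain needs at least two links; links in both directions
#' yield `"none"` with a warning record.
#'
#' @param contacts data frame from [detect_contacts()].
#' @param map an [atom_map()] (used only for its molecule class metadata).
#' @param invert_convention swap the `cc`/`c` labels.
#' @return An object of class `contact_network` with fields `direction`
#'   (`"cc"`, `"c"` or `"none"`), `contacts` (the ring-hydroxyl links
#'   used), `warning` (`NULL` or a message), and `convention`.
#' @export
classify_network <- function(contacts, map, invert_convention = FALSE) {
  ring <- c("O2", "O3", "O4")
  ct <- contacts[contacts$donor %in% ring & contacts$acceptor %in% ring, ,
                 drop = FALSE]
  pos <- function(lab) as.integer(sub("O", "", lab))
  step <- pos(ct$acceptor) - pos(ct$donor)
  inc <- ct[step == 1L, , drop = FALSE]
  dec <- ct[step == -1L, , drop = FALSE]
  warn <- NULL
  direction <- "none"
  if (nrow(inc) >= 2L && nrow(dec) == 0L) {
    direction <- "cc"
  } else if (nrow(dec) >= 2L && nrow(inc) == 0L) {
    direction <- "c"
  } else if (nrow(inc) > 0L && nrow(dec) > 0L) {
    warn <- "contradictory contact chain: links in both directions"
    warning(warn)
  }
  if (invert_convention && direction != "none")
    direction <- if (direction == "cc") "c" else "cc"
  structure(
    list(direction = direction, contacts = ct, warning = warn,
         convention = sprintf(
           "cc = donor->acceptor in increasing ring position%s",
           if (invert_convention) " (inverted)" else "")),
    class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("<contact_network: %s, %d ring links>\n",
              x$direction, nrow(x$contacts)))
  invisible(x)
}

.torsion_defs <- list(
  ring_upper   = list(atoms = c("O6", "C6", "C5", "O5"), case = "upper"),
  ring_lower   = list(atoms = c("H6", "O6", "C6", "C5"), case = "lower"),
  phenyl       = list(atoms = c("C2", "C1", "O1", "C7"), case = "upper"),
  phenyl_tilt  = list(atoms = c("C1", "O1", "C7", "C12"), case = NA),
  ph_ch2oh_upper = list(atoms = c("C11", "C10", "C13", "O7"), case = "upper"),
  ph_ch2oh_lower = list(atoms = c("C10", "C13", "O7", "H7"), case = "lower"))

.measure_torsion <- function(geom, map, def) {
  idx <- vapply(def$atoms, function(l) map_index(map, l), 1L)
  dihedral(geom, idx[1], idx[2], idx[3], idx[4])
}

#' Assemble the systematic conformer name
#'
#' Computes all classifiable torsions and the contact-network direction
#' and joins their labels into the systematic name: ring hydroxymethyl
#' pair, network, phenyl torsion, and (gastrodin only) the phenyl
#' hydroxymethyl pair, e.g. `"G-g+/cc/T"` or `"G-g+/cc/T/G+g-"`. The
#' phenyl tilt dihedral (C1-O1-C7-C12) is measured and reported but not
#' encoded in the name: its value tracks the phenyl torsion label
#' one-to-one, so labelling it separately would add no information.
#'
#' @param geom a [geometry()].
#' @param map an [atom_map()].
#' @param cutoff H...O contact cutoff, Angstrom (see [detect_contacts()]).
#' @param invert_convention see [classify_network()].
#' @return An object of class `conformer_name` with fields
#'   `ring_hydroxymethyl` (pair of [classify_torsion()] labels), `network`
#'   (a `contact_network`), `phenyl`, `phenyl_hydroxymethyl` (gastrodin
#'   only, else `NULL`), `phenyl_tilt_deg`, and `rendered` (the
#'   slash-joined string).
#' @export
assemble_name <- function(geom, map, cutoff = 2.7, invert_convention = FALSE) {
  up <- classify_torsion(.measure_torsion(geom, map, .torsion_defs$ring_upper),
                         "upper")
  lo <- classify_torsion(.measure_torsion(geom, map, .torsion_defs$ring_lower),
                         "lower")
  net <- classify_network(detect_contacts(geom, map, cutoff), map,
                          invert_convention)
  ph <- classify_torsion(.measure_torsion(geom, map, .torsion_defs$phenyl),
                         "upper")
  tilt <- .measure_torsion(geom, map, .torsion_defs$phenyl_tilt)
  parts <- c(paste0(up$value, lo$value), net$direction, ph$value)
  ph_hm <- NULL
  if (map$molecule_class == "gastrodin") {
    up2 <- classify_torsion(
      .measure_torsion(geom, map, .torsion_defs$ph_ch2oh_upper), "upper")
    lo2 <- classify_torsion(
      .measure_torsion(geom, map, .torsion_defs$ph_ch2oh_lower), "lower")
    ph_hm <- list(upper = up2, lower = lo2)
    parts <- c(parts, paste0(up2$value, lo2$value))
  }
  structure(
    list(ring_hydroxymethyl = list(upper = up, lower = lo),
         network = net, phenyl = ph, phenyl_hydroxymethyl = ph_hm,
         phenyl_tilt_deg = tilt,
         rendered = paste(parts, collapse = "/")),
    class = "conformer_name")
}

#' @export
print.conformer_name <- function(x, ...) {
  cat(x$rendered, "\n")
  invisible(x)
}

#' @export
format.conformer_name <- function(x, ...) x$rendered

#' Tabulate named internal coordinates of a conformer
#'
#' Produces a deterministic report of requested distances (Angstrom),
#' angles and dihedrals (degrees), addressed by chemical atom labels, in
#' the style of the structural-parameter tables used to compare the most
#' stable conformers.
#'
#' @param geom a [geometry()].
#' @param map an [atom_map()].
#' @param params named list; each element is a character vector of 2
#'   (distance), 3 (angle) or 4 (dihedral) chemical labels. Defaults to a
#'   standard set: the classifiable torsions, the phenyl tilt, and the
#'   ring-hydroxyl H...O contact distances.
#' @return Data frame with columns `name`, `type`, `atoms`, `value`.
#' @export
structural_report <- function(geom, map, params = NULL) {
  if (is.null(params)) {
    params <- list(
      `O6-C6-C5-O5` = c("O6", "C6", "C5", "O5"),
      `H6-O6-C6-C5` = c("H6", "O6", "C6", "C5"),
      `C2-C1-O1-C7` = c("C2", "C1", "O1", "C7"),
      `C1-O1-C7-C12` = c("C1", "O1", "C7", "C12"),
      `H2...O3` = c("H2", "O3"),
      `H3...O4` = c("H3", "O4"),
      `H3...O2` = c("H3", "O2"),
      `H4...O3` = c("H4", "O3"))
    if (map$molecule_class == "gastrodin") {
      params$`C11-C10-C13-O7` <- c("C11", "C10", "C13", "O7")
      params$`C10-C13-O7-H7` <- c("C10", "C13", "O7", "H7")
    }
  }
  rows <- lapply(names(params), function(nm) {
    labs <- params[[nm]]
    idx <- vapply(labs, function(l) map_index(map, l), 1L)
    val <- switch(as.character(length(idx)),
      "2" = atom_distance(geom, idx[1], idx[2]),
      "3" = bond_angle(geom, idx[1], idx[2], idx[3]),
      "4" = dihedral(geom, idx[1], idx[2], idx[3], idx[4]),
      stop("parameter '", nm, "' must list 2, 3 or 4 atoms"))
    data.frame(name = nm,
               type = c("2" = "distance", "3" = "angle",
                        "4" = "dihedral")[as.character(length(idx))],
               atoms = paste(labs, collapse = "-"),
               value = val, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
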
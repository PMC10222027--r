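#' Atom maps: naming the scaffold atoms of a glycoside
#'
#' Torsion classification needs to know which rows of an XYZ file are the
#' chemically named scaffold atoms (C1..C6, O1, O5, O6, H6, the phenyl
#' carbons C7..C12, the ring hydroxyls at C2/C3/C4, and for gastrodin-like
#' molecules the phenyl hydroxymethyl C13/O7/H7). Atom order in XYZ files
#' from different electronic-structure codes is arbitrary, so the mapping
#' is always explicit configuration and never inferred from connectivity.
#'
#' Config files (YAML or JSON) use **0-based** indices, the convention of
#' most structure-file tooling; they are converted to R's 1-based indexing
#' on load. The chemical labels C1, O5, ... are names, not file positions.
#'
#' @name atom_map
NULL

.scaffold_core <- c("C1", "C2", "C3", "C4", "C5", "C6",
                    "O1", "O5", "O6", "H6",
                    "C7", "C8", "C9", "C10", "C11", "C12")
.scaffold_gastrodin <- c("C13", "O7", "H7")

#' Construct an atom map
#'
#' @param indices named list or vector of 1-based atom indices for the
#'   scaffold atoms `C1..C6, O1, O5, O6, H6, C7..C12` and, for gastrodin
#'   class molecules, `C13, O7, H7`.
#' @param hydroxyls named list of `c(O, H)` 1-based index pairs for the
#'   ring hydroxyl groups, names `"C2"`, `"C3"`, `"C4"`.
#' @param molecule_class `"phb_glu"` or `"gastrodin"`.
#' @return An object of class `atom_map`.
#' @export
atom_map <- function(indices, hydroxyls,
                     molecule_class = c("phb_glu", "gastrodin")) {
  molecule_class <- match.arg(molecule_class)
  indices <- lapply(indices, as.integer)
  need <- .scaffold_core
  if (molecule_class == "gastrodin") need <- c(need, .scaffold_gastrodin)
  missing <- setdiff(need, names(indices))
  if (length(missing))
    stop("atom map is missing scaffold atoms: ", paste(missing, collapse = ", "))
  extra_g <- intersect(.scaffold_gastrodin, names(indices))
  if (molecule_class == "phb_glu" && length(extra_g))
    stop("phb_glu atom map must not define gastrodin atoms: ",
         paste(extra_g, collapse = ", "))
  if (!all(c("C2", "C3", "C4") %in% names(hydroxyls)))
    stop("hydroxyls must name the C2, C3 and C4 (O, H) pairs")
  hydroxyls <- lapply(hydroxyls, as.integer)
  if (any(vapply(hydroxyls, length, 1L) != 2L))
    stop("each hydroxyl entry must be an (O, H) index pair")
  all_idx <- c(unlist(indices[need]), unlist(hydroxyls[c("C2", "C3", "C4")]))
  if (any(all_idx < 1L))
    stop("atom indices must be >= 1 after conversion to 1-based")
  if (anyDuplicated(all_idx))
    stop("atom map indices must be distinct")
  structure(
    list(indices = indices[need],
         hydroxyls = hydroxyls[c("C2", "C3", "C4")],
         molecule_class = molecule_class),
    class = "atom_map")
}

#' @export
print.atom_map <- function(x, ...) {
  cat(sprintf("<atom_map: %s, %d scaffold atoms, 3 ring hydroxyls>\n",
              x$molecule_class, length(x$indices)))
  invisible(x)
}

#' Look up a named scaffold atom index
#'
#' @param map an [atom_map()].
#' @param label chemical label, e.g. `"C1"`, `"O5"`; hydroxyl oxygens and
#'   hydrogens at C2/C3/C4 are addressed as `"O2"`/`"H2"` etc.
#' @return 1-based atom index.
#' @export
map_index <- function(map, label) {
  if (label %in% names(map$indices)) return(map$indices[[label]])
  m <- regmatches(label, regexec("^([OH])([234])$", label))[[1]]
  if (length(m) == 3L) {
    pair <- map$hydroxyls[[paste0("C", m[3])]]
    return(if (m[2] == "O") pair[1] else pair[2])
  }
  stop("atom map cannot resolve label '", label, "'")
}

#' Read an atom map from a YAML or JSON config file
#'
#' The file holds `molecule_class`, an `atoms` mapping of chemical labels
#' to **0-based** indices, and a `hydroxyls` mapping of `C2`/`C3`/`C4` to
#' 0-based `[O, H]` pairs.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return An [atom_map()].
#' @export
read_atom_map <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$atoms) || is.null(cfg$hydroxyls))
    stop("atom map config must define 'atoms' and 'hydroxyls'")
  atom_map(lapply(cfg$atoms, function(i) as.integer(i) + 1L),
           lapply(cfg$hydroxyls, function(p) as.integer(p) + 1L),
           molecule_class = cfg$molecule_class %||% "phb_glu")
}

#' Write an atom map to YAML (0-based indices)
#'
#' @param map an [atom_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_atom_map <- function(map, path) {
  yaml::write_yaml(
    list(molecule_class = map$molecule_class,
         atoms = lapply(map$indices, function(i) i - 1L),
         hydroxyls = lapply(map$hydroxyls, function(p) p - 1L)),
    path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
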
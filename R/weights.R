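#' Conformer weight sets
#'
#' A `weights` object maps conformer ids to percentage populations and
#' records where those percentages came from: `"boltzmann"` (computed from
#' free energies), `"stated"` (transcribed from a published analysis), or
#' `"refined"` (fit against experimental spectra). Boltzmann and refined
#' weights must sum to 100; stated sets are preserved verbatim even when
#' they do not (published empirical weight lists occasionally sum to
#' slightly more or less than 100), and normalization is always explicit,
#' never silent.
#'
#' @param x named numeric vector: conformer id -> percentage (>= 0).
#' @param provenance one of `"boltzmann"`, `"stated"`, `"refined"`.
#' @return An object of class `conformer_weights`.
#' @export
conformer_weights <- function(x,
                              provenance = c("boltzmann", "stated",
                                             "refined")) {
  provenance <- match.arg(provenance)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("weights must be a named numeric vector (conformer id -> percent)")
  if (anyDuplicated(names(x))) stop("conformer ids must be unique")
  if (any(x < 0)) stop("weights must be non-negative")
  if (provenance != "stated" && abs(sum(x) - 100) > 1e-9)
    stop(sprintf("%s weights must sum to 100 (got %.12g)", provenance, sum(x)))
  structure(list(percent = x, provenance = provenance),
            class = "conformer_weights")
}

#' @export
print.conformer_weights <- function(x, digits = 2, ...) {
  cat(sprintf("<conformer_weights: %s, %d conformers, total %.6g%%>\n",
              x$provenance, length(x$percent), sum(x$percent)))
  print(round(x$percent, digits))
  invisible(x)
}

#' Explicitly renormalize a weight set to sum to 100
#'
#' @param w a [conformer_weights()] object.
#' @param provenance provenance of the result; defaults to the input's.
#' @return A [conformer_weights()] object summing to 100.
#' @export
normalize_weights <- function(w, provenance = w$provenance) {
  total <- sum(w$percent)
  if (total <= 0) stop("cannot normalize: total weight is zero")
  conformer_weights(100 * w$percent / total, provenance = provenance)
}

#' Write / read weights JSON (id -> percent plus provenance)
#'
#' @param w a [conformer_weights()] object.
#' @param path output path.
#' @return `path` (write) or a [conformer_weights()] object (read).
#' @export
write_weights_json <- function(w, path) {
  jsonlite::write_json(
    list(provenance = w$provenance, percent = as.list(w$percent)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_weights_json
#' @export
read_weights_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  conformer_weights(unlist(obj$percent), provenance = obj$provenance)
}

#' Published empirical conformer weight sets
#'
#' Returns, exactly as printed in the source analysis, the empirical
#' per-conformer percentage weights for phenyl beta-D-glucopyranoside
#' (`"phb_glu"`) and gastrodin in DMSO and in water, or the gastrodin
#' core-group percentages (`set = "core"`, keyed by the 3-part
#' ph-beta-glu core name). Provenance is `"stated"`, and totals are not
#' adjusted: the gastrodin DMSO per-conformer list sums to 105 and the
#' gastrodin water per-conformer list covers only the conformers whose
#' weights were adjusted (sum 83); use [normalize_weights()] if a
#' normalized set is needed.
#'
#' @param molecule `"phb_glu"` or `"gastrodin"`.
#' @param solvent `"dmso"` or `"water"`.
#' @param set `"conformer"` for per-conformer weights, `"core"` for the
#'   gastrodin ph-beta-glu core-group percentages.
#' @return A [conformer_weights()] object with provenance `"stated"`.
#' @export
stated_weights <- function(molecule = c("phb_glu", "gastrodin"),
                           solvent = c("dmso", "water"),
                           set = c("conformer", "core")) {
  molecule <- match.arg(molecule)
  solvent <- match.arg(solvent)
  set <- match.arg(set)
  if (set == "core" && molecule != "gastrodin")
    stop("core-group weight sets are defined for gastrodin only")
  key <- paste(molecule, solvent, set, sep = ".")
  w <- switch(key,
    "phb_glu.dmso.conformer" = c(
      "G-g+/cc/T" = 60, "G+g-/cc/T" = 10, "Tg+/cc/T" = 10, "G-g-/cc/T" = 10,
      "G-g+/c/T" = 2.5, "G+t/cc/T" = 2.5, "G-t/cc/T" = 2.5, "G+g+/cc/T" = 2.5),
    "phb_glu.water.conformer" = c(
      "G-g+/cc/T" = 20, "G+g-/cc/T" = 30, "Tg+/cc/T" = 5, "G-g-/cc/T" = 10,
      "G-g+/c/T" = 5, "G+t/cc/T" = 5, "G-t/cc/T" = 5, "G+g+/cc/T" = 5,
      "G+g-/c/T" = 3, "Tt/c/T" = 1, "Tg-/c/T" = 1, "G+g-/cc/G-" = 10),
    "gastrodin.dmso.conformer" = c(
      "G-g+/cc/T/G+g-" = 14,
      "G+g-/cc/T/G-g-" = 6, "G+g-/cc/T/G+g+" = 6, "G+g-/cc/T/G-g+" = 6,
      "G-g+/cc/T/G-g-" = 8, "G+g-/cc/T/G+g-'" = 8, "G-g+/cc/T/G+g+" = 8,
      "G-g+/cc/T/G-g+" = 8, "G+g+/cc/T/G+g-" = 8, "G+g-/cc/T/G+g-''" = 8,
      "Tg+/cc/T/G+g+" = 2, "G+g+/cc/T/G-g+" = 2, "Tg+/cc/T/G-g-" = 2,
      "Tg+/cc/T/G-g+" = 2, "Tg+/cc/T/G+g-" = 2,
      "Tt/c/T/G+g-" = 15),
    "gastrodin.water.conformer" = c(
      "G-g+/cc/T/G+g-" = 10, "G+g-/cc/T/G-g-" = 10, "G+g-/cc/T/G+g+" = 8,
      "G+g-/cc/T/G-g+" = 10, "G-g+/cc/T/G-g-" = 12, "G+g-/cc/T/G+g-" = 4,
      "G-g+/cc/T/G+g+" = 12, "G-g+/cc/T/G-g+" = 10, "G+g+/cc/T/G+g-" = 7),
    "gastrodin.dmso.core" = c(
      "G+g-/cc/T" = 47, "G-g+/cc/T" = 22, "G+g+/cc/T" = 9,
      "Tg+/cc/T" = 8, "Tt/c/T" = 14),
    "gastrodin.water.core" = c(
      "G+g-/cc/T" = 61, "G-g+/cc/T" = 21, "G+g+/cc/T" = 9,
      "Tg+/cc/T" = 8, "Tt/c/T" = 0.3),
    stop("no stated weight set for ", key))
  conformer_weights(w, provenance = "stated")
}
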
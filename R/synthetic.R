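#' Synthetic conformer ensembles
#'
#' Seeded generators that stand in for the quantum-chemistry stage:
#' geometries built by sequential internal-coordinate placement so that
#' every classifiable torsion realizes a prescribed rotamer label,
#' per-conformer stick spectra whose positions and signs differ enough
#' between conformers for their weights to be identifiable, and a noisy
#' composite "experimental" spectrum with known ground-truth weights.
#' Intensities and normal-mode structure are not physically realistic;
#' the generator exists so the classification, averaging and re-weighting
#' machinery can be exercised end to end.
#'
#' @name synthetic_data
NULL

.label_angle <- function(label) {
  switch(label,
         "G+" = , "g+" = 60,
         "G-" = , "g-" = -60,
         "T" = , "t" = 180,
         stop("unknown rotamer label '", label, "'"))
}

#' Build a geometry realizing prescribed torsion labels
#'
#' Places a minimal glycoside-like scaffold atom by atom (default bond
#' length 1.4 Angstrom, tetrahedral angles on the sugar, trigonal on the
#' phenyl ring) such that each classifiable dihedral equals its label's
#' canonical angle plus an optional uniform jitter, and positions the
#' ring-hydroxyl hydrogens along the O...O axes so the requested `cc`/`c`
#' contact chain is realized under the package's network convention. The
#' geometry is a synthetic test scaffold, not an optimized structure.
#'
#' @param labels list with elements `ring_upper`, `ring_lower` (`G+`/`G-`/
#'   `T` and `g+`/`g-`/`t`), `network` (`"cc"` or `"c"`), `phenyl`
#'   (upper-case label), and for the gastrodin scaffold `ph_upper`,
#'   `ph_lower`.
#' @param scaffold `"phb_glu"` or `"gastrodin"`.
#' @param seed integer seed for the jitter draw (mandatory).
#' @param jitter half-width of the uniform torsion jitter in degrees;
#'   bounded at 15 so labels stay unambiguous (canonical angles are 120
#'   degrees apart).
#' @param conformer_id id for the resulting geometry; defaults to the
#'   systematic name implied by `labels`.
#' @return List with elements `geometry` (a [geometry()]) and `atom_map`
#'   (the matching [atom_map()]).
#' @export
make_conformer_geometry <- function(labels,
                                    scaffold = c("phb_glu", "gastrodin"),
                                    seed, jitter = 0,
                                    conformer_id = NULL) {
  scaffold <- match.arg(scaffold)
  if (missing(seed)) stop("a seed is mandatory")
  if (jitter < 0 || jitter > 15)
    stop("jitter must be in [0, 15] degrees to keep labels unambiguous")
  need <- c("ring_upper", "ring_lower", "network", "phenyl")
  if (scaffold == "gastrodin") need <- c(need, "ph_upper", "ph_lower")
  missing_l <- setdiff(need, names(labels))
  if (length(missing_l))
    stop("labels missing: ", paste(missing_l, collapse = ", "))
  if (!labels$network %in% c("cc", "c"))
    stop("network label must be 'cc' or 'c'")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  jit <- function() if (jitter > 0) stats::runif(1, -jitter, jitter) else 0

  tor <- list(
    ring_upper = .label_angle(labels$ring_upper) + jit(),
    ring_lower = .label_angle(labels$ring_lower) + jit(),
    phenyl = .label_angle(labels$phenyl) + jit())
  if (scaffold == "gastrodin") {
    tor$ph_upper <- .label_angle(labels$ph_upper) + jit()
    tor$ph_lower <- .label_angle(labels$ph_lower) + jit()
  }

  b <- 1.4      # generic heavy-atom bond, Angstrom
  boh <- 0.96   # O-H bond
  tet <- 109.5
  tri <- 120

  atoms <- character(0)
  coords <- NULL
  idx <- list()
  add <- function(el, label, pos) {
    atoms <<- c(atoms, el)
    coords <<- rbind(coords, pos)
    idx[[label]] <<- length(atoms)
  }
  pos <- function(label) coords[idx[[label]], ]
  place <- function(a, bb, cc, bond, ang, torsion)
    place_atom(pos(a), pos(bb), pos(cc), bond, ang, torsion)

  ## sugar-ring fragment: O5 -> C5 -> C6 arm plus ring carbons C1..C4
  add("O", "O5", c(0, 0, 0))
  add("C", "C5", c(b, 0, 0))
  add("C", "C6", c(b + b * cos(pi * (180 - tet) / 180),
                   b * sin(pi * (180 - tet) / 180), 0))
  add("O", "O6", place("O5", "C5", "C6", b, tet, tor$ring_upper))
  add("H", "H6", place("C5", "C6", "O6", boh, tet, tor$ring_lower))
  add("C", "C1", place("C6", "C5", "O5", b, tet, -55))
  add("O", "O1", place("C5", "O5", "C1", b, tet, 170))
  add("C", "C2", place("O1", "O5", "C1", b, tet, -125))
  add("C", "C3", place("O5", "C1", "C2", b, tet, 55))
  add("C", "C4", place("C1", "C2", "C3", b, tet, -55))
  ## equatorial-like ring hydroxyl oxygens
  add("O", "O2", place("O5", "C1", "C2", b, tet, 180))
  add("O", "O3", place("C1", "C2", "C3", b, tet, -178))
  add("O", "O4", place("C2", "C3", "C4", b, tet, 178))
  ## phenyl ring off O1; C2-C1-O1-C7 is the classified phenyl torsion
  add("C", "C7", place("C2", "C1", "O1", b, tri, tor$phenyl))
  add("C", "C12", place("C1", "O1", "C7", b, tri, 15))   # tilt, reported only
  add("C", "C8", place("C1", "O1", "C7", b, tri, 15 - 180))
  add("C", "C9", place("O1", "C7", "C8", b, tri, 180))
  add("C", "C10", place("C7", "C8", "C9", b, tri, 0))
  add("C", "C11", place("C8", "C9", "C10", b, tri, 0))
  if (scaffold == "gastrodin") {
    add("C", "C13", place("C9", "C10", "C11", b, tri, 180))
    add("O", "O7", place("C11", "C10", "C13", b, tet, tor$ph_upper))
    add("H", "H7", place("C10", "C13", "O7", boh, tet, tor$ph_lower))
  }

  ## ring-hydroxyl hydrogens: point each chain donor straight at its
  ## acceptor oxygen so the H...O distance is d(O,O) - 0.96
  aim <- function(o_lab, acc_lab) {
    o <- pos(o_lab); a <- pos(acc_lab)
    o + boh * .unit(a - o)
  }
  away <- function(o_lab, acc_lab) {
    o <- pos(o_lab); a <- pos(acc_lab)
    o - boh * .unit(a - o)
  }
  ## fixed atom order regardless of chain direction, so one atom map
  ## serves every conformer of an ensemble
  if (labels$network == "cc") {
    add("H", "H2", aim("O2", "O3"))
    add("H", "H3", aim("O3", "O4"))
    add("H", "H4", away("O4", "O3"))
  } else {
    add("H", "H2", away("O2", "O3"))
    add("H", "H3", aim("O3", "O2"))
    add("H", "H4", aim("O4", "O3"))
  }

  core <- c(.scaffold_core,
            if (scaffold == "gastrodin") .scaffold_gastrodin)
  map <- atom_map(
    indices = stats::setNames(lapply(core, function(l) idx[[l]]), core),
    hydroxyls = list(C2 = c(idx$O2, idx$H2),
                     C3 = c(idx$O3, idx$H3),
                     C4 = c(idx$O4, idx$H4)),
    molecule_class = scaffold)
  if (is.null(conformer_id)) {
    parts <- c(paste0(labels$ring_upper, labels$ring_lower),
               labels$network, labels$phenyl)
    if (scaffold == "gastrodin")
      parts <- c(parts, paste0(labels$ph_upper, labels$ph_lower))
    conformer_id <- paste(parts, collapse = "/")
  }
  list(geometry = geometry(atoms, coords, conformer_id), atom_map = map)
}

## save/restore the RNG state so generators do not disturb the caller's
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Specify a synthetic ensemble
#'
#' @param conformer_ids character vector of conformer ids (systematic
#'   names when geometries are also generated).
#' @param truth_weights ground-truth percentages, summing to 100.
#' @param modalities modalities to generate.
#' @param n_lines lines per conformer per modality.
#' @param wavenumber_range length-2 range for line positions; defaults to
#'   the modality's [default_grid()] range (shrunk 5% at each edge so
#'   bands stay on-grid after broadening).
#' @param sign_prob probability that a chiral line is positive.
#' @param noise noise level as a fraction of max |signal| of the
#'   composite spectrum.
#' @param seed integer seed (mandatory); split internally so line
#'   generation and noise use independent streams.
#' @return An object of class `synthetic_ensemble_spec`.
#' @export
synthetic_ensemble_spec <- function(conformer_ids, truth_weights,
                                    modalities = c("IR", "VCD"),
                                    n_lines = 12,
                                    wavenumber_range = NULL,
                                    sign_prob = 0.5,
                                    noise = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (length(conformer_ids) != length(truth_weights))
    stop("one truth weight per conformer is required")
  if (any(truth_weights < 0) || abs(sum(truth_weights) - 100) > 1e-9)
    stop("truth weights must be >= 0 and sum to 100")
  modalities <- match.arg(modalities, .modalities, several.ok = TRUE)
  structure(
    list(conformer_ids = as.character(conformer_ids),
         truth_weights = stats::setNames(truth_weights, conformer_ids),
         modalities = modalities, n_lines = n_lines,
         wavenumber_range = wavenumber_range,
         sign_prob = sign_prob, noise = noise, seed = as.integer(seed)),
    class = "synthetic_ensemble_spec")
}

#' Generate per-conformer stick spectra for a synthetic ensemble
#'
#' Line positions are drawn uniformly over the modality's range,
#' intensities uniformly in (0.2, 1], and chiral (VCD/ROA) lines are
#' signed with probability `sign_prob` of being positive. Draws are fully
#' determined by the spec's seed; conformers get independent positions so
#' their spectra are distinguishable and the mixing weights identifiable.
#'
#' @param spec a [synthetic_ensemble_spec()].
#' @return Nested list `sticks[[modality]][[conformer_id]]` of
#'   [stick_spectrum()] objects.
#' @export
make_ensemble_sticks <- function(spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  out <- list()
  for (mod in spec$modalities) {
    rng <- spec$wavenumber_range
    if (is.null(rng)) {
      g <- range(default_grid(mod))
      span <- diff(g)
      rng <- c(g[1] + 0.05 * span, g[2] - 0.05 * span)
    }
    out[[mod]] <- stats::setNames(lapply(spec$conformer_ids, function(id) {
      if (spec$n_lines == 0)
        return(stick_spectrum(numeric(0), numeric(0), mod, id))
      nu <- sort(stats::runif(spec$n_lines, rng[1], rng[2]))
      inten <- stats::runif(spec$n_lines, 0.2, 1)
      if (is_signed_modality(mod))
        inten <- inten * ifelse(stats::runif(spec$n_lines) < spec$sign_prob,
                                1, -1)
      stick_spectrum(nu, inten, mod, id)
    }), spec$conformer_ids)
  }
  out
}

#' Compose a noisy synthetic "experimental" spectrum
#'
#' Broadens each conformer's stick spectrum, averages with the
#' ground-truth weights, and adds seeded Gaussian noise with standard
#' deviation `noise * max(abs(signal))`. With `noise = 0` the result is
#' exactly the truth-weighted ensemble average.
#'
#' @param sticks named list (conformer id -> [stick_spectrum()]) for one
#'   modality.
#' @param truth_weights named percentages summing to 100.
#' @param gamma Lorentzian HWHH, cm^-1.
#' @param noise noise fraction of max |signal|.
#' @param seed integer seed for the noise draw (mandatory when
#'   `noise > 0`).
#' @param grid wavenumber grid; defaults to the modality's
#'   [default_grid()].
#' @return A [grid_spectrum()]; metadata records the truth weights, gamma,
#'   noise level and seed.
#' @export
make_experimental_spectrum <- function(sticks, truth_weights, gamma = 4,
                                       noise = 0, seed = NULL, grid = NULL) {
  if (noise > 0 && is.null(seed))
    stop("a seed is mandatory when noise > 0")
  w <- conformer_weights(truth_weights, provenance = "stated")
  if (is.null(grid)) grid <- default_grid(sticks[[1]]$modality)
  broadened <- lapply(sticks, lorentzian_broaden, grid = grid, gamma = gamma)
  avg <- ensemble_average(broadened, w)
  vals <- avg$values
  if (noise > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    vals <- vals + stats::rnorm(length(vals),
                                sd = noise * max(abs(vals)))
  }
  grid_spectrum(grid, vals, avg$modality,
                metadata = list(truth_weights = truth_weights, gamma = gamma,
                                noise = noise, seed = seed))
}
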
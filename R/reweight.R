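#' Spectral similarity and weight refinement
#'
#' Agreement between a simulated and an experimental trace is quantified
#' by the normalized overlap integral
#' `S = int(f*g) / sqrt(int(f^2) * int(g^2))`
#' over the shared wavenumber range. Signed (VCD/ROA) spectra are compared
#' as-is, so `S` ranges over `[-1, 1]` and `S = 1` only when the traces
#' are positive multiples of each other; unsigned (IR/Raman) spectra are
#' first aligned to a common zero baseline by subtracting each trace's
#' minimum, giving `S` in `[0, 1]`.
#'
#' @name reweight
NULL

.trapz <- function(x, y) pracma::trapz(x, y)

#' Normalized overlap similarity between two spectra
#'
#' @param sim,exp [grid_spectrum()] objects of the same modality. If their
#'   grids differ, both are linearly resampled onto the overlap of the two
#'   ranges, which must span at least `min_overlap` cm^-1.
#' @param min_overlap minimum shared range, cm^-1.
#' @return An object of class `similarity_score` with fields `value`,
#'   `modality`, and the overlap integrals used.
#' @export
similarity <- function(sim, exp, min_overlap = 100) {
  if (sim$modality != exp$modality)
    stop("cannot compare spectra of different modalities")
  lo <- max(min(sim$grid), min(exp$grid))
  hi <- min(max(sim$grid), max(exp$grid))
  if (hi - lo < min_overlap)
    stop(sprintf("shared wavenumber range (%.1f cm^-1) is below %g cm^-1",
                 hi - lo, min_overlap))
  same_grid <- length(sim$grid) == length(exp$grid) &&
    max(abs(sim$grid - exp$grid)) < 1e-9
  if (same_grid) {
    x <- sim$grid; f <- sim$values; g <- exp$values
  } else {
    step <- min(mean(diff(sim$grid)), mean(diff(exp$grid)))
    x <- seq(lo, hi, by = step)
    f <- stats::approx(sim$grid, sim$values, x)$y
    g <- stats::approx(exp$grid, exp$values, x)$y
  }
  if (!is_signed_modality(sim$modality)) {
    f <- f - min(f)
    g <- g - min(g)
  }
  ff <- .trapz(x, f * f)
  gg <- .trapz(x, g * g)
  if (ff <= 0 || gg <= 0)
    stop("similarity undefined: zero-norm spectrum on the compared range")
  fg <- .trapz(x, f * g)
  structure(list(value = fg / sqrt(ff * gg), modality = sim$modality,
                 integrals = c(fg = fg, ff = ff, gg = gg)),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("<similarity %s: %.6f>\n", x$modality, x$value))
  invisible(x)
}

## similarity of a weighted combination M %*% (w/100) against a fixed
## experimental trace; precomputed pieces keep the optimizer loop cheap
.make_overlap_fn <- function(spectra, expspec) {
  ids <- names(spectra)
  g0 <- spectra[[1]]
  signed <- is_signed_modality(g0$modality)
  same_grid <- length(g0$grid) == length(expspec$grid) &&
    max(abs(g0$grid - expspec$grid)) < 1e-9
  if (same_grid) {
    x <- g0$grid
    M <- vapply(spectra, function(s) s$values, numeric(length(g0$grid)))
    gexp <- expspec$values
  } else {
    lo <- max(min(g0$grid), min(expspec$grid))
    hi <- min(max(g0$grid), max(expspec$grid))
    step <- min(mean(diff(g0$grid)), mean(diff(expspec$grid)))
    x <- seq(lo, hi, by = step)
    M <- vapply(spectra,
                function(s) stats::approx(s$grid, s$values, x)$y,
                numeric(length(x)))
    gexp <- stats::approx(expspec$grid, expspec$values, x)$y
  }
  if (!signed) gexp <- gexp - min(gexp)
  gg <- .trapz(x, gexp * gexp)
  if (gg <= 0) stop("similarity undefined: zero-norm experimental spectrum")
  function(frac) {
    f <- as.numeric(M %*% frac)
    if (!signed) f <- f - min(f)
    ff <- .trapz(x, f * f)
    if (ff <= 0) return(NA_real_)
    .trapz(x, f * gexp) / sqrt(ff * gg)
  }
}

#' Refine conformer weights against experimental spectra
#'
#' Formalizes the empirical re-weighting of conformer populations as a
#' simplex-constrained optimization. Minimizes
#' `J(w) = alpha*(1 - S_chiral(w)) + (1-alpha)*(1 - S_parent(w))
#'        + lambda * sum_i (w_i - w_i^Boltzmann)^2 / 100^2`
#' over `{w >= 0, sum(w) = 100}`, where `S_chiral` is the overlap
#' similarity of the weighted VCD (or ROA) average with experiment and
#' `S_parent` the same for IR (or Raman). The chiral modality dominates by
#' default (`alpha = 0.7`) because VCD/ROA features discriminate between
#' conformers far more strongly than the parent IR/Raman. The quadratic
#' Boltzmann prior (`lambda`, default 0.1) keeps the solution anchored to
#' the predicted stability trend; `lambda = 0` fits the spectra alone and
#' very large `lambda` returns the Boltzmann weights.
#'
#' Optimization is deterministic: the simplex is parameterized by softmax
#' and minimized by BFGS from the Boltzmann starting point, optionally
#' followed by multi-starts from each simplex vertex; the best iterate is
#' returned and is never worse than the starting point.
#'
#' @param conformer_spectra list with elements `chiral` and/or `parent`,
#'   each a named list (conformer id -> [grid_spectrum()]) on a shared
#'   grid.
#' @param experimental list with matching elements `chiral` and/or
#'   `parent`, each a [grid_spectrum()].
#' @param boltzmann a [conformer_weights()] object covering all conformers (the
#'   starting point and prior center).
#' @param alpha chiral-vs-parent mixing in `[0, 1]`.
#' @param lambda Boltzmann prior strength (>= 0).
#' @param multistart also start from each simplex vertex.
#' @param maxit iteration cap per start.
#' @return An object of class `refinement_result`: `weights` (provenance
#'   `"refined"`), `objective`, `similarity_before`/`similarity_after`
#'   (per modality), `alpha`, `lambda`, `converged`, `n_starts`.
#' @export
refine_weights <- function(conformer_spectra, experimental, boltzmann,
                           alpha = 0.7, lambda = 0.1,
                           multistart = FALSE, maxit = 500) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (lambda < 0) stop("lambda must be >= 0")
  roles <- intersect(c("chiral", "parent"), names(conformer_spectra))
  roles <- roles[vapply(roles, function(r) !is.null(experimental[[r]]), TRUE)]
  if (!length(roles))
    stop("need conformer and experimental spectra for at least one modality")
  ids <- names(conformer_spectra[[roles[1]]])
  if (length(ids) < 2L) stop("need >= 2 conformers to refine")
  for (r in roles) {
    if (!identical(sort(names(conformer_spectra[[r]])), sort(ids)))
      stop("conformer ids differ between modalities")
    conformer_spectra[[r]] <- conformer_spectra[[r]][ids]
  }
  missing <- setdiff(ids, names(boltzmann$percent))
  if (length(missing))
    stop("Boltzmann weights missing for: ", paste(missing, collapse = ", "))
  wB <- boltzmann$percent[ids]

  overlap <- lapply(roles, function(r)
    .make_overlap_fn(conformer_spectra[[r]], experimental[[r]]))
  names(overlap) <- roles
  mix <- c(chiral = alpha, parent = 1 - alpha)[roles]
  if (sum(mix) <= 0) mix[] <- 1 / length(mix)
  mix <- mix / sum(mix)

  objective <- function(frac) {
    s <- vapply(roles, function(r) overlap[[r]](frac), 0)
    if (anyNA(s)) return(1e6)
    sum(mix * (1 - s)) + lambda * sum((100 * frac - wB)^2) / 100^2
  }
  obj_z <- function(z) {
    e <- exp(z - max(z))
    objective(e / sum(e))
  }

  starts <- list(log(pmax(wB / 100, 1e-8)))
  if (multistart)
    for (k in seq_along(ids)) {
      z <- rep(-6, length(ids)); z[k] <- 6
      starts[[length(starts) + 1L]] <- z
    }
  best <- NULL
  converged <- FALSE
  for (z0 in starts) {
    fit <- stats::optim(z0, obj_z, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      converged <- fit$convergence == 0L
    }
  }
  frac0 <- wB / 100
  obj0 <- objective(frac0)
  e <- exp(best$par - max(best$par))
  frac <- e / sum(e)
  obj <- objective(frac)
  if (obj > obj0) {  # never return anything worse than the starting point
    frac <- frac0
    obj <- obj0
    converged <- TRUE
  }
  s_before <- vapply(roles, function(r) overlap[[r]](frac0), 0)
  s_after <- vapply(roles, function(r) overlap[[r]](frac), 0)
  structure(
    list(weights = conformer_weights(stats::setNames(100 * frac, ids),
                           provenance = "refined"),
         objective = obj, objective_start = obj0,
         similarity_before = s_before, similarity_after = s_after,
         alpha = alpha, lambda = lambda,
         converged = converged, n_starts = length(starts)),
    class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("<refinement_result: objective %.6g (start %.6g), %s>\n",
              x$objective, x$objective_start,
              if (x$converged) "converged" else "NOT converged"))
  for (r in names(x$similarity_after))
    cat(sprintf("  %s similarity %.4f -> %.4f\n",
                r, x$similarity_before[[r]], x$similarity_after[[r]]))
  print(x$weights)
  invisible(x)
}

.first_upper_label <- function(part1) {
  m <- regmatches(part1, regexec("^(G\\+|G-|T)", part1))[[1]]
  if (length(m) < 2L) return(NA_character_)
  m[2]
}

#' Group conformer weights into conformational abundances
#'
#' Sums percentage weights by a grouping key extracted from each
#' systematic conformer name:
#' * `"pyranose-hydroxymethyl"`: the upper-case rotamer label (`G+`, `G-`
#'   or `T`) of the ring hydroxymethyl group, i.e. of the first name part
#'   — the G+:G-:T distribution;
#' * `"phb-glu-core"`: the first three name parts (the ph-beta-glu core of
#'   a gastrodin conformer), e.g. `"G+g-/cc/T"`.
#'
#' All groups implied by the key are reported even when zero (for the
#' hydroxymethyl key: G+, G-, T). The group total equals the input weight
#' total exactly; stated weight sets that do not sum to 100 are not
#' renormalized here.
#'
#' @param w a [conformer_weights()] object keyed by systematic conformer names, or
#'   accompanied by `names` giving the name for each conformer id.
#' @param key `"pyranose-hydroxymethyl"` or `"phb-glu-core"`.
#' @param names optional character vector mapping `names(w$percent)` to
#'   systematic names when the weight keys are not themselves names.
#' @return An object of class `distribution_report`: a data frame with
#'   columns `group`, `percent`; attributes `key` and `provenance`.
#' @export
group_abundances <- function(w, key = c("pyranose-hydroxymethyl",
                                        "phb-glu-core"),
                             names = NULL) {
  key <- match.arg(key)
  nm <- if (is.null(names)) base::names(w$percent) else as.character(names)
  if (length(nm) != length(w$percent))
    stop("`names` must provide one systematic name per conformer")
  parts <- strsplit(nm, "/", fixed = TRUE)
  keys <- vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (key == "pyranose-hydroxymethyl") {
      k <- .first_upper_label(p[1])
      if (is.na(k) || length(p) < 3L) NA_character_ else k
    } else {
      if (length(p) < 3L) NA_character_
      else paste(p[1:3], collapse = "/")
    }
  }, "")
  bad <- which(is.na(keys))
  if (length(bad))
    stop("unparseable conformer name(s): ",
         paste(unique(nm[bad]), collapse = ", "))
  agg <- tapply(w$percent, keys, sum)
  if (key == "pyranose-hydroxymethyl") {
    full <- stats::setNames(numeric(3), c("G+", "G-", "T"))
    full[base::names(agg)] <- agg
    agg <- full
  }
  structure(
    data.frame(group = base::names(agg), percent = as.numeric(agg),
               row.names = NULL, stringsAsFactors = FALSE),
    key = key, provenance = w$provenance,
    class = c("distribution_report", "data.frame"))
}

#' Roll core-group percentages up to the hydroxymethyl distribution
#'
#' Takes percentages keyed by 3-part ph-beta-glu core names (e.g.
#' `"G+g-/cc/T"`) and sums them by the upper-case ring-hydroxymethyl
#' label, yielding the G+:G-:T distribution. Values are reported at full
#' precision; no rounding is applied.
#'
#' @param core_groups named numeric vector or a `distribution_report`
#'   keyed by core names, or a `"stated"` [conformer_weights()] object.
#' @return A `distribution_report` with groups G+, G-, T.
#' @export
core_group_rollup <- function(core_groups) {
  if (inherits(core_groups, "conformer_weights")) {
    prov <- core_groups$provenance
    v <- core_groups$percent
  } else if (inherits(core_groups, "distribution_report")) {
    prov <- attr(core_groups, "provenance") %||% "stated"
    v <- stats::setNames(core_groups$percent, core_groups$group)
  } else {
    prov <- "stated"
    v <- core_groups
  }
  w <- conformer_weights(v, provenance = "stated")
  rep <- group_abundances(w, key = "pyranose-hydroxymethyl")
  attr(rep, "provenance") <- prov
  rep
}

#' @export
print.distribution_report <- function(x, digits = 1, ...) {
  cat(sprintf("<distribution_report: key '%s', provenance %s>\n",
              attr(x, "key"), attr(x, "provenance")))
  df <- as.data.frame(x)
  df$percent <- round(df$percent, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
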
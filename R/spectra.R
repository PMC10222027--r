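#' Stick and grid spectra
#'
#' A `stick_spectrum` is a line list (wavenumber, intensity) for one
#' conformer and one modality; IR and Raman intensities are non-negative,
#' VCD and ROA intensities are signed. A `grid_spectrum` is the broadened
#' continuous trace on a uniform wavenumber grid. Intensities are
#' arbitrary units end to end.
#'
#' @name spectra
NULL

.modalities <- c("IR", "VCD", "Raman", "ROA")
.signed_modalities <- c("VCD", "ROA")

#' Is a modality signed (chiral)?
#'
#' @param modality one of `"IR"`, `"VCD"`, `"Raman"`, `"ROA"`.
#' @return `TRUE` for VCD and ROA.
#' @export
is_signed_modality <- function(modality) modality %in% .signed_modalities

#' Construct a stick spectrum
#'
#' @param wavenumber line positions, cm^-1, all positive and finite.
#' @param intensity line intensities (arbitrary units); must be >= 0 for
#'   IR/Raman, may be signed for VCD/ROA.
#' @param modality one of `"IR"`, `"VCD"`, `"Raman"`, `"ROA"`.
#' @param conformer_id identifier string.
#' @return An object of class `stick_spectrum`.
#' @export
stick_spectrum <- function(wavenumber, intensity, modality,
                           conformer_id = "conf") {
  modality <- match.arg(modality, .modalities)
  if (length(wavenumber) != length(intensity))
    stop("wavenumber and intensity must have the same length")
  if (length(wavenumber) &&
      (!all(is.finite(wavenumber)) || any(wavenumber <= 0)))
    stop("wavenumbers must be positive and finite")
  if (length(intensity) && !all(is.finite(intensity)))
    stop("intensities must be finite")
  if (!is_signed_modality(modality) && any(intensity < 0))
    stop(modality, " intensities must be non-negative")
  structure(
    list(conformer_id = as.character(conformer_id), modality = modality,
         lines = data.frame(wavenumber = as.numeric(wavenumber),
                            intensity = as.numeric(intensity))),
    class = "stick_spectrum")
}

#' @export
print.stick_spectrum <- function(x, ...) {
  cat(sprintf("<stick_spectrum '%s' %s: %d lines>\n",
              x$conformer_id, x$modality, nrow(x$lines)))
  invisible(x)
}

#' Construct a grid spectrum
#'
#' @param grid strictly increasing, uniformly spaced wavenumbers, cm^-1.
#' @param values signal at each grid point.
#' @param modality one of `"IR"`, `"VCD"`, `"Raman"`, `"ROA"`.
#' @param metadata free-form list (broadening gamma, scale coefficients,
#'   weights used, provenance, ...).
#' @return An object of class `grid_spectrum`.
#' @export
grid_spectrum <- function(grid, values, modality, metadata = list()) {
  modality <- match.arg(modality, .modalities)
  if (length(grid) != length(values))
    stop("grid and values must have the same length")
  if (length(grid) >= 2L) {
    dg <- diff(grid)
    if (any(dg <= 0)) stop("grid must be strictly increasing")
    if (diff(range(dg)) > 1e-8 * mean(dg))
      stop("grid must be uniformly spaced")
  }
  structure(list(grid = as.numeric(grid), values = as.numeric(values),
                 modality = modality, metadata = metadata),
            class = "grid_spectrum")
}

#' @export
print.grid_spectrum <- function(x, ...) {
  cat(sprintf("<grid_spectrum %s: %d points, %.6g..%.6g cm^-1>\n",
              x$modality, length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Default wavenumber grid for a modality
#'
#' IR and VCD default to the 1000-1700 cm^-1 fingerprint window typical of
#' solution FTIR/VCD work on carbohydrates; Raman and ROA to the
#' 200-2000 cm^-1 range of a typical ROA acquisition. Step 1 cm^-1.
#'
#' @param modality one of `"IR"`, `"VCD"`, `"Raman"`, `"ROA"`.
#' @param step grid step, cm^-1.
#' @return Numeric grid vector.
#' @export
default_grid <- function(modality, step = 1) {
  modality <- match.arg(modality, .modalities)
  if (modality %in% c("IR", "VCD")) seq(1000, 1700, by = step)
  else seq(200, 2000, by = step)
}

#' Lorentzian band broadening of a stick spectrum
#'
#' Convolves the line list with an area-normalized Lorentzian,
#' `S(v) = sum_k I_k * (gamma/pi) / ((v - v_k)^2 + gamma^2)`,
#' so each line contributes total integrated area `I_k` and the peak
#' height of an isolated unit line is `1/(pi*gamma)`. `gamma` is the
#' half-width at half-height (HWHH), 4 cm^-1 by default. An empty line
#' list yields a zero spectrum.
#'
#' @param stick a [stick_spectrum()].
#' @param grid wavenumber grid; defaults to [default_grid()] for the
#'   stick's modality.
#' @param gamma HWHH in cm^-1 (> 0).
#' @return A [grid_spectrum()] whose metadata records `gamma`.
#' @export
lorentzian_broaden <- function(stick, grid = NULL, gamma = 4) {
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be positive")
  if (is.null(grid)) grid <- default_grid(stick$modality)
  vals <- numeric(length(grid))
  if (nrow(stick$lines)) {
    ## grid-point x line matrix of Lorentzian kernels
    dv <- outer(grid, stick$lines$wavenumber, "-")
    kern <- (gamma / pi) / (dv^2 + gamma^2)
    vals <- as.numeric(kern %*% stick$lines$intensity)
  }
  grid_spectrum(grid, vals, stick$modality,
                metadata = list(gamma = gamma,
                                conformer_id = stick$conformer_id))
}

#' Fit a linear wavenumber scale model
#'
#' Ordinary least squares of experimental on calculated band positions:
#' `v_exp ~ a * v_calc + b`. Used to correct the systematic overestimation
#' of harmonic frequencies before comparing simulation with experiment. A
#' uniform scale factor can be supplied directly via [scale_model()].
#'
#' @param nu_calc,nu_exp matched band positions, cm^-1 (>= 2 pairs with
#'   distinct `nu_calc`).
#' @return An object of class `scale_model` with fields `a` (slope, > 0),
#'   `b` (intercept, cm^-1), `pairs`, `residuals`.
#' @export
fit_linear_scale <- function(nu_calc, nu_exp) {
  if (length(nu_calc) != length(nu_exp))
    stop("nu_calc and nu_exp must have the same length")
  if (length(nu_calc) < 2L || length(unique(nu_calc)) < 2L)
    stop("need >= 2 pairs with distinct calculated wavenumbers")
  fit <- stats::lm(nu_exp ~ nu_calc)
  a <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  scale_model(a, b, pairs = data.frame(nu_calc = nu_calc, nu_exp = nu_exp),
              residuals = unname(stats::residuals(fit)))
}

#' @rdname fit_linear_scale
#' @param a slope (dimensionless, > 0); a uniform scale factor when `b = 0`.
#' @param b intercept, cm^-1.
#' @param pairs,residuals fitted pairs and residuals, if any.
#' @export
scale_model <- function(a, b = 0, pairs = NULL, residuals = NULL) {
  if (!is.finite(a) || a <= 0) stop("scale slope must be positive")
  structure(list(a = a, b = b, pairs = pairs, residuals = residuals),
            class = "scale_model")
}

#' @export
print.scale_model <- function(x, ...) {
  cat(sprintf("<scale_model: v_exp = %.6g * v_calc + %.6g cm^-1>\n", x$a, x$b))
  invisible(x)
}

#' Apply a linear frequency scale to a stick spectrum
#'
#' Maps each line `v_k -> a*v_k + b`; intensities are unchanged. Because
#' `a > 0` the line ordering is preserved.
#'
#' @param stick a [stick_spectrum()].
#' @param model a [scale_model()].
#' @return The scaled [stick_spectrum()].
#' @export
apply_scale <- function(stick, model) {
  nu <- model$a * stick$lines$wavenumber + model$b
  bad <- which(nu <= 0)
  if (length(bad))
    stop(sprintf("scaling drives line %d (%.6g cm^-1) to %.6g cm^-1 <= 0",
                 bad[1], stick$lines$wavenumber[bad[1]], nu[bad[1]]))
  stick_spectrum(nu, stick$lines$intensity, stick$modality,
                 stick$conformer_id)
}

#' Population-weighted ensemble average of grid spectra
#'
#' Pointwise `sum_i (w_i / 100) * S_i(v)` over conformers sharing one grid
#' and modality. Every conformer must have a weight; weights for unknown
#' conformers are ignored with a warning.
#'
#' @param spectra named list of [grid_spectrum()] objects (names =
#'   conformer ids), all on the same grid and modality.
#' @param w a [conformer_weights()] object covering all conformer ids.
#' @return The averaged [grid_spectrum()]; metadata records the weights
#'   used and their provenance.
#' @export
ensemble_average <- function(spectra, w) {
  if (!length(spectra)) stop("no spectra to average")
  ids <- names(spectra)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("`spectra` must be a named list keyed by conformer id")
  g0 <- spectra[[1]]
  for (s in spectra) {
    if (s$modality != g0$modality) stop("spectra mix modalities")
    if (length(s$grid) != length(g0$grid) ||
        max(abs(s$grid - g0$grid)) > 1e-9)
      stop("spectra must share one grid")
  }
  missing <- setdiff(ids, names(w$percent))
  if (length(missing))
    stop("no weight for conformer(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(w$percent), ids)
  if (length(unknown))
    warning("weights given for unknown conformer(s): ",
            paste(unknown, collapse = ", "))
  vals <- numeric(length(g0$grid))
  for (id in ids)
    vals <- vals + (w$percent[[id]] / 100) * spectra[[id]]$values
  grid_spectrum(g0$grid, vals, g0$modality,
                metadata = list(weights = w$percent[ids],
                                provenance = w$provenance))
}

#' Read / write stick-spectrum CSV
#'
#' Long format with columns `conformer_id, modality, wavenumber_cm1,
#' intensity`; one file can hold all conformers and modalities.
#'
#' @param path CSV path.
#' @return `read_sticks_csv`: nested list `sticks[[modality]][[conformer_id]]`
#'   of [stick_spectrum()] objects.
#' @export
read_sticks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("conformer_id", "modality", "wavenumber_cm1", "intensity")
  if (!all(need %in% names(df)))
    stop("stick CSV must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (mod in unique(df$modality)) {
    sub <- df[df$modality == mod, ]
    out[[mod]] <- lapply(split(sub, sub$conformer_id), function(s)
      stick_spectrum(s$wavenumber_cm1, s$intensity, mod, s$conformer_id[1]))
  }
  out
}

#' @rdname read_sticks_csv
#' @param sticks nested list as returned by [read_sticks_csv()] or
#'   [make_ensemble_sticks()].
#' @export
write_sticks_csv <- function(sticks, path) {
  rows <- list()
  for (mod in names(sticks)) for (id in names(sticks[[mod]])) {
    s <- sticks[[mod]][[id]]
    if (nrow(s$lines))
      rows[[length(rows) + 1L]] <- data.frame(
        conformer_id = id, modality = mod,
        wavenumber_cm1 = s$lines$wavenumber, intensity = s$lines$intensity,
        stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(conformer_id = character(), modality = character(),
               wavenumber_cm1 = numeric(), intensity = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a two-column grid-spectrum CSV
#'
#' Columns `wavenumber_cm1, value`. Reading resamples nothing; the file's
#' grid must already be uniform.
#'
#' @param path CSV path.
#' @param modality modality of the stored trace.
#' @return `read_spectrum_csv`: a [grid_spectrum()].
#' @export
read_spectrum_csv <- function(path, modality) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wavenumber_cm1", "value")
  if (!all(need %in% names(df)))
    stop("spectrum CSV must have columns: ", paste(need, collapse = ", "))
  o <- order(df$wavenumber_cm1)
  grid_spectrum(df$wavenumber_cm1[o], df$value[o], modality)
}

#' @rdname read_spectrum_csv
#' @param spec a [grid_spectrum()].
#' @export
write_spectrum_csv <- function(spec, path) {
  utils::write.csv(
    data.frame(wavenumber_cm1 = spec$grid, value = spec$values),
    path, row.names = FALSE)
  invisible(path)
}
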
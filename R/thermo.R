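#' Boltzmann populations from relative free energies
#'
#' Relative free energies (kJ/mol, relative to the ensemble minimum) are
#' converted to percentage populations at a given temperature, and an
#' energy window can prune high-lying conformers before spectral
#' simulation.
#'
#' @name ensemble_thermo
NULL

## gas constant, kJ mol^-1 K^-1
.R_KJ <- 8.31446e-3

#' Construct an ensemble-energies table
#'
#' @param conformer_id character vector of unique conformer ids.
#' @param delta_G relative free energies, kJ/mol. Normalized so the
#'   minimum is zero.
#' @param temperature temperature in K; 298.15 (room temperature) by
#'   default.
#' @return An object of class `ensemble_energies` (a data frame with
#'   columns `conformer_id`, `delta_G` and a `temperature` attribute).
#' @export
ensemble_energies <- function(conformer_id, delta_G, temperature = 298.15) {
  if (length(conformer_id) != length(delta_G))
    stop("conformer_id and delta_G must have the same length")
  if (length(delta_G) < 1L) stop("at least one conformer is required")
  if (anyDuplicated(conformer_id)) stop("conformer ids must be unique")
  if (!all(is.finite(delta_G))) stop("delta_G must be finite")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive")
  df <- data.frame(conformer_id = as.character(conformer_id),
                   delta_G = delta_G - min(delta_G),
                   stringsAsFactors = FALSE)
  structure(df, temperature = temperature,
            class = c("ensemble_energies", "data.frame"))
}

#' Read an energies CSV (columns conformer_id, delta_G_kJmol)
#'
#' @param path CSV path.
#' @param temperature temperature in K.
#' @return An [ensemble_energies()] table.
#' @export
read_energies_csv <- function(path, temperature = 298.15) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("conformer_id", "delta_G_kJmol")
  if (!all(need %in% names(df)))
    stop("energies CSV must have columns: ", paste(need, collapse = ", "))
  ensemble_energies(df$conformer_id, df$delta_G_kJmol, temperature)
}

#' Percentage Boltzmann populations
#'
#' `w_i = 100 * exp(-dG_i / RT) / sum_j exp(-dG_j / RT)` with
#' `R = 8.31446e-3` kJ/mol/K.
#'
#' @param energies an [ensemble_energies()] table.
#' @return A [conformer_weights()] object with provenance `"boltzmann"`.
#' @export
boltzmann_percentages <- function(energies) {
  temperature <- attr(energies, "temperature")
  if (is.null(temperature)) temperature <- 298.15
  if (temperature <= 0) stop("temperature must be positive")
  x <- exp(-(energies$delta_G - min(energies$delta_G)) /
             (.R_KJ * temperature))
  w <- 100 * x / sum(x)
  conformer_weights(stats::setNames(w, energies$conformer_id), provenance = "boltzmann")
}

#' Filter conformers by a free-energy window
#'
#' Retains conformers with `delta_G <= window` (kJ/mol) and re-normalizes
#' the relative energies to the new minimum. The ensemble minimum is
#' always retained, so the result is never empty. The default window of
#' 15 kJ/mol is the conventional pruning threshold below which all
#' conformers with non-negligible room-temperature population survive.
#'
#' @param energies an [ensemble_energies()] table.
#' @param window energy window in kJ/mol (> 0 allowed to be 0, which
#'   keeps only the degenerate minima).
#' @return A filtered [ensemble_energies()] table.
#' @export
filter_energy_window <- function(energies, window = 15) {
  if (!is.finite(window) || window < 0) stop("window must be >= 0")
  keep <- energies$delta_G <= window + 1e-12
  ensemble_energies(energies$conformer_id[keep], energies$delta_G[keep],
                    attr(energies, "temperature") %||% 298.15)
}
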
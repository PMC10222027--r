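# shared fixtures and independent oracles, built in code at test time

default_labels <- function(ring_upper = "G-", ring_lower = "g+",
                           network = "cc", phenyl = "T",
                           ph_upper = NULL, ph_lower = NULL) {
  l <- list(ring_upper = ring_upper, ring_lower = ring_lower,
            network = network, phenyl = phenyl)
  if (!is.null(ph_upper)) l$ph_upper <- ph_upper
  if (!is.null(ph_lower)) l$ph_lower <- ph_lower
  l
}

# a 3-conformer synthetic benchmark with known mixing weights
make_recovery_case <- function(truth = c(a = 60, b = 30, c = 10),
                               noise = 0, seed = 42,
                               modalities = c("IR", "VCD")) {
  spec <- synthetic_ensemble_spec(
    conformer_ids = names(truth), truth_weights = unname(truth),
    modalities = modalities, n_lines = 10, noise = noise, seed = seed)
  sticks <- make_ensemble_sticks(spec)
  broadened <- lapply(sticks, function(mods)
    lapply(mods, lorentzian_broaden))
  experimental <- lapply(sticks, function(mods)
    make_experimental_spectrum(mods, spec$truth_weights,
                               noise = noise, seed = seed + 10000L))
  list(spec = spec, sticks = sticks, broadened = broadened,
       experimental = experimental, truth = spec$truth_weights)
}

# brute-force oracle: maximize chiral similarity over the 2-simplex at
# integer-percent resolution, independent of the optimizer under test
oracle_simplex_grid <- function(broadened, expspec, step = 1) {
  ids <- names(broadened)
  stopifnot(length(ids) == 3L)
  M <- vapply(broadened, function(s) s$values, numeric(length(expspec$grid)))
  best <- list(s = -Inf, w = NULL)
  for (w1 in seq(0, 100, by = step)) {
    for (w2 in seq(0, 100 - w1, by = step)) {
      w3 <- 100 - w1 - w2
      f <- as.numeric(M %*% (c(w1, w2, w3) / 100))
      s <- sum(f * expspec$values) /
        sqrt(sum(f * f) * sum(expspec$values^2))
      if (is.finite(s) && s > best$s)
        best <- list(s = s, w = stats::setNames(c(w1, w2, w3), ids))
    }
  }
  best
}

# trapezoid quadrature, independent of the package internals
trapz_oracle <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
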
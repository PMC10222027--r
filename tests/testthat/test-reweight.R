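test_that("similarity satisfies the Cauchy-Schwarz identities", {
  grid <- seq(1000, 1700, by = 1)
  f <- lorentzian_broaden(stick_spectrum(c(1100, 1400), c(1, -1), "VCD"),
                          grid)
  expect_equal(similarity(f, f)$value, 1, tolerance = 1e-12)
  neg <- grid_spectrum(grid, -f$values, "VCD")
  expect_equal(similarity(f, neg)$value, -1, tolerance = 1e-12)
  # positive scaling of either side leaves the score unchanged
  scaled <- grid_spectrum(grid, 7.3 * f$values, "VCD")
  expect_equal(similarity(f, scaled)$value, 1, tolerance = 1e-12)
  # disjoint narrow bands are nearly orthogonal
  g <- lorentzian_broaden(stick_spectrum(c(1150, 1600), c(1, 1), "VCD"),
                          grid, gamma = 2)
  h <- lorentzian_broaden(stick_spectrum(c(1300, 1500), c(1, 1), "VCD"),
                          grid, gamma = 2)
  expect_lt(abs(similarity(g, h)$value), 0.05)
  # errors: modality mismatch, short overlap, zero norm
  ir <- grid_spectrum(grid, f$values, "IR")
  expect_error(similarity(f, ir), "modalities")
  short <- grid_spectrum(seq(1000, 1050, 1), rep(1, 51), "VCD")
  expect_error(similarity(f, short), "below")
  zero <- grid_spectrum(grid, rep(0, length(grid)), "VCD")
  expect_error(similarity(f, zero), "zero-norm")
})

test_that("unsigned similarity aligns baselines before comparing", {
  grid <- seq(1000, 1700, by = 1)
  f <- lorentzian_broaden(stick_spectrum(1300, 1, "IR"), grid)
  # an additive offset must not change the unsigned score
  offset <- grid_spectrum(grid, f$values + 0.5, "IR")
  expect_equal(similarity(f, offset)$value, 1, tolerance = 1e-12)
})

test_that("refine_weights recovers known mixing weights (noise-free)", {
  case <- make_recovery_case(noise = 0, seed = 42)
  en <- ensemble_energies(names(case$truth), c(0, 1, 2))
  wB <- boltzmann_percentages(en)
  res <- refine_weights(
    list(chiral = case$broadened$VCD, parent = case$broadened$IR),
    list(chiral = case$experimental$VCD, parent = case$experimental$IR),
    wB, alpha = 0.7, lambda = 0)
  expect_s3_class(res, "refinement_result")
  expect_lte(res$objective, res$objective_start)
  expect_equal(sum(res$weights$percent), 100, tolerance = 1e-9)
  expect_lte(max(abs(res$weights$percent[names(case$truth)] - case$truth)),
             2)
  expect_gte(res$similarity_after[["chiral"]], 1 - 1e-6)
  # independent oracle: integer-grid search over the simplex agrees
  oracle <- oracle_simplex_grid(case$broadened$VCD, case$experimental$VCD)
  expect_lte(max(abs(oracle$w - case$truth)), 2)
})

test_that("refinement cannot beat an experimental trace it already matches", {
  case <- make_recovery_case(truth = c(a = 50, b = 30, c = 20), seed = 77)
  wB <- conformer_weights(c(a = 50, b = 30, c = 20), "refined")
  # experimental == Boltzmann average: the start is already optimal
  expb <- make_experimental_spectrum(case$sticks$VCD, wB$percent)
  res <- refine_weights(list(chiral = case$broadened$VCD),
                        list(chiral = expb), wB, lambda = 0)
  expect_lte(res$objective, res$objective_start + 1e-12)
  expect_gte(res$similarity_after[["chiral"]], 1 - 1e-6)
})

test_that("a dominant prior pins the solution to the Boltzmann weights", {
  case <- make_recovery_case(seed = 19)
  en <- ensemble_energies(names(case$truth), c(0, 2, 4))
  wB <- boltzmann_percentages(en)
  res <- refine_weights(list(chiral = case$broadened$VCD),
                        list(chiral = case$experimental$VCD),
                        wB, lambda = 1e6)
  expect_equal(unname(res$weights$percent), unname(wB$percent),
               tolerance = 1e-3)
})

test_that("refinement is invariant to conformer ordering", {
  case <- make_recovery_case(seed = 23)
  wB <- conformer_weights(c(a = 40, b = 35, c = 25), "refined")
  res1 <- refine_weights(list(chiral = case$broadened$VCD),
                         list(chiral = case$experimental$VCD), wB,
                         lambda = 0.1)
  perm <- c("c", "a", "b")
  res2 <- refine_weights(list(chiral = case$broadened$VCD[perm]),
                         list(chiral = case$experimental$VCD), wB,
                         lambda = 0.1)
  expect_equal(res1$weights$percent[perm], res2$weights$percent,
               tolerance = 1e-4)
})

test_that("recovery degrades gracefully under 5% noise", {
  errs <- numeric(20)
  for (k in 1:20) {
    case <- make_recovery_case(noise = 0.05, seed = 1000 + k,
                               modalities = "VCD")
    wB <- conformer_weights(c(a = 34, b = 33, c = 33), "refined")
    res <- refine_weights(list(chiral = case$broadened$VCD),
                          list(chiral = case$experimental$VCD),
                          wB, alpha = 1, lambda = 0)
    errs[k] <- max(abs(res$weights$percent[names(case$truth)] - case$truth))
  }
  expect_lt(max(errs), 5)
})

test_that("group_abundances reproduces the published worked examples", {
  # DMSO per-conformer weights group to G+ 15, G- 75, T 10
  dmso <- group_abundances(stated_weights("phb_glu", "dmso"),
                           key = "pyranose-hydroxymethyl")
  expect_equal(stats::setNames(dmso$percent, dmso$group),
               c("G+" = 15, "G-" = 75, "T" = 10))
  # water weights group to 53/40/7
  water <- group_abundances(stated_weights("phb_glu", "water"),
                            key = "pyranose-hydroxymethyl")
  expect_equal(stats::setNames(water$percent, water$group),
               c("G+" = 53, "G-" = 40, "T" = 7))
  # total weight is conserved exactly, including off-100 stated sets
  g105 <- group_abundances(stated_weights("gastrodin", "dmso"),
                           key = "pyranose-hydroxymethyl")
  expect_equal(sum(g105$percent),
               sum(stated_weights("gastrodin", "dmso")$percent))
})

test_that("group_abundances handles core keys, zeros and bad names", {
  w <- stated_weights("gastrodin", "dmso")
  core <- group_abundances(w, key = "phb-glu-core")
  expect_true(all(grepl("^[GT][+-]?[gt][+-]?/c{1,2}/", core$group)))
  expect_equal(sum(core$percent), 105)
  # all weight on one conformer: 100 in its group, zeros reported
  one <- group_abundances(conformer_weights(c("G+g-/cc/T" = 100), "refined"),
                          key = "pyranose-hydroxymethyl")
  expect_equal(stats::setNames(one$percent, one$group),
               c("G+" = 100, "G-" = 0, "T" = 0))
  expect_error(
    group_abundances(conformer_weights(c("whatever" = 100), "refined"),
                     key = "pyranose-hydroxymethyl"),
    "unparseable")
})

test_that("core_group_rollup reproduces the gastrodin distributions", {
  dmso <- core_group_rollup(stated_weights("gastrodin", "dmso", "core"))
  expect_equal(stats::setNames(dmso$percent, dmso$group),
               c("G+" = 56, "G-" = 22, "T" = 22))
  water <- core_group_rollup(stated_weights("gastrodin", "water", "core"))
  expect_equal(stats::setNames(water$percent, water$group),
               c("G+" = 70, "G-" = 21, "T" = 8.3))
  # full precision is kept: the T group is 8.3, not rounded to 8 or 9
  expect_equal(water$percent[water$group == "T"], 8.3, tolerance = 1e-12)
  # plain named vectors work too, and empty groups report as zero
  r <- core_group_rollup(c("G+g-/cc/T" = 100))
  expect_equal(stats::setNames(r$percent, r$group),
               c("G+" = 100, "G-" = 0, "T" = 0))
})
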
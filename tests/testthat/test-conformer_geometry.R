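test_that("read_xyz parses multi-frame files and applies the id fallback", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c(
    "4", "first frame",
    "C 0 0 0", "C 1.5 0 0", "C 2.0 1.4 0", "C 2.5 1.4 1.2",
    "2", "",
    "O 0 0 0", "H 0.96 0 0",
    "2", "",
    "O 0 0 1", "H 0.96 0 1"), path)
  geoms <- read_xyz(path)
  expect_length(geoms, 3L)
  expect_equal(length(geoms[[1]]$atoms), 4L)
  expect_equal(geoms[[1]]$conformer_id, "first frame")
  # blank comment lines fall back to the 0-based frame index
  expect_equal(geoms[[2]]$conformer_id, "1")
  expect_equal(geoms[[3]]$conformer_id, "2")

  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "truncated", "C 0 0 0", "C 1 0 0"), bad)
  expect_error(read_xyz(bad), "frame 0")
  bad2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "x", "C a b c"), bad2)
  expect_error(read_xyz(bad2), "non-numeric")
})

test_that("xyz round-trips through write_xyz", {
  g <- make_conformer_geometry(default_labels(), "phb_glu", seed = 3)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(g$geometry, path)
  back <- read_xyz(path)[[1]]
  expect_equal(back$atoms, g$geometry$atoms)
  expect_equal(back$coords, g$geometry$coords, tolerance = 1e-7)
  expect_equal(back$conformer_id, "G-g+/cc/T")
})

test_that("dihedral follows the IUPAC convention on planar references", {
  # planar cis (0) and trans (180) arrangements
  cis <- geometry(rep("C", 4),
                  rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_equal(dihedral(cis, 1, 2, 3, 4), 0)
  trans <- geometry(rep("C", 4),
                    rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)))
  expect_equal(dihedral(trans, 1, 2, 3, 4), 180)
  collinear <- geometry(rep("C", 4),
                        rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)))
  expect_error(dihedral(collinear, 1, 2, 3, 4), "collinear")
})

test_that("internal-coordinate placement reproduces prescribed torsions", {
  a <- c(0, 0, 0); b <- c(1.54, 0, 0); c0 <- c(2.1, 1.4, 0)
  for (tor in c(-150, -60, 0, 60, 120, 180)) {
    d <- place_atom(a, b, c0, 1.54, 111, tor)
    g <- geometry(rep("C", 4), rbind(a, b, c0, d))
    expect_equal(dihedral(g, 1, 2, 3, 4), wrap_angle(tor), tolerance = 1e-6)
  }
})

test_that("dihedral is invariant under atom-order reversal", {
  set.seed(11)
  for (r in 1:20) {
    coords <- matrix(rnorm(12), 4, 3)
    g <- geometry(rep("C", 4), coords)
    d1 <- tryCatch(dihedral(g, 1, 2, 3, 4), error = function(e) NA)
    if (is.na(d1)) next
    expect_equal(dihedral(g, 4, 3, 2, 1), d1, tolerance = 1e-9)
  }
})

test_that("classify_torsion picks the nearest canonical angle circularly", {
  expect_equal(classify_torsion(60, "upper")$value, "G+")
  expect_equal(classify_torsion(-51, "upper")$value, "G-")
  # circular metric: 170 and -170 are both 10 degrees from 180
  expect_equal(classify_torsion(170, "upper")$value, "T")
  expect_equal(classify_torsion(-170, "upper")$value, "T")
  expect_equal(classify_torsion(175, "lower")$value, "t")
  expect_equal(classify_torsion(-60, "lower")$value, "g-")
  # invariance under full turns
  for (ang in c(-130, -45, 10, 85, 150)) {
    expect_equal(classify_torsion(ang + 360, "upper")$value,
                 classify_torsion(ang, "upper")$value)
    expect_equal(classify_torsion(ang - 720, "upper")$value,
                 classify_torsion(ang, "upper")$value)
  }
  # exact boundaries warn and resolve deterministically
  expect_warning(l0 <- classify_torsion(0, "upper"), "boundary")
  expect_equal(l0$value, "G+")
  expect_warning(l120 <- classify_torsion(120, "upper"), "boundary")
  expect_equal(l120$value, "G+")
})

test_that("detect_contacts finds H...O contacts by distance cutoff", {
  g <- make_conformer_geometry(default_labels(), "phb_glu", seed = 5)
  # move H2 to exactly 2.5 A from O3 along the O2->O3 axis
  geom <- g$geometry; map <- g$atom_map
  o3 <- geom$coords[map_index(map, "O3"), ]
  o2 <- geom$coords[map_index(map, "O2"), ]
  u <- (o3 - o2) / sqrt(sum((o3 - o2)^2))
  geom$coords[map_index(map, "H2"), ] <- o3 - 2.5 * u
  ct <- detect_contacts(geom, map, cutoff = 2.7)
  h2o3 <- ct[ct$donor == "O2" & ct$acceptor == "O3", ]
  expect_equal(nrow(h2o3), 1L)
  expect_equal(h2o3$distance, 2.5, tolerance = 1e-9)
  # a tiny cutoff removes every contact
  expect_equal(nrow(detect_contacts(geom, map, cutoff = 0.5)), 0L)
})

test_that("an H equidistant from two acceptors yields both contacts", {
  g <- make_conformer_geometry(default_labels(), "phb_glu", seed = 6)
  geom <- g$geometry; map <- g$atom_map
  o2 <- geom$coords[map_index(map, "O2"), ]
  o4 <- geom$coords[map_index(map, "O4"), ]
  mid <- (o2 + o4) / 2
  # place O3's H at a point 2.6 A from both O2 and O4 (off the midpoint,
  # perpendicular to the O2-O4 axis)
  half <- sqrt(sum((o4 - o2)^2)) / 2
  expect_true(half < 2.6)
  axis <- (o4 - o2) / (2 * half)
  perp <- c(-axis[2], axis[1], 0)
  perp <- perp - sum(perp * axis) * axis
  perp <- perp / sqrt(sum(perp^2))
  geom$coords[map_index(map, "H3"), ] <- mid + sqrt(2.6^2 - half^2) * perp
  ct <- detect_contacts(geom, map, cutoff = 2.7)
  h3 <- ct[ct$donor == "O3" & ct$acceptor %in% c("O2", "O4"), ]
  expect_setequal(h3$acceptor, c("O2", "O4"))
  expect_equal(h3$distance, rep(2.6, 2), tolerance = 1e-9)
})

test_that("classify_network maps chain direction to cc/c and needs 2 links", {
  map <- make_conformer_geometry(default_labels(), "phb_glu", seed = 1)$atom_map
  mk <- function(donor, acceptor)
    data.frame(donor = donor, acceptor = acceptor, distance = 2.5)
  expect_equal(classify_network(mk(c("O2", "O3"), c("O3", "O4")),
                                map)$direction, "cc")
  expect_equal(classify_network(mk(c("O4", "O3"), c("O3", "O2")),
                                map)$direction, "c")
  # a single link is not a chain
  expect_equal(classify_network(mk("O2", "O3"), map)$direction, "none")
  # contradictory links warn and give none
  expect_warning(
    net <- classify_network(mk(c("O2", "O4"), c("O3", "O3")), map),
    "contradictory")
  expect_equal(net$direction, "none")
  # the convention can be inverted by configuration
  expect_equal(classify_network(mk(c("O2", "O3"), c("O3", "O4")), map,
                                invert_convention = TRUE)$direction, "c")
})

test_that("assemble_name builds systematic names for both scaffolds", {
  g <- make_conformer_geometry(default_labels("G-", "g+", "cc", "T"),
                               "phb_glu", seed = 2)
  nm <- assemble_name(g$geometry, g$atom_map)
  expect_equal(nm$rendered, "G-g+/cc/T")
  expect_s3_class(nm$ring_hydroxymethyl$upper, "torsion_label")
  # the phenyl tilt is reported numerically but never part of the name
  expect_true(is.finite(nm$phenyl_tilt_deg))
  expect_false(grepl(sprintf("%.0f", nm$phenyl_tilt_deg), nm$rendered))

  gg <- make_conformer_geometry(
    default_labels("G-", "g+", "cc", "T", ph_upper = "G+", ph_lower = "g-"),
    "gastrodin", seed = 2)
  expect_equal(assemble_name(gg$geometry, gg$atom_map)$rendered,
               "G-g+/cc/T/G+g-")

  gt <- make_conformer_geometry(default_labels(ring_lower = "t"),
                                "phb_glu", seed = 2)
  # lower-case role renders lower-case labels
  expect_match(assemble_name(gt$geometry, gt$atom_map)$rendered,
               "^G-t/")
})

test_that("generated names round-trip over every label combination", {
  uppers <- c("G+", "G-", "T"); lowers <- c("g+", "g-", "t")
  nets <- c("cc", "c")
  k <- 0
  for (ru in uppers) for (rl in lowers) for (nw in nets) for (ph in uppers) {
    k <- k + 1
    g <- make_conformer_geometry(default_labels(ru, rl, nw, ph),
                                 "phb_glu", seed = k, jitter = 15)
    expect_equal(assemble_name(g$geometry, g$atom_map)$rendered,
                 paste0(ru, rl, "/", nw, "/", ph))
  }
  # gastrodin: vary the phenyl hydroxymethyl labels over their 3 x 3 grid
  for (pu in uppers) for (pl in lowers) {
    k <- k + 1
    g <- make_conformer_geometry(
      default_labels(ph_upper = pu, ph_lower = pl), "gastrodin",
      seed = k, jitter = 15)
    expect_equal(assemble_name(g$geometry, g$atom_map)$rendered,
                 paste0("G-g+/cc/T/", pu, pl))
  }
})

test_that("structural_report returns consistent internal coordinates", {
  g <- make_conformer_geometry(default_labels(), "phb_glu", seed = 9)
  rep <- structural_report(g$geometry, g$atom_map)
  expect_true(all(rep$value[rep$type == "distance"] >= 0))
  # dihedral rows agree with dihedral() on the same atoms
  map <- g$atom_map
  idx <- vapply(c("O6", "C6", "C5", "O5"),
                function(l) map_index(map, l), 1L)
  expect_equal(rep$value[rep$name == "O6-C6-C5-O5"],
               dihedral(g$geometry, idx[1], idx[2], idx[3], idx[4]))
  # custom parameters: distances are symmetric, right angles measure 90
  tri <- geometry(c("C", "C", "C"),
                  rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  m2 <- g$atom_map
  expect_equal(atom_distance(tri, 1, 2), atom_distance(tri, 2, 1))
  expect_equal(bond_angle(tri, 1, 2, 3), 90)
  expect_error(structural_report(g$geometry, map,
                                 params = list(bad = c("Q9", "O5"))),
               "resolve")
})

test_that("atom maps validate indices and resolve chemical labels", {
  g <- make_conformer_geometry(default_labels(), "phb_glu", seed = 4)
  map <- g$atom_map
  expect_equal(g$geometry$atoms[map_index(map, "O5")], "O")
  expect_equal(g$geometry$atoms[map_index(map, "H3")], "H")
  expect_error(map_index(map, "O9"), "resolve")
  # round-trip through the 0-based YAML representation
  path <- withr::local_tempfile(fileext = ".yaml")
  write_atom_map(map, path)
  back <- read_atom_map(path)
  expect_equal(back$indices, map$indices)
  expect_equal(back$hydroxyls, map$hydroxyls)
  # duplicate indices rejected
  idx <- map$indices; idx$C1 <- idx$C2
  expect_error(atom_map(idx, map$hydroxyls, "phb_glu"), "distinct")
})
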
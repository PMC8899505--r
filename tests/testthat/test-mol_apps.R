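# Filtering, uniqueness, reordering, splitting, coordinate utilities.

test_that("sequential filters partition the input and log staged removals", {
  mols <- lapply(c("gefitinib", "dasatinib", "osimertinib", "benzene"), bm)
  crit <- list(
    filter_criterion("property_compare", property = "TopologicalPolarSurfaceArea",
                     comparator = "less", threshold = 140),
    filter_criterion("property_compare", property = "NRotBond",
                     comparator = "less_equal", threshold = 10))
  out <- filter_molecules(mols, crit, "all")
  expect_identical(length(out$matched) + length(out$unmatched), length(mols))
  expect_identical(out$log$removed_at_stage, c(0L, 0L))
  # a molecule over the TPSA limit is removed at stage one
  tight <- list(filter_criterion("property_compare",
                                 property = "TopologicalPolarSurfaceArea",
                                 comparator = "less", threshold = 100),
                filter_criterion("property_compare", property = "NRotBond",
                                 comparator = "less_equal", threshold = 10))
  out2 <- filter_molecules(mols, tight, "all")
  expect_identical(out2$log$removed_at_stage[1], 1L)  # dasatinib TPSA 106.5
  # any-mode matches on either criterion
  out3 <- filter_molecules(mols, tight, "any")
  expect_identical(length(out3$matched), 4L)
})

test_that("filter partition property holds for random criteria on fixtures", {
  mols <- lapply(1:20, random_molecule)
  crit <- list(filter_criterion("property_compare", property = "Weight",
                                comparator = "greater", threshold = 80),
               filter_criterion("defined_atom_types"),
               filter_criterion("simple_connectivity"))
  for (mode in c("all", "any")) {
    out <- filter_molecules(mols, crit, mode)
    expect_identical(length(out$matched) + length(out$unmatched), 20L)
  }
})

test_that("substructure filters match the containment predicate", {
  mols <- list(bm("gefitinib"), bm("benzene"), bm("piperazine"))
  crit <- filter_criterion("contains_fragments_from", queries = bm("aniline"))
  out <- filter_molecules(mols, crit)
  expect_identical(vapply(out$matched, function(m) m$name, character(1)),
                   "gefitinib")
})

test_that("descriptor failure routes the molecule to unmatched with a log", {
  mols <- list(bm("benzene"), bm("water"))
  crit <- filter_criterion("property_compare", property = "IsActive",
                           comparator = "greater", threshold = 0)
  out <- filter_molecules(mols, crit)
  expect_length(out$matched, 0L)
  expect_identical(out$log$errors, 2L)
})

test_that("uniqueness levels nest and policies merge properties correctly", {
  b1 <- bm("benzene"); b2 <- bm("benzene")
  r <- unique_molecules(list(b1, b2))
  expect_identical(c(length(r$unique), length(r$dupes)), c(1L, 1L))
  # enantiomers: one constitution, two configurations
  sr <- bm("stereo_R"); ss <- bm("stereo_S")
  expect_length(unique_molecules(list(sr, ss), "Constitutions")$unique, 1L)
  expect_length(unique_molecules(list(sr, ss), "Configurations")$unique, 2L)
  # level ordering on a mixed bag with conformers
  g <- bm("gefitinib")
  g2 <- rotate_molecule(g, c(1, 1, 0), 0.4)       # same conformer, moved
  g3 <- g; g3$atoms$x[1] <- g3$atoms$x[1] + 2     # different conformer
  bag <- list(g, g2, g3, sr, ss)
  counts <- vapply(c("Constitutions", "Configurations", "Conformations",
                     "Exact"),
                   function(lv) length(unique_molecules(bag, lv)$unique),
                   integer(1))
  expect_true(all(diff(counts) >= 0L))
  expect_identical(unname(counts["Exact"]), 5L)
  # merge keeps first value on conflict; overwrite keeps last
  m1 <- bm("benzene"); m1$properties <- list(a = "1")
  m2 <- bm("benzene"); m2$properties <- list(a = "2", b = "3")
  um <- unique_molecules(list(m1, m2), dupes_policy = "merge")$unique[[1]]
  expect_identical(um$properties, list(a = "1", b = "3"))
  uo <- unique_molecules(list(m1, m2), dupes_policy = "overwrite")$unique[[1]]
  expect_identical(uo$properties[c("a", "b")], list(a = "2", b = "3"))
})

test_that("uniqueness counts satisfy |unique| + |dupes| = |input| on fuzz", {
  mols <- c(lapply(1:10, random_molecule), lapply(1:5, random_molecule))
  r <- unique_molecules(mols, "Constitutions")
  expect_identical(length(r$unique) + length(r$dupes), 15L)
  expect_gte(length(r$dupes), 5L)
})

test_that("reordering is stable, directional, and truncatable", {
  ms <- list(bm("ethanol"), bm("benzene"), bm("methane"))
  ro <- reorder_molecules(ms, "Weight", reverse = TRUE)
  expect_identical(vapply(ro, function(m) m$name, character(1)),
                   c("benzene", "ethanol", "methane"))
  ro2 <- reorder_molecules(ms, "Weight")
  expect_identical(ro2[[1]]$name, "methane")
  # ties preserve input order (stability)
  same <- list(bm("benzene"), bm("ethanol"), bm("benzene"))
  same[[1]]$name <- "first"; same[[3]]$name <- "third"
  tied <- reorder_molecules(same, "NRings", reverse = TRUE)
  expect_identical(vapply(tied, function(m) m$name, character(1))[1:2],
                   c("first", "third"))
  # output cap
  many <- rep(list(bm("water")), 25)
  expect_length(reorder_molecules(many, "Weight", output_max = 10), 10L)
  expect_error(reorder_molecules(ms, "Atom_Mass"), "scalar")
})

test_that("splits obey their definitions and partition heavy atoms", {
  tol <- bm("toluene")
  expect_identical(n_atoms(split_molecules(tol, "Scaffolds")[[1]]), 6L)
  expect_identical(n_atoms(split_molecules(tol, "Rings")[[1]]), 6L)
  expect_identical(n_atoms(split_molecules(tol, "Chains")[[1]]), 1L)
  expect_length(split_molecules(bm("propane"), "Scaffolds"), 0L)
  expect_identical(n_atoms(split_molecules(bm("propane"), "Chains")[[1]]), 3L)
  b <- bm("benzene")
  expect_identical(n_atoms(split_molecules(b, "Scaffolds")[[1]]), 6L)
  # scaffold + inverse scaffold partition the heavy atoms
  for (name in c("gefitinib", "afatinib", "osimertinib", "toluene")) {
    mol <- bm(name)
    sc <- split_molecules(mol, "Scaffolds")
    inv <- split_molecules(mol, "InverseScaffold")
    n_sc <- sum(vapply(sc, n_atoms, integer(1)))
    n_inv <- sum(vapply(inv, n_atoms, integer(1)))
    expect_identical(n_sc + n_inv, length(heavy_atoms(mol)), label = name)
  }
  # MCS split returns the shared fragment
  lcs <- split_molecules(bm("gefitinib"), "LargestCommonSubstructure",
                         reference = bm("afatinib"))
  expect_identical(n_atoms(lcs[[1]]), 21L)
})

test_that("centroid and recenter satisfy their contracts", {
  two <- molecule("two", data.frame(element = c("C", "C"), charge = 0L,
                                    x = c(0, 2), y = 0, z = 0,
                                    aromatic = FALSE))
  expect_equal(centroid(two), c(x = 1, y = 0, z = 0), ignore_attr = TRUE)
  for (name in c("benzene", "gefitinib", "stereo_R")) {
    rc <- recenter(bm(name))
    expect_lt(max(abs(centroid(rc))), 1e-6)
    rc2 <- recenter(rc)
    expect_equal(coords(rc2), coords(rc), tolerance = 1e-9)
  }
})
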
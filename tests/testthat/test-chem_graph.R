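# Molecular graph model, SDF round trips, standardization.

test_that("SDF reading handles empty input, records and data blocks", {
  expect_identical(read_sdf(character()), list())
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines("", f)
  expect_length(read_sdf(f), 0L)

  mol <- bm("benzene")
  mol$properties <- list(IsActive = "1", Note = "two\nlines")
  f2 <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(list(mol), f2)
  back <- read_sdf(f2)[[1]]
  expect_identical(back$properties$IsActive, "1")
  expect_identical(back$properties$Note, "two\nlines")
})

test_that("write/read round trip preserves graphs, coordinates, properties", {
  for (name in c("ethanol", "benzene", "pyridine", "gefitinib", "stereo_R")) {
    mol <- bm(name)
    mol$properties <- list(tag = name)
    f <- withr::local_tempfile(fileext = ".sdf")
    write_sdf(list(mol), f)
    back <- read_sdf(f)[[1]]
    expect_identical(back$atoms$element, mol$atoms$element)
    expect_equal(coords(back), coords(mol), tolerance = 1e-4)
    expect_identical(back$properties, mol$properties)
    expect_identical(sort(back$bonds$order), sort(mol$bonds$order))
  }
})

test_that("gzip SDF input is detected from magic bytes", {
  f <- withr::local_tempfile(fileext = ".sdf.gz")
  write_sdf(list(bm("ethanol")), f)
  mols <- read_sdf(f)
  expect_length(mols, 1L)
  expect_identical(mols[[1]]$atoms$element, c("C", "C", "O"))
})

test_that("bond order 4 reads as aromatic and kekulizes; explicit output", {
  benz <- exact_benzene()
  f <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(list(benz), f, explicit_aromaticity = TRUE)
  lines <- readLines(f)
  expect_length(grep("^  \\d  \\d  4", lines), 6L)
  back <- read_sdf(f)[[1]]
  expect_true(all(back$bonds$aromatic))
  expect_true(all(back$atoms$aromatic))
  expect_identical(sort(back$bonds$order), c(1L, 1L, 1L, 2L, 2L, 2L))
  # default output is kekulized
  f2 <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(list(back), f2)
  expect_length(grep("^  \\d  \\d  4", readLines(f2)), 0L)
})

test_that("malformed records are skipped in lenient mode, fatal in strict", {
  good <- write_sdf(list(bm("water")))
  bad <- c("broken", "", "", "  X  0  0  0  0  0  0  0  0  0999 V2000",
           "M  END", "$$$$")
  txt <- c(bad, good)
  expect_warning(mols <- read_sdf(txt), "record 1")
  expect_length(mols, 1L)
  expect_error(read_sdf(txt, strict = TRUE), "record 1")
})

test_that("V3000 records are rejected with a clear error", {
  rec <- c("m", "", "", "  0  0  0  0  0  0  0  0  0  0999 V3000",
           "M  END", "$$$$")
  expect_warning(expect_length(read_sdf(rec), 0L), "V3000")
})

test_that("hydrogen saturation fills valences and is idempotent", {
  me <- bm("methane")
  expect_identical(n_atoms(me), 1L)
  meh <- add_hydrogens(me)
  expect_identical(sum(meh$atoms$element == "H"), 4L)
  expect_identical(n_atoms(add_hydrogens(meh)), n_atoms(meh))
  # aromatic valence bookkeeping: pyridine N gains 0 H, pyrrole N gains 1 H
  pyd <- add_hydrogens(bm("pyridine"))
  pyr <- add_hydrogens(bm("pyrrole"))
  h_on_n <- function(m) {
    ni <- which(m$atoms$element == "N")
    adj <- chemtk:::adjacency(m)
    sum(m$atoms$element[adj[[ni]]$nbr] == "H")
  }
  expect_identical(h_on_n(pyd), 0L)
  expect_identical(h_on_n(pyr), 1L)
  # heavy-atom count and heavy-atom properties unchanged
  g <- bm("gefitinib")
  gh <- add_hydrogens(g)
  expect_identical(length(heavy_atoms(gh)), length(heavy_atoms(g)))
  expect_equal(tpsa(gh), tpsa(g))
})

test_that("neutralization follows the protonation/bond-order rule table", {
  # carboxylate: O- becomes OH (charge 0)
  carbox <- molecule("acetate", data.frame(
    element = c("C", "C", "O", "O"), charge = c(0L, 0L, 0L, -1L),
    x = 1:4, y = 0, z = 0, aromatic = FALSE),
    data.frame(a1 = c(1, 2, 2), a2 = c(2, 3, 4), order = c(1L, 2L, 1L)))
  fixed <- neutralize(carbox)
  expect_identical(fixed$atoms$charge[4], 0L)
  expect_identical(chemtk:::implicit_h_counts(fixed)[4], 1L)
  # ammonium with explicit H: one H removed, charge cleared
  amm <- add_hydrogens(molecule("ammonium", data.frame(
    element = "N", charge = 1L, x = 0, y = 0, z = 0, aromatic = FALSE)))
  expect_identical(sum(amm$atoms$element == "H"), 4L)
  fixed <- neutralize(amm)
  expect_identical(fixed$atoms$charge[1], 0L)
  expect_identical(sum(fixed$atoms$element == "H"), 3L)
  # quaternary ammonium is untouchable
  quat <- molecule("quat", data.frame(
    element = c("N", "C", "C", "C", "C"), charge = c(1L, 0L, 0L, 0L, 0L),
    x = 1:5, y = 0, z = 0, aromatic = FALSE),
    data.frame(a1 = 1, a2 = 2:5, order = 1L))
  expect_identical(neutralize(quat)$atoms$charge[1], 1L)
})

test_that("atom-type validation flags over-valent atoms only", {
  penta <- molecule("pentavalent", data.frame(
    element = c("C", "C", "C", "C", "C", "C"), charge = 0L,
    x = 1:6, y = 0, z = 0, aromatic = FALSE),
    data.frame(a1 = 1, a2 = 2:6, order = 1L))
  expect_identical(validate_atom_types(penta), 1L)
  for (name in builtin_molecule_names())
    expect_identical(validate_atom_types(bm(name)), integer(0))
})

test_that("ring perception and aromaticity match textbook cases", {
  benz <- bm("benzene")
  expect_identical(sum(benz$atoms$aromatic), 6L)
  expect_identical(sum(benz$bonds$aromatic), 6L)
  expect_identical(sum(bm("cyclohexane")$atoms$aromatic), 0L)
  expect_identical(sum(bm("naphthalene")$atoms$aromatic), 10L)
  expect_identical(sum(bm("pyrrole")$atoms$aromatic), 5L)
  expect_identical(sum(bm("piperazine")$atoms$aromatic), 0L)
})

test_that("components split largest-first; kekulize preserves bond multisets", {
  salt <- molecule("salt", data.frame(
    element = c("C", "C", "C", "O"), charge = 0L, x = 1:4, y = 0, z = 0,
    aromatic = FALSE),
    data.frame(a1 = c(1, 2), a2 = c(2, 3), order = 1L))
  comps <- connected_components(salt)
  expect_length(comps, 2L)
  expect_identical(n_atoms(comps[[1]]), 3L)
  # kekulize o perceive = identity on bond-order multisets without aromatics
  eth <- bm("ethanol")
  expect_identical(sort(kekulize(perceive_rings_and_aromaticity(eth))$bonds$order),
                   sort(eth$bonds$order))
})

test_that("independent SDF reader agrees on atoms and bonds", {
  skip_if_not_installed("ChemmineR")
  f <- system.file("extdata", "structures", "gefitinib.sdf",
                   package = "chemtk")
  ours <- read_sdf(f)[[1]]
  ref <- suppressWarnings(ChemmineR::read.SDFset(f))[[1]]
  expect_identical(n_atoms(ours), nrow(ChemmineR::atomblock(ref)))
  expect_identical(nrow(ours$bonds), nrow(ChemmineR::bondblock(ref)))
  ab <- ChemmineR::atomblock(ref)
  expect_equal(unname(coords(ours)), unname(ab[, 1:3]), tolerance = 1e-4)
})
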
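# Substructure comparison, Tanimoto/Tversky, RMSD, superposition, alignment.

test_that("identical molecules give complete mappings and TC 1", {
  for (name in c("benzene", "aniline", "gefitinib")) {
    mol <- bm(name)
    res <- mcs(mol, mol)
    expect_identical(res$size, length(heavy_atoms(mol)))
    expect_equal(tanimoto(res), 1)
    expect_equal(tanimoto(mcs(mol, mol, connected = FALSE)), 1)
  }
})

test_that("worked-example drug pair reproduces the printed similarities", {
  g <- bm("gefitinib"); a <- bm("afatinib")
  con <- mcs(g, a, connected = TRUE)
  dis <- mcs(g, a, connected = FALSE)
  expect_identical(con$size, 21L)
  expect_equal(tanimoto(con), 21 / (31 + 34 - 21))
  expect_gte(tanimoto(dis), tanimoto(con))
  expect_equal(tanimoto(dis), 30 / (31 + 34 - 30))
})

test_that("connected MCS of ethylbenzene and toluene is ring + one carbon", {
  res <- mcs(bm("ethylbenzene"), bm("toluene"))
  expect_identical(res$size, 7L)
})

test_that("MCS size equals the modular-product max-clique oracle", {
  small <- c("methane", "water", "ethanol", "propane", "benzene",
             "cyclohexane", "toluene", "ethylbenzene", "pyridine", "pyrrole",
             "naphthalene", "aniline", "piperazine")
  mols <- lapply(small, bm)
  for (i in seq_along(mols)) for (j in seq(i, length(mols))) {
    got <- mcs(mols[[i]], mols[[j]], connected = TRUE)$size
    expect_identical(got, oracle_mcs_size(mols[[i]], mols[[j]]),
                     info = paste(small[i], small[j]))
  }
})

test_that("MCS mappings are feasible under the comparison types", {
  cmp <- comparison_type()
  pairs <- list(c("gefitinib", "afatinib"), c("toluene", "ethylbenzene"),
                c("pyridine", "pyrrole"))
  for (pr in pairs) {
    a <- bm(pr[1]); b <- bm(pr[2])
    res <- mcs(a, b)
    keysA <- chemtk:::atom_keys(a, cmp$atom_level)
    keysB <- chemtk:::atom_keys(b, cmp$atom_level)
    expect_true(all(keysA[res$mapping[, 1]] == keysB[res$mapping[, 2]]))
    codeA <- chemtk:::bond_code_matrix(a, cmp$bond_level)
    codeB <- chemtk:::bond_code_matrix(b, cmp$bond_level)
    sub_a <- codeA[res$mapping[, 1], res$mapping[, 1]]
    sub_b <- codeB[res$mapping[, 2], res$mapping[, 2]]
    expect_identical(sub_a, sub_b)
    expect_false(anyDuplicated(res$mapping[, 1]) > 0)
    expect_false(anyDuplicated(res$mapping[, 2]) > 0)
  }
})

test_that("lower atom resolution never shrinks the MCS", {
  pairs <- list(c("gefitinib", "afatinib"), c("toluene", "ethylbenzene"),
                c("benzene", "pyridine"))
  for (pr in pairs) {
    hi <- mcs(bm(pr[1]), bm(pr[2]), comparison_type("AtomType"))$size
    lo <- mcs(bm(pr[1]), bm(pr[2]), comparison_type("ElementType"))$size
    expect_gte(lo, hi)
  }
})

test_that("Tanimoto is symmetric, bounded, and a Tversky special case", {
  set.seed(11)
  for (seed in 1:6) {
    a <- random_molecule(seed); b <- random_molecule(seed + 100)
    rab <- mcs(a, b); rba <- mcs(b, a)
    expect_equal(tanimoto(rab), tanimoto(rba))
    expect_gte(tanimoto(rab), 0); expect_lte(tanimoto(rab), 1)
    expect_equal(tversky(rab, 1, 1), tanimoto(rab))
    expect_gte(tanimoto(mcs(a, b, connected = FALSE)), tanimoto(rab))
  }
})

test_that("substructure containment matches an independent check", {
  g <- bm("gefitinib")
  expect_true(contains_substructure(g, bm("aniline")))
  expect_true(contains_substructure(bm("aniline"), bm("aniline")))
  expect_false(contains_substructure(bm("aniline"), g))  # query larger
  expect_true(contains_substructure(bm("toluene"), bm("benzene")))
  expect_false(contains_substructure(bm("cyclohexane"), bm("benzene")))
  # gefitinib contains a morpholine but no pyrrole
  expect_false(contains_substructure(g, bm("pyrrole")))
})

test_that("RMSD and SymmetryRMSD behave under ring symmetry", {
  benz <- exact_benzene()
  expect_equal(rmsd(benz, benz), 0)
  expect_equal(symmetry_rmsd(benz, benz), 0)
  rot <- rotate_molecule(benz, c(0, 0, 1), pi / 3)
  expect_gt(rmsd(benz, rot), 0.5)
  expect_lt(symmetry_rmsd(benz, rot), 1e-6)
  expect_lte(symmetry_rmsd(benz, rot), rmsd(benz, rot))
  expect_error(rmsd(benz, bm("pyridine")), "identical")
})

test_that("Kabsch superposition recovers rigid transforms", {
  set.seed(5)
  P <- matrix(rnorm(30), 10, 3)
  fit <- kabsch_superimpose(P, P)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  rotP <- rotate_molecule(
    molecule("pts", data.frame(element = "C", charge = 0L, x = P[, 1],
                               y = P[, 2], z = P[, 3], aromatic = FALSE)),
    c(1, 2, 3), 0.7)
  fit2 <- kabsch_superimpose(P, coords(rotP))
  expect_lt(fit2$rmsd, 1e-9)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superimpose(P[1:2, ], P[1:2, ]), "at least 3")
})

test_that("scaffold alignment reduces mapped-atom RMSD without distortion", {
  g <- bm("gefitinib")
  moved <- rotate_molecule(g, c(1, 0, 0), 1.1)
  moved$atoms$x <- moved$atoms$x + 5
  res <- mcs(g, moved)
  pre <- sqrt(mean(rowSums((coords(g)[res$mapping[, 1], ] -
                            coords(moved)[res$mapping[, 2], ])^2)))
  aligned <- align_to_scaffold(g, list(moved))[[1]]
  post <- sqrt(mean(rowSums((coords(g)[res$mapping[, 1], ] -
                             coords(aligned)[res$mapping[, 2], ])^2)))
  expect_lte(post, pre)
  expect_lt(post, 1e-6)
  # internal geometry unchanged
  expect_equal(as.matrix(dist(coords(aligned))), as.matrix(dist(coords(moved))),
               tolerance = 1e-9)
  # self alignment is the identity
  self <- align_to_scaffold(g, list(g))[[1]]
  expect_equal(coords(self), coords(g), tolerance = 1e-6)
  # explicit-atom mode reproduces the Kabsch fit of those pairs
  expl <- align_to_scaffold(g, list(moved), mode = "explicit",
                            scaffold_atoms = 1:4, mol_atoms = 1:4)[[1]]
  fit <- kabsch_superimpose(coords(g)[1:4, ], coords(moved)[1:4, ])
  manual <- chemtk:::transform_molecule(moved, fit$rotation,
                                        colMeans(coords(moved)[1:4, ]),
                                        fit$translation)
  expect_equal(coords(expl), coords(manual), tolerance = 1e-9)
})

test_that("ensemble comparison has the documented shapes and determinism", {
  mols3 <- list(bm("benzene"), bm("benzene"), bm("benzene"))
  m <- compare_ensembles(mols3, method = "LargestCommonSubstructureTanimoto")
  expect_identical(dim(m), c(3L, 3L))
  expect_true(all(m == 1))
  a2 <- list(bm("benzene"), bm("toluene"))
  b5 <- lapply(c("benzene", "toluene", "pyridine", "aniline", "ethylbenzene"), bm)
  m2 <- compare_ensembles(a2, b5, method = "LargestCommonSubstructureTanimoto")
  expect_identical(dim(m2), c(5L, 2L))
  m2b <- compare_ensembles(a2, b5, method = "LargestCommonSubstructureTanimoto",
                           threads = 4L)
  expect_identical(m2, m2b)
})
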
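# Feature-dataset generation, binary/CSV formats, transformations.

test_that("dataset generation has one row per molecule with results from MDL", {
  mols <- lapply(c("benzene", "ethanol", "pyridine"), bm)
  mols[[1]]$properties <- list(IsActive = "1")
  mols[[2]]$properties <- list(IsActive = "0")
  mols[[3]]$properties <- list(IsActive = "1")
  ds <- generate_dataset(mols, "Combine(Weight, NRings)", "Combine(IsActive)")
  expect_identical(dim(ds), c(3L, 2L))
  expect_identical(as.numeric(ds$Y), c(1, 0, 1))
  # missing result: row kept with NA, dropped under forbid_incomplete
  mols[[2]]$properties <- list()
  ds2 <- generate_dataset(mols, "Combine(Weight, NRings)", "Combine(IsActive)")
  expect_true(is.na(ds2$Y[2, 1]))
  ds3 <- generate_dataset(mols, "Combine(Weight, NRings)", "Combine(IsActive)",
                          forbid_incomplete = TRUE)
  expect_identical(nrow(ds3$X), 2L)
  # constant results
  ds4 <- generate_dataset(mols, "Weight", "Constant(7)")
  expect_true(all(ds4$Y == 7))
})

test_that("binary format round-trips bit-exactly with a readable header", {
  ds <- synthetic_qsar(100, 10, seed = 42)
  f <- withr::local_tempfile(fileext = ".bin")
  write_bin(ds, f)
  ds1 <- read_bin(f)
  write_bin(ds1, f)
  ds2 <- read_bin(f)
  expect_identical(ds1$X, ds2$X)
  expect_identical(ds1$Y, ds2$Y)
  expect_identical(ds1$ids, ds2$ids)
  expect_identical(ds1$feature_labels, ds$feature_labels)
  # header lines are plain text
  hdr <- readLines(f, n = 3, warn = FALSE, skipNul = TRUE)
  expect_match(hdr[1], "CHEMTK-DATASET")
  # empty dataset round trip
  e <- feature_dataset(character(), matrix(0, 0, 3), matrix(0, 0, 1))
  f2 <- withr::local_tempfile(fileext = ".bin")
  write_bin(e, f2)
  eb <- read_bin(f2)
  expect_identical(dim(eb$X), c(0L, 3L))
  # corrupted magic is rejected
  writeLines("NOT-A-DATASET", f2)
  expect_error(read_bin(f2), "magic")
})

test_that("CSV round trip is lossless and column assignment follows args", {
  ds <- read_bin({
    f <- withr::local_tempfile(); write_bin(synthetic_qsar(50, 6, seed = 3), f); f
  })
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, f)
  back <- read_dataset_csv(f, number_result_cols = 1)
  expect_identical(back$X, ds$X)
  expect_identical(back$Y, ds$Y)
  expect_identical(back$feature_labels, sprintf("f%d", 0:5))  # placeholders
  # two result columns claim the last two
  back2 <- read_dataset_csv(f, number_result_cols = 2)
  expect_identical(ncol(back2$X), 5L)
  expect_identical(back2$Y[, 2], ds$Y[, 1])
  expect_error(read_dataset_csv(f, number_result_cols = 1,
                                number_id_chars = 2), "width")
})

test_that("randomize is a seeded joint permutation; chunks are contiguous", {
  ds <- synthetic_qsar(10, 2, seed = 1)
  r1 <- randomize(ds, 7); r2 <- randomize(ds, 7)
  expect_identical(r1$ids, r2$ids)
  expect_identical(r1$X, r2$X)
  expect_false(identical(r1$ids, ds$ids))
  # ids stay aligned with rows
  i <- match(ds$ids[1], r1$ids)
  expect_identical(r1$X[i, ], ds$X[1, ])
  # 10 rows, 5 chunks, block 0 = rows 1..2
  c0 <- chunks(ds, 5, 0)
  expect_identical(c0$ids, ds$ids[1:2])
  parts <- lapply(0:4, function(b) chunks(ds, 5, b)$ids)
  expect_identical(unlist(parts), ds$ids)
  expect_identical(chunks(ds, 5, 1:4)$ids, ds$ids[3:10])
  expect_error(chunks(ds, 5, 5), "range")
})

test_that("combine joins feature columns over identical id sequences", {
  ds <- synthetic_qsar(20, 3, seed = 2)
  ds2 <- ds; ds2$X <- ds$X * 2
  both <- combine_datasets(list(ds, ds2))
  expect_identical(ncol(both$X), 6L)
  expect_identical(both$Y, ds$Y)
  bad <- randomize(ds2, 3)
  expect_error(combine_datasets(list(ds, bad)), "id sequences")
  stacked <- combine_datasets(list(ds, ds2), by_rows = TRUE)
  expect_identical(nrow(stacked$X), 40L)
})

test_that("balancing reaches the target ratio without touching the majors", {
  ds <- synthetic_qsar(2000, 4, active_fraction = 0.005, seed = 9)
  n_act <- sum(ds$Y); n_inact <- sum(ds$Y == 0)
  b <- balance(ds, 0.10, seed = 4)
  expect_identical(sum(b$Y == 0), n_inact)
  expect_gte(sum(b$Y) / sum(b$Y == 0), 0.0999)
  # already balanced: only shuffled
  even <- synthetic_qsar(100, 3, active_fraction = 0.5, seed = 5)
  b2 <- balance(even, 0.3, seed = 1)
  expect_identical(nrow(b2$X), 100L)
  # max_repeats = 1 forbids duplication
  expect_warning(b3 <- balance(ds, 0.10, max_repeats = 1, seed = 2),
                 "max_repeats")
  expect_identical(nrow(b3$X), nrow(ds$X))
})

test_that("PCA matches the covariance eigendecomposition and keeps geometry", {
  ds <- synthetic_qsar(60, 5, seed = 12)
  pm <- pca_train(ds)
  ev <- eigen(cov(ds$X), symmetric = TRUE)
  expect_equal(pm$values, pmax(ev$values, 0), tolerance = 1e-9)
  expect_true(all(diff(pm$values) <= 1e-9))
  expect_equal(crossprod(pm$vectors), diag(5), tolerance = 1e-6)
  # fraction 1 keeps everything and preserves pairwise distances
  pa <- pca_apply(ds, pm, 1)
  expect_identical(ncol(pa$X), 5L)
  expect_equal(as.matrix(dist(pa$X)), as.matrix(dist(ds$X)), tolerance = 1e-5)
  # planar data at fraction 0.95 keeps exactly two components
  set.seed(3)
  basis <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:2]
  planar <- matrix(rnorm(200), 100, 2) %*% t(basis)
  dsp <- feature_dataset(sprintf("p%03d", 1:100), planar,
                         matrix(0, 100, 1))
  k <- ncol(pca_apply(dsp, pca_train(dsp), 0.95)$X)
  expect_identical(k, 2L)
  expect_error(pca_apply(ds, pm, 0), "fraction")
})

test_that("k-means recovers separated blobs; k = n returns the rows", {
  set.seed(6)
  n <- 80
  blob <- rbind(matrix(rnorm(2 * n, 0, 1), n, 2),
                matrix(rnorm(2 * n, 10, 1), n, 2))
  ds <- feature_dataset(sprintf("b%03d", seq_len(2 * n)), blob,
                        matrix(rep(0:1, each = n), ncol = 1))
  km <- kmeans_reduce(ds, 2, seed = 3)
  cents <- km$X[order(km$X[, 1]), ]
  expect_lt(max(abs(cents[1, ] - 0)), 3 / sqrt(n))
  expect_lt(max(abs(cents[2, ] - 10)), 3 / sqrt(n))
  # per-cluster mean results
  expect_equal(sort(as.numeric(km$Y)), c(0, 1))
  small <- ds_small <- feature_dataset(c("a", "b", "c"),
                                       matrix(c(0, 5, 9, 0, 5, 9), 3),
                                       matrix(1:3, ncol = 1))
  km3 <- kmeans_reduce(small, 3, seed = 1)
  expect_identical(sort(km3$X[, 1]), c(0, 5, 9))
})

test_that("summary statistics match hand computation on a 3-row dataset", {
  ds <- feature_dataset(c("a", "b", "c"),
                        matrix(c(1, 2, 3, 10, 20, 30), 3),
                        matrix(c(1, NA, 0), ncol = 1))
  s <- dataset_summary(ds)
  expect_identical(s$rows, 3L)
  expect_equal(s$feature_mean, c(2, 20))
  expect_equal(s$feature_sd, c(1, 10))
  expect_equal(s$result_density, 2 / 3)
})
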
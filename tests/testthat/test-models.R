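# Trainable models: dropout ANN, decision tree, SOM, linear regression,
# scaling, and the text serialization.

test_that("input scaling normalizes training data and passes constants", {
  set.seed(1)
  X <- cbind(rnorm(50, 5, 2), runif(50, -3, 7), rep(4, 50))
  av <- scaling_fit(X, "AveStd")
  Z <- scaling_apply(av, X)
  expect_equal(colMeans(Z), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(apply(Z, 2, sd)[1:2], c(1, 1), tolerance = 1e-12)
  mm <- scaling_fit(X, "MinMax")
  R <- scaling_apply(mm, X)
  expect_gte(min(R), 0); expect_lte(max(R), 1)
})

test_that("forward propagation satisfies the degenerate contracts", {
  # all-zero weights and biases with sigmoid hidden: output is the bias (0)
  # and the hidden activations are 0.5 everywhere
  m <- chemtk:::new_ann(
    weights = list(matrix(0, 4, 3), matrix(0, 1, 4)),
    biases = list(numeric(4), numeric(1)), transfer = "Sigmoid", leak = 0,
    dropout = c(0, 0), scaling = scaling_fit(matrix(0, 2, 3), "none"))
  fw <- ann_forward(m, matrix(rnorm(15), 5, 3))
  expect_true(all(fw$y[[2]] == 0.5))
  # p = 0 train mode equals test mode exactly
  set.seed(2)
  m$weights <- lapply(m$weights, function(w) matrix(rnorm(length(w)), nrow(w)))
  X <- matrix(rnorm(15), 5, 3)
  expect_identical(ann_forward(m, X, train_mode = TRUE)$output,
                   ann_forward(m, X, train_mode = FALSE)$output)
  # a single linear layer is a plain matrix multiply
  lin <- chemtk:::new_ann(weights = list(matrix(1:6 / 10, 2, 3)),
                          biases = list(c(1, -1)), transfer = "Sigmoid",
                          leak = 0, dropout = 0,
                          scaling = scaling_fit(matrix(0, 2, 3), "none"))
  expect_equal(ann_forward(lin, X)$output,
               sweep(X %*% t(lin$weights[[1]]), 2, c(1, -1), "+"))
})

test_that("analytic gradients match central differences on a 3-2-1 net", {
  set.seed(3)
  X <- matrix(rnorm(18), 6, 3)
  Y <- matrix(rnorm(6), 6, 1)
  for (transfer in c("Sigmoid", "Rectifier")) {
    m <- chemtk:::new_ann(
      weights = list(matrix(rnorm(6), 2, 3), matrix(rnorm(2), 1, 2)),
      biases = list(rnorm(2), rnorm(1)), transfer = transfer, leak = 0.05,
      dropout = c(0, 0), scaling = scaling_fit(X, "none"))
    g <- chemtk:::ann_gradient(m, X, Y)
    eps <- 1e-6
    worst <- 0
    for (l in 1:2) {
      for (i in seq_along(m$weights[[l]])) {
        mp <- m; mp$weights[[l]][i] <- mp$weights[[l]][i] + eps
        mn <- m; mn$weights[[l]][i] <- mn$weights[[l]][i] - eps
        num <- (chemtk:::ann_gradient(mp, X, Y)$loss -
                chemtk:::ann_gradient(mn, X, Y)$loss) / (2 * eps)
        worst <- max(worst, abs(g$dW[[l]][i] - num) /
                     max(1e-8, abs(g$dW[[l]][i]) + abs(num)))
      }
      for (i in seq_along(m$biases[[l]])) {
        mp <- m; mp$biases[[l]][i] <- mp$biases[[l]][i] + eps
        mn <- m; mn$biases[[l]][i] <- mn$biases[[l]][i] - eps
        num <- (chemtk:::ann_gradient(mp, X, Y)$loss -
                chemtk:::ann_gradient(mn, X, Y)$loss) / (2 * eps)
        worst <- max(worst, abs(g$db[[l]][i] - num) /
                     max(1e-8, abs(g$db[[l]][i]) + abs(num)))
      }
    }
    expect_lt(worst, 1e-5)
  }
})

test_that("dropout expectation matches the test-time weight scaling", {
  # on a linear network the average over masks equals test mode exactly in
  # expectation; Monte-Carlo over many masks approaches it
  set.seed(4)
  m <- chemtk:::new_ann(
    weights = list(matrix(rnorm(8), 2, 4)), biases = list(c(0, 0)),
    transfer = "Sigmoid", leak = 0, dropout = 0.3,
    scaling = scaling_fit(matrix(0, 2, 4), "none"))
  X <- matrix(rnorm(4), 1, 4)
  test_out <- ann_forward(m, X)$output
  mc <- replicate(4000, ann_forward(m, X, train_mode = TRUE)$output[1, 1])
  expect_lt(abs(mean(mc) - test_out[1, 1]), 4 * sd(mc) / sqrt(4000))
})

test_that("the network learns XOR and separable classes", {
  xor_ds <- feature_dataset(c("a", "b", "c", "d"),
                            rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
                            matrix(c(0, 1, 1, 0), ncol = 1))
  m <- ann_train(xor_ds, hidden = 8, eta = 0.5, alpha = 0.9, dropout = 0,
                 steps_per_update = 0, max_iterations = 3000,
                 objective = "RMSD", scaling = "none", seed = 2)
  expect_lt(mean((predict(m, xor_ds) - xor_ds$Y)^2), 0.05)
  sep <- randomize(synthetic_qsar(300, 5, seed = 11), 1)
  parts <- split_cv(sep, 5, 0)
  am <- ann_train(parts$train, parts$monitor, hidden = 16,
                  dropout = c(0.05, 0.1), steps_per_update = 20,
                  max_iterations = 25, seed = 3)
  sc <- auc(roc_curve(predict(am, parts$independent), parts$independent$Y))
  expect_gt(sc, 0.95)
})

test_that("training is deterministic given the seed", {
  ds <- synthetic_qsar(80, 4, seed = 6)
  m1 <- ann_train(ds, hidden = 6, max_iterations = 8, dropout = 0.1, seed = 9)
  m2 <- ann_train(ds, hidden = 6, max_iterations = 8, dropout = 0.1, seed = 9)
  expect_identical(m1$weights, m2$weights)
  s1 <- som_train(ds, map_dims = c(3, 3), max_iterations = 10, seed = 4)
  s2 <- som_train(ds, map_dims = c(3, 3), max_iterations = 10, seed = 4)
  expect_identical(s1$weights, s2$weights)
})

test_that("decision tree partitioners and scores pick the oracle split", {
  # information gain of a perfect split of balanced classes is 1 bit
  lab <- c(rep(1L, 4), rep(0L, 4))
  expect_equal(chemtk:::split_rating(lab, c(rep(FALSE, 4), rep(TRUE, 4)),
                                     "InformationGain"), 1)
  # pure-class input collapses to a single leaf
  pure <- feature_dataset(letters[1:4], matrix(rnorm(8), 4),
                          matrix(1, 4, 1))
  expect_length(dt_train(pure)$nodes, 1L)
  # root split matches an exhaustive search over (feature, threshold)
  set.seed(7)
  X <- matrix(rnorm(40), 20, 2)
  y <- as.numeric(X[, 1] + 0.3 * X[, 2] > 0)
  ds <- feature_dataset(sprintf("r%02d", 1:20), X, matrix(y, ncol = 1))
  for (part in c("InformationGain", "Gini")) {
    fit <- dt_train(ds, partitioner = part)
    root <- fit$nodes[[fit$root]]
    best <- list(r = -Inf)
    for (f in 1:2) {
      u <- sort(unique(X[, f]))
      for (t in (head(u, -1) + tail(u, -1)) / 2) {
        r <- chemtk:::split_rating(y, X[, f] < t, part)
        if (r > best$r + 1e-12) best <- list(r = r, f = f, t = t)
      }
    }
    expect_identical(root$feature, best$f)
    expect_equal(root$threshold, best$t)
  }
  # Sequence only splits with a pure child
  fitq <- dt_train(ds, partitioner = "Sequence")
  root <- fitq$nodes[[fitq$root]]
  lab_left <- y[X[, root$feature] < root$threshold]
  lab_right <- y[X[, root$feature] >= root$threshold]
  expect_true(length(unique(lab_left)) == 1L ||
              length(unique(lab_right)) == 1L)
  # training accuracy is perfect with distinct continuous features
  pr <- predict(dt_train(ds), ds)
  expect_identical(as.numeric(pr > 0.5), y)
})

test_that("tree logic export is equivalent to the thresholded prediction", {
  set.seed(8)
  X <- matrix(rnorm(60), 30, 2)
  y <- as.numeric(X[, 1] > 0.2 | X[, 2] < -0.5)
  fit <- dt_train(feature_dataset(sprintf("r%02d", 1:30), X,
                                  matrix(y, ncol = 1)))
  lg <- dt_to_logic(fit)
  # the root condition is printed first
  root <- fit$nodes[[fit$root]]
  expect_match(lg$text[1], sprintf("^if f%d <", root$feature - 1L))
  # evaluate the exported descriptor through MDL properties on 200 rows
  set.seed(9)
  Xt <- matrix(rnorm(400), 200, 2)
  for (i in seq_len(200)) {
    mol <- molecule("probe",
                    data.frame(element = "C", charge = 0L, x = 0, y = 0,
                               z = 0, aromatic = FALSE),
                    properties = list(f0 = format(Xt[i, 1], digits = 17),
                                      f1 = format(Xt[i, 2], digits = 17)))
    e <- evaluate_descriptor(lg$descriptor, mol)
    p <- as.numeric(predict(fit, Xt[i, , drop = FALSE])[1, 1] >= 0.5)
    expect_identical(e, p)
  }
  # single leaf exports a constant
  leafy <- dt_train(feature_dataset("a", matrix(0, 1, 1), matrix(1, 1, 1)))
  expect_match(dt_to_logic(leafy)$descriptor, "^Constant")
})

test_that("linear regression recovers exact coefficients and shrinks", {
  set.seed(10)
  X <- matrix(rnorm(300), 100, 3)
  y <- 2 * X[, 1] - 3 * X[, 2] + 1
  fit <- linreg_train(X, matrix(y, ncol = 1))
  expect_equal(as.numeric(fit$coefficients), c(1, 2, -3, 0), tolerance = 1e-8)
  # ridge shrinkage is monotone in lambda
  norms <- vapply(c(0, 1, 10, 100, 1e4), function(l)
    sum(linreg_train(X, matrix(y, ncol = 1), smoothing = l)$coefficients[-1]^2),
    numeric(1))
  expect_true(all(diff(norms) < 0))
  # matches the normal-equations oracle
  lam <- 2.5
  beta <- solve(crossprod(cbind(1, X)) + lam * diag(c(0, 1, 1, 1)),
                crossprod(cbind(1, X), y))
  fit2 <- linreg_train(X, matrix(y, ncol = 1), smoothing = lam)
  expect_equal(as.numeric(fit2$coefficients), as.numeric(beta),
               tolerance = 1e-9)
  # singular at lambda 0 advises smoothing
  Xs <- cbind(X, X[, 1])
  expect_error(linreg_train(Xs, matrix(y, ncol = 1)), "smoothing")
})

test_that("SOM radius schedule matches the formula endpoints", {
  expect_equal(som_radius(0, 7.5, 140), 7.5 * (1 - 1 / 560))
  expect_equal(som_radius(0, 7.5, 140), 7.48661, tolerance = 1e-5)
  expect_identical(som_radius(559, 7.5, 140), 0)
  expect_identical(som_radius(1000, 7.5, 140), 0)
})

test_that("radius-0 bubble SOM training is winner-only online k-means", {
  set.seed(11)
  X <- matrix(rnorm(40), 20, 2)
  ds <- feature_dataset(sprintf("x%02d", 1:20), X, matrix(0, 20, 1))
  m <- som_train(ds, map_dims = c(2, 1), radius = 0, length = 10,
                 kernel = "Bubble", steps_per_update = 1,
                 max_iterations = 3, scaling = "none", shuffle = FALSE,
                 seed = 13)
  # oracle: sequential winner updates with rate 0.8
  W <- chemtk:::with_seed(13, X[sample.int(20, 2), ])
  chemtk:::with_seed(13, {
    sample.int(20, 2)   # consume the initializer draw as the trainer does
    for (t in 1:3) {
      for (i in 1:20) {
        d <- rowSums((W - matrix(X[i, ], 2, 2, byrow = TRUE))^2)
        w <- which.min(d)
        W[w, ] <- W[w, ] + 0.8 * (X[i, ] - W[w, ])
      }
    }
  })
  expect_equal(m$weights, W, tolerance = 1e-12)
})

test_that("SOM nodes settle into separated clusters; AD scores calibrate", {
  set.seed(12)
  n <- 60
  X <- rbind(matrix(rnorm(2 * n, 0, 0.5), n, 2),
             matrix(rnorm(2 * n, 8, 0.5), n, 2))
  ds <- feature_dataset(sprintf("c%03d", 1:(2 * n)), X,
                        matrix(rep(0:1, each = n), ncol = 1))
  m <- som_train(ds, map_dims = c(2, 1), radius = 1, length = 20,
                 max_iterations = 60, scaling = "none", seed = 2)
  w <- m$weights[order(m$weights[, 1]), ]
  expect_lt(max(abs(w[1, ] - 0)), 1)
  expect_lt(max(abs(w[2, ] - 8)), 1)
  # applicability domain: far points score ~1; training scores ~uniform
  far <- matrix(80, 2, 2)
  expect_true(all(som_ad_score(m, far) >= 0.99))
  self_scores <- som_ad_score(m, X)
  expect_lt(suppressWarnings(ks.test(self_scores, "punif")$statistic), 0.15)
  # AD score is monotone in the closest-node distance
  probe <- rbind(c(0, 0), c(1, 1), c(2, 2), c(4, 4))
  sc <- som_ad_score(m, probe)
  expect_true(all(diff(sc) >= 0))
})

test_that("models save and load as text with bit-exact predictions", {
  ds <- synthetic_qsar(60, 4, seed = 14)
  dsr <- synthetic_qsar(60, 4, regression = TRUE, seed = 14)
  dir <- withr::local_tempdir()
  models <- list(
    ann_train(ds, hidden = 5, max_iterations = 4, seed = 1),
    dt_train(ds),
    linreg_train(dsr),
    som_train(ds, map_dims = c(2, 2), max_iterations = 5, seed = 2))
  for (i in seq_along(models)) model_save(models[[i]], dir, "model", i - 1L)
  expect_identical(list.files(dir),
                   sprintf("model%06d.model", 0:3))
  loaded <- model_load(dir)
  Xr <- matrix(rnorm(40), 10, 4)
  for (i in seq_along(models))
    expect_identical(predict(models[[i]], Xr), predict(loaded[[i]], Xr))
  # model files are plain text
  expect_match(readLines(file.path(dir, "model000000.model"), n = 1L),
               "NeuralNetwork")
  # corrupted type tag errors
  writeLines('{"type":"Mystery"}', file.path(dir, "model000009.model"))
  expect_error(model_load(dir), "type tag")
})
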
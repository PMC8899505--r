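# Kohonen self-organizing map with the decaying-radius neighborhood schedule
# and the applicability-domain score built on pooled training distances.
#
# Radius schedule:  radius(t) = radius0 * (1 - (t + 1) / (4 * length)),
# clamped at 0, so the radius reaches exactly 0 at t = 4*length - 1.
# Winner search (BMU): squared Euclidean distance d_j(x) = sum_i (x_i-w_ji)^2.
# Weight update: w <- w + alpha * beta * (x - w) with beta = 0.8 for the
# winning node and 0.2 for the other nodes inside the radius; alpha = 1 for
# the Bubble kernel and exp(-d^2 / (2 radius^2)) (d = grid distance to the
# winner) for the Gaussian kernel.

#' Neighborhood radius schedule
#'
#' @param t iteration index (0-based).
#' @param radius0 initial radius.
#' @param length schedule length parameter; the radius reaches 0 at
#'   `t = 4 * length - 1`.
#' @return radius at iteration `t` (never negative).
#' @export
som_radius <- function(t, radius0, length) {
  pmax(0, radius0 * (1 - (t + 1) / (4 * length)))
}

som_grid <- function(map_dims) {
  as.matrix(expand.grid(gx = seq_len(map_dims[1]) - 1L,
                        gy = seq_len(map_dims[2]) - 1L))
}

# index of best matching unit per row (squared Euclidean, first wins ties)
som_bmu <- function(weights, X) {
  d <- outer(rowSums(X^2), rep(1, nrow(weights))) - 2 * X %*% t(weights) +
    outer(rep(1, nrow(X)), rowSums(weights^2))
  max.col(-d, ties.method = "first")
}

#' Train a self-organizing map
#'
#' Nodes live on a rectangular grid (`map_dims`); weights are initialized from
#' randomly chosen training rows. Each iteration processes batches of
#' `steps_per_update` rows (0 = the full training set accumulated before a
#' single update). Within a batch every row selects its best matching unit;
#' nodes within the current radius of a winner (Euclidean grid distance,
#' non-toroidal) are pulled toward the row. Node results are per-node means of
#' the training results; training distances to the closest node are pooled for
#' applicability-domain scoring.
#'
#' @param train a `feature_dataset` or feature matrix.
#' @param Y results when `train` is a matrix.
#' @param map_dims grid dimensions, e.g. `c(10, 10)`.
#' @param radius initial neighborhood radius.
#' @param length schedule length (radius hits 0 at iteration `4*length - 1`).
#' @param kernel `"Bubble"` (constant rate inside the radius) or `"Gaussian"`.
#' @param steps_per_update batch size; 0 = full batch.
#' @param max_iterations training iterations.
#' @param scaling input scaling mode.
#' @param shuffle reshuffle row order per iteration.
#' @param seed RNG seed.
#' @return a `som_model`.
#' @export
som_train <- function(train, Y = NULL, map_dims = c(10L, 10L), radius = 7.5,
                      length = 140L, kernel = c("Bubble", "Gaussian"),
                      steps_per_update = 0L, max_iterations = length,
                      scaling = "AveStd", shuffle = TRUE, seed = 1L) {
  kernel <- match.arg(kernel)
  if (radius < 0) stop("radius must be non-negative")
  xy <- as_xy(train, Y)
  if (is.null(xy$Y)) xy$Y <- matrix(NA_real_, nrow(xy$X), 1L)
  sc <- scaling_fit(xy$X, scaling)
  X <- scaling_apply(sc, xy$X)
  n <- nrow(X)
  grid <- som_grid(map_dims)
  k <- nrow(grid)
  gd2 <- as.matrix(dist(grid))^2       # squared grid distances
  with_seed(seed, {
    W <- X[sample.int(n, k, replace = k > n), , drop = FALSE]
    bs <- if (steps_per_update <= 0L) n else min(steps_per_update, n)
    for (t in seq_len(max_iterations) - 1L) {
      r <- som_radius(t, radius, length)
      ord <- if (shuffle) sample.int(n) else seq_len(n)
      for (start in seq(1L, n, by = bs)) {
        rows <- ord[start:min(start + bs - 1L, n)]
        bmu <- som_bmu(W, X[rows, , drop = FALSE])
        # accumulate batch updates, then apply once
        delta <- W * 0
        cnt <- numeric(k)
        for (m in seq_along(rows)) {
          x <- X[rows[m], ]
          win <- bmu[m]
          nbr <- which(gd2[win, ] <= r^2)
          beta <- ifelse(nbr == win, 0.8, 0.2)
          a <- if (kernel == "Bubble" || r == 0) rep(1, length(nbr))
               else exp(-gd2[win, nbr] / (2 * r^2))
          delta[nbr, ] <- delta[nbr, ] +
            (a * beta) * sweep(-W[nbr, , drop = FALSE], 2, x, "+")
          cnt[nbr] <- cnt[nbr] + 1
        }
        upd <- cnt > 0
        W[upd, ] <- W[upd, , drop = FALSE] +
          delta[upd, , drop = FALSE] / cnt[upd]
      }
    }
    bmu <- som_bmu(W, X)
    node_results <- do.call(rbind, lapply(seq_len(k), function(j) {
      rows <- which(bmu == j)
      if (!length(rows)) rep(NA_real_, ncol(xy$Y))
      else colMeans(xy$Y[rows, , drop = FALSE], na.rm = TRUE)
    }))
    dmin <- sqrt(vapply(seq_len(n), function(i)
      sum((X[i, ] - W[bmu[i], ])^2), numeric(1)))
    structure(list(type = "Kohonen", map_dims = map_dims, weights = W,
                   grid = grid, node_results = node_results,
                   train_distances = sort(dmin),
                   config = list(radius = radius, length = length,
                                 kernel = kernel,
                                 steps_per_update = steps_per_update,
                                 max_iterations = max_iterations, seed = seed),
                   scaling = sc),
              class = c("som_model", "chemtk_model"))
  })
}

#' @export
predict.som_model <- function(object, newdata, ...) {
  X <- scaling_apply(object$scaling, as_xy(newdata)$X)
  bmu <- som_bmu(object$weights, X)
  object$node_results[bmu, , drop = FALSE]
}

#' Applicability-domain score
#'
#' The normalized distance of a compound to the closest map node: the
#' fraction of training rows whose own closest-node distance is strictly
#' smaller (all nodes share one pooled distance distribution). A score of
#' 0.90 means the compound is farther from the closest node than 90% of the
#' training set.
#'
#' @param model a trained `som_model`.
#' @param X feature matrix (unscaled; the model's scaling is applied).
#' @return numeric scores in `[0, 1]`, one per row.
#' @export
som_ad_score <- function(model, X) {
  Xs <- scaling_apply(model$scaling, as_xy(X)$X)
  bmu <- som_bmu(model$weights, Xs)
  d <- sqrt(vapply(seq_len(nrow(Xs)), function(i)
    sum((Xs[i, ] - model$weights[bmu[i], ])^2), numeric(1)))
  td <- model$train_distances
  vapply(d, function(x) mean(td < x), numeric(1))
}
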
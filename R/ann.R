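# Feed-forward neural network with dropout, trained by backpropagation with
# momentum on a mean-squared-error loss. Forward propagation through layers
# l = 0..L-1:  z(l+1) = w(l+1) y(l) + b(l+1),  y(l+1) = f(z(l+1)).
# During training each layer's outputs are multiplied by a Bernoulli dropout
# mask r (reshuffled every batch); at test time the corresponding weights are
# scaled down by 1 - p instead. The output layer is linear.

transfer_fun <- function(name, leak = 0) {
  switch(name,
    Sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                   df = function(z, y) y * (1 - y)),
    Rectifier = list(f = function(z) ifelse(z > 0, z, leak * z),
                     # y and z share their sign for leak >= 0
                     df = function(z, y) ifelse(y > 0, 1, leak)),
    Linear = list(f = identity, df = function(z, y) 1),
    stop("unknown transfer function: ", name))
}

new_ann <- function(weights, biases, transfer, leak, dropout, scaling) {
  structure(list(type = "NeuralNetwork", weights = weights, biases = biases,
                 transfer = transfer, leak = leak, dropout = dropout,
                 scaling = scaling),
            class = c("ann_model", "chemtk_model"))
}

#' Forward propagation
#'
#' @param model an `ann_model`.
#' @param X input matrix (already scaled; `predict()` handles scaling).
#' @param train_mode apply dropout masks instead of the test-time `1 - p`
#'   weight scaling.
#' @param masks optional list of 0/1 mask vectors (input layer first); drawn
#'   from the current RNG when omitted in train mode.
#' @return list with `output` and per-layer activations `y` (input first).
#' @export
ann_forward <- function(model, X, train_mode = FALSE, masks = NULL) {
  X <- as.matrix(X)
  L <- length(model$weights)
  tf <- transfer_fun(model$transfer, model$leak)
  p <- model$dropout
  if (train_mode && is.null(masks)) {
    masks <- lapply(seq_len(L), function(l) {
      nl <- ncol(model$weights[[l]])
      if (l <= length(p) && p[l] > 0) as.numeric(runif(nl) >= p[l])
      else rep(1, nl)
    })
  }
  ys <- vector("list", L + 1L)
  ys[[1]] <- X
  a <- X
  for (l in seq_len(L)) {
    if (train_mode) {
      a <- sweep(a, 2, masks[[l]], "*")
    } else if (l <= length(p) && p[l] > 0) {
      a <- a * (1 - p[l])
    }
    z <- sweep(a %*% t(model$weights[[l]]), 2, model$biases[[l]], "+")
    a <- if (l < L) tf$f(z) else z    # linear output layer
    ys[[l + 1L]] <- a
  }
  list(output = a, y = ys, masks = if (train_mode) masks)
}

#' @export
predict.ann_model <- function(object, newdata, ...) {
  X <- scaling_apply(object$scaling, as_xy(newdata)$X)
  ann_forward(object, X, train_mode = FALSE)$output
}

# Analytic gradient of the MSE loss (mean over defined result entries) with
# respect to every weight and bias, under the given dropout masks.
ann_gradient <- function(model, X, Y, masks = NULL, train_mode = !is.null(masks)) {
  fw <- ann_forward(model, X, train_mode = train_mode, masks = masks)
  masks <- fw$masks
  L <- length(model$weights)
  tf <- transfer_fun(model$transfer, model$leak)
  p <- model$dropout
  Y <- as.matrix(Y)
  resid <- fw$output - Y
  wts <- !is.na(resid)
  resid[!wts] <- 0
  n_def <- max(1L, sum(wts))
  delta <- 2 * resid / n_def           # linear output layer
  dW <- vector("list", L); db <- vector("list", L)
  for (l in seq.int(L, 1L)) {
    a_in <- fw$y[[l]]
    if (train_mode) a_in <- sweep(a_in, 2, masks[[l]], "*")
    else if (l <= length(p) && p[l] > 0) a_in <- a_in * (1 - p[l])
    dW[[l]] <- t(delta) %*% a_in
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      back <- delta %*% model$weights[[l]]
      if (train_mode) back <- sweep(back, 2, masks[[l]], "*")
      else if (l <= length(p) && p[l] > 0) back <- back * (1 - p[l])
      yprev <- fw$y[[l]]
      delta <- back * tf$df(NULL, yprev)
    }
  }
  list(dW = dW, db = db, loss = sum(resid^2) / n_def)
}

#' Train a neural network
#'
#' Mean-squared-error loss, backpropagation with classical momentum
#' (`delta_w(t) = -eta grad + alpha delta_w(t-1)`), mini-batches of
#' `steps_per_update` rows (0 = full batch), dropout masks reshuffled each
#' batch, and missing result entries contributing zero gradient. The returned
#' model is the one from the best monitor-score iteration.
#'
#' @param train training `feature_dataset`.
#' @param monitor monitoring `feature_dataset` (scored once per iteration);
#'   defaults to the training set.
#' @param hidden integer vector of hidden layer sizes.
#' @param transfer `"Sigmoid"` or `"Rectifier"` (hidden layers; output linear).
#' @param leak leak slope for the rectifier.
#' @param alpha momentum coefficient.
#' @param eta learning rate.
#' @param dropout per-layer dropout probabilities, input layer first (padded
#'   with zeros).
#' @param steps_per_update batch size; 0 uses the full training set.
#' @param shuffle reshuffle row order each iteration.
#' @param balance oversample the minor class (see [balance()]) before
#'   training.
#' @param balance_ratio,balance_max_repeats balancing parameters.
#' @param max_iterations training epochs.
#' @param objective objective-function spec string or function scoring the
#'   monitor set (default `AUC`; higher is better unless the objective says
#'   otherwise).
#' @param scaling input scaling mode.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return an `ann_model`; attribute `"monitor_scores"` carries the
#'   per-iteration scores.
#' @export
ann_train <- function(train, monitor = train, hidden = 32L,
                      transfer = "Sigmoid", leak = 0.05, alpha = 0.5,
                      eta = 0.05, dropout = 0, steps_per_update = 1L,
                      shuffle = TRUE, balance = FALSE, balance_ratio = 0.1,
                      balance_max_repeats = Inf, max_iterations = 20L,
                      objective = "AUC", scaling = "AveStd", seed = 1L) {
  stopifnot(inherits(train, "feature_dataset"))
  if (balance) train <- balance(train, balance_ratio, balance_max_repeats,
                                seed = seed)
  obj <- if (is.function(objective)) objective else objective_function(objective)
  maximize <- isTRUE(attr(obj, "maximize")) || is.null(attr(obj, "maximize"))
  sc <- scaling_fit(train$X, scaling)
  X <- scaling_apply(sc, train$X)
  Y <- train$Y
  Xm <- scaling_apply(sc, monitor$X)
  sizes <- c(ncol(X), hidden, ncol(Y))
  L <- length(sizes) - 1L
  p <- rep(0, L)
  p[seq_along(dropout)] <- dropout
  with_seed(seed, {
    weights <- lapply(seq_len(L), function(l)
      matrix(runif(sizes[l + 1L] * sizes[l], -0.5, 0.5) / sqrt(sizes[l]),
             sizes[l + 1L], sizes[l]))
    biases <- lapply(seq_len(L), function(l) numeric(sizes[l + 1L]))
    model <- new_ann(weights, biases, transfer, leak, p, sc)
    vW <- lapply(weights, function(w) w * 0)
    vb <- lapply(biases, function(b) b * 0)
    n <- nrow(X)
    bs <- if (steps_per_update <= 0L) n else min(steps_per_update, n)
    best <- -Inf
    best_model <- model
    scores <- numeric(max_iterations)
    for (it in seq_len(max_iterations)) {
      ord <- if (shuffle) sample.int(n) else seq_len(n)
      for (start in seq(1L, n, by = bs)) {
        rows <- ord[start:min(start + bs - 1L, n)]
        g <- ann_gradient(model, X[rows, , drop = FALSE],
                          Y[rows, , drop = FALSE],
                          masks = NULL, train_mode = any(p > 0))
        if (!is.finite(g$loss))
          stop("non-finite training loss at iteration ", it)
        for (l in seq_len(L)) {
          vW[[l]] <- alpha * vW[[l]] - eta * g$dW[[l]]
          vb[[l]] <- alpha * vb[[l]] - eta * g$db[[l]]
          model$weights[[l]] <- model$weights[[l]] + vW[[l]]
          model$biases[[l]] <- model$biases[[l]] + vb[[l]]
        }
      }
      pred <- ann_forward(model, Xm)$output
      # a degenerate monitor chunk (e.g. single-class under AUC) cannot rank
      # models; training continues and the latest model is kept
      s <- tryCatch(obj(pred, monitor$Y), error = function(e) NA_real_)
      scores[it] <- s
      if (is.na(s)) { best_model <- model; next }
      if ((maximize && s >= best) || (!maximize && -s >= best)) {
        best <- if (maximize) s else -s
        best_model <- model
      }
    }
    structure(best_model, monitor_scores = scores)
  })
}
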
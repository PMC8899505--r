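# Model layer shared machinery: input scaling, linear regression, and the
# text (JSON) model serialization used by every trainable model type.

#' Fit and apply input scaling
#'
#' `AveStd` centers to mean 0 / SD 1 (constant columns pass through with SD
#' treated as 1); `MinMax` maps the training range onto `[0, 1]`; `none`
#' leaves features untouched.
#'
#' @param X numeric training matrix.
#' @param mode `"AveStd"`, `"MinMax"`, or `"none"`.
#' @param spec a `scaling_spec` from `scaling_fit()`.
#' @return `scaling_fit()` returns a `scaling_spec`; `scaling_apply()` the
#'   transformed matrix.
#' @export
scaling_fit <- function(X, mode = c("AveStd", "MinMax", "none")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  spec <- switch(mode,
    AveStd = {
      s <- apply(X, 2, stats::sd)
      s[!is.finite(s) | s == 0] <- 1
      list(mode = mode, center = colMeans(X), scale = s)
    },
    MinMax = {
      lo <- apply(X, 2, min); hi <- apply(X, 2, max)
      rg <- hi - lo
      rg[rg == 0] <- 1
      list(mode = mode, center = lo, scale = rg)
    },
    none = list(mode = mode, center = rep(0, ncol(X)),
                scale = rep(1, ncol(X))))
  structure(spec, class = "scaling_spec")
}

#' @rdname scaling_fit
#' @export
scaling_apply <- function(spec, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, spec$center), 2, spec$scale, "/")
}

# pull (X, Y) out of a feature_dataset or pass matrices through
as_xy <- function(data, Y = NULL) {
  if (inherits(data, "feature_dataset")) list(X = data$X, Y = data$Y)
  else list(X = as.matrix(data), Y = if (!is.null(Y)) as.matrix(Y))
}

# ---- linear regression ------------------------------------------------------

#' Ridge-smoothed linear regression
#'
#' Solves `(X'X + lambda I) beta = X'Y` by Cholesky factorization (the
#' intercept is not penalized). With `smoothing = 0` a singular system is an
#' error advising a positive smoothing value.
#'
#' @param train a `feature_dataset` (or feature matrix).
#' @param Y result matrix when `train` is a plain matrix.
#' @param smoothing ridge penalty `lambda >= 0`.
#' @param scaling input scaling mode.
#' @return a `linreg_model` with `coefficients` (one column per result,
#'   intercept first).
#' @export
linreg_train <- function(train, Y = NULL, smoothing = 0, scaling = "none") {
  xy <- as_xy(train, Y)
  sc <- scaling_fit(xy$X, scaling)
  X <- cbind(1, scaling_apply(sc, xy$X))
  P <- diag(c(0, rep(1, ncol(X) - 1L)))
  A <- crossprod(X) + smoothing * P
  R <- tryCatch(chol(A), error = function(e)
    stop("singular normal equations; use smoothing > 0"))
  beta <- backsolve(R, backsolve(R, crossprod(X, xy$Y), transpose = TRUE))
  structure(list(type = "LinearRegression", coefficients = beta,
                 smoothing = smoothing, scaling = sc),
            class = c("linreg_model", "chemtk_model"))
}

#' Predict from a trained model
#'
#' @param object a trained model.
#' @param newdata feature matrix or `feature_dataset`.
#' @param ... unused.
#' @return numeric prediction matrix (rows match `newdata`).
#' @export
predict.linreg_model <- function(object, newdata, ...) {
  X <- as_xy(newdata)$X
  cbind(1, scaling_apply(object$scaling, X)) %*% object$coefficients
}

# ---- serialization ----------------------------------------------------------

ser_matrix <- function(m) list(dim = dim(m), values = as.numeric(m))
deser_matrix <- function(s) matrix(as.numeric(s$values), s$dim[1], s$dim[2])

model_to_list <- function(model) {
  UseMethod("model_to_list")
}

#' @export
model_to_list.linreg_model <- function(model) {
  list(type = "LinearRegression",
       coefficients = ser_matrix(model$coefficients),
       smoothing = model$smoothing, scaling = unclass(model$scaling))
}

#' @export
model_to_list.ann_model <- function(model) {
  list(type = "NeuralNetwork",
       weights = lapply(model$weights, ser_matrix),
       biases = model$biases,
       transfer = model$transfer, leak = model$leak,
       dropout = model$dropout, scaling = unclass(model$scaling))
}

#' @export
model_to_list.dtree_model <- function(model) {
  list(type = "DecisionTree", nodes = model$nodes,
       config = model$config, scaling = unclass(model$scaling))
}

#' @export
model_to_list.som_model <- function(model) {
  list(type = "Kohonen", map_dims = model$map_dims,
       weights = ser_matrix(model$weights),
       grid = ser_matrix(model$grid),
       node_results = ser_matrix(model$node_results),
       train_distances = model$train_distances,
       config = model$config, scaling = unclass(model$scaling))
}

model_from_list <- function(s) {
  sc <- structure(list(mode = s$scaling$mode,
                       center = as.numeric(s$scaling$center),
                       scale = as.numeric(s$scaling$scale)),
                  class = "scaling_spec")
  switch(s$type,
    LinearRegression = structure(
      list(type = s$type, coefficients = deser_matrix(s$coefficients),
           smoothing = s$smoothing, scaling = sc),
      class = c("linreg_model", "chemtk_model")),
    NeuralNetwork = structure(
      list(type = s$type, weights = lapply(s$weights, deser_matrix),
           biases = lapply(s$biases, as.numeric),
           transfer = s$transfer, leak = s$leak,
           dropout = as.numeric(s$dropout), scaling = sc),
      class = c("ann_model", "chemtk_model")),
    DecisionTree = structure(
      list(type = s$type, nodes = s$nodes, config = s$config, scaling = sc),
      class = c("dtree_model", "chemtk_model")),
    Kohonen = structure(
      list(type = s$type, map_dims = as.numeric(s$map_dims),
           weights = deser_matrix(s$weights), grid = deser_matrix(s$grid),
           node_results = deser_matrix(s$node_results),
           train_distances = as.numeric(s$train_distances),
           config = s$config, scaling = sc),
      class = c("som_model", "chemtk_model")),
    stop("unknown model type tag: ", s$type))
}

#' Save and load models as self-describing text files
#'
#' Models are written as JSON (full double precision) under
#' `<directory>/<prefix>NNNNNN.model`; `model_load()` returns every indexed
#' model sorted by index. A load/save round trip reproduces predictions
#' bit-exactly.
#'
#' @param model a trained model.
#' @param directory storage directory (created if missing).
#' @param prefix file name prefix.
#' @param index model index within the storage.
#' @return `model_save()` the path, invisibly; `model_load()` a list of
#'   models.
#' @export
model_save <- function(model, directory, prefix = "model", index = 0L) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(directory, sprintf("%s%06d.model", prefix, index))
  json <- jsonlite::toJSON(model_to_list(model), digits = I(17),
                           auto_unbox = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname model_save
#' @export
model_load <- function(directory, prefix = "model") {
  files <- sort(list.files(directory,
                           pattern = paste0("^", prefix, "[0-9]{6}\\.model$"),
                           full.names = TRUE))
  if (!length(files)) stop("no model files with prefix ", sQuote(prefix),
                           " in ", directory)
  lapply(files, function(f) {
    s <- jsonlite::fromJSON(readLines(f, warn = FALSE),
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE,
                            simplifyVector = TRUE)
    model_from_list(s)
  })
}
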
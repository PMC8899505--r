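# Cross-validation driver: chunk-based train/monitor/independent splits, the
# learning-method specification grammar, per-fold training with prediction
# merging, model testing, and the prediction-backed descriptor properties.

#' Split a dataset into train / monitor / independent partitions
#'
#' The rows are divided into `n_folds` contiguous chunks; chunk `fold` serves
#' as both the monitoring and the independent set, the remaining chunks as the
#' training set. Randomize the dataset first (the independents then partition
#' it across folds).
#'
#' @param ds a `feature_dataset`.
#' @param n_folds number of folds (at least 2).
#' @param fold 0-based fold index.
#' @return list with `train`, `monitor`, `independent` datasets.
#' @export
split_cv <- function(ds, n_folds, fold) {
  stopifnot(n_folds >= 2L)
  if (fold < 0L || fold >= n_folds) stop("fold out of range 0..", n_folds - 1L)
  list(train = chunks(ds, n_folds, setdiff(seq_len(n_folds) - 1L, fold)),
       monitor = chunks(ds, n_folds, fold),
       independent = chunks(ds, n_folds, fold))
}

# ---- learning-method grammar -------------------------------------------------

kw_value <- function(node, key, default = NULL) {
  kw <- get_kwarg(node, key)
  if (is.null(kw)) return(default)
  switch(kw$kind,
    constant = kw$value,
    name = kw$name,
    call = if (kw$name == "Constant") as.numeric(
      vapply(kw$args, `[[`, numeric(1), "value")) else format(kw),
    format(kw))
}

kw_logical <- function(node, key, default) {
  v <- kw_value(node, key, NULL)
  if (is.null(v)) return(default)
  if (is.numeric(v)) return(v != 0)
  tolower(as.character(v)) %in% c("true", "t", "1", "yes")
}

# positional numeric arguments of a nested call kwarg, e.g. dropout (0.05, 0.25)
kw_numbers <- function(node, key, default) {
  kw <- get_kwarg(node, key)
  if (is.null(kw)) {
    # also accept the bare-call form "dropout (0.05, 0.25)" parsed as args
    hits <- Filter(function(a) a$kind == "call" &&
                     normalize_key(a$name) == normalize_key(key), node$args)
    if (!length(hits)) return(default)
    kw <- hits[[1]]
  }
  if (kw$kind == "constant") return(kw$value)
  if (kw$kind == "call")
    return(as.numeric(vapply(kw$args, `[[`, numeric(1), "value")))
  default
}

#' Train a model from a learning-method specification
#'
#' Dispatches on the specification string used in training configurations:
#' `NeuralNetwork(...)`, `DecisionTree(...)`, `Kohonen(...)` /
#' `ApplicabilityDomainKohonen(...)`, `LinearRegression(...)`.
#'
#' @param spec learning-method text (or parsed node).
#' @param train,monitor training and monitoring `feature_dataset`s.
#' @param max_iterations training iterations.
#' @param seed RNG seed.
#' @return a trained model.
#' @export
train_model <- function(spec, train, monitor = train, max_iterations = 20L,
                        seed = 1L) {
  node <- if (is.character(spec)) parse_descriptor(spec) else spec
  if (node$kind == "name") node <- list(kind = "call", name = node$name,
                                        args = list(), kwargs = list())
  switch(node$name,
    NeuralNetwork = {
      wu <- get_kwarg(node, "weightupdate")
      alpha <- 0.5; eta <- 0.05
      if (!is.null(wu) && wu$kind == "call") {
        alpha <- kw_value(wu, "alpha", alpha)
        eta <- kw_value(wu, "eta", eta)
      }
      tf <- get_kwarg(node, "transferfunction")
      leak <- 0.05
      transfer <- "Sigmoid"
      if (!is.null(tf)) {
        if (tf$kind == "call") {
          transfer <- tf$name
          if (length(tf$args)) leak <- tf$args[[1]]$value
        } else transfer <- tf$name
      }
      arch <- kw_numbers(node, "hiddenarchitecture", 32)
      ann_train(train, monitor,
                hidden = as.integer(arch), transfer = transfer, leak = leak,
                alpha = alpha, eta = eta,
                dropout = kw_numbers(node, "dropout", 0),
                steps_per_update = as.integer(kw_value(node, "stepsperupdate", 1)),
                shuffle = kw_logical(node, "shuffle", TRUE),
                balance = kw_logical(node, "balance", FALSE),
                balance_ratio = kw_value(node, "balancetargetratio", 0.1),
                balance_max_repeats = kw_value(node, "balancemaxrepeats", Inf),
                max_iterations = max_iterations,
                objective = kw_value(node, "objectivefunction", "AUC"),
                scaling = kw_value(node, "scaling", "AveStd"),
                seed = seed)
    },
    DecisionTree = dt_train(
      train,
      partitioner = kw_value(node, "partitioner", "InformationGain"),
      node_score = kw_value(node, "nodescore", "SplitRating"),
      activity_cutoff = kw_value(node, "activitycutoff", 0.5),
      min_split = as.integer(kw_value(node, "minsplit", 0))),
    LinearRegression = {
      solver <- get_kwarg(node, "solver")
      smoothing <- 0
      if (!is.null(solver) && solver$kind == "call")
        smoothing <- kw_value(solver, "smoothing", 0)
      linreg_train(train, smoothing = smoothing)
    },
    Kohonen = ,
    ApplicabilityDomainKohonen = som_train(
      train,
      map_dims = as.integer(kw_numbers(node, "mapdimensions", c(10, 10))),
      radius = kw_value(node, "radius", 7.5),
      length = kw_value(node, "length", 140),
      kernel = kw_value(node, "neighborkernel", "Bubble"),
      steps_per_update = as.integer(kw_value(node, "stepsperupdate", 0)),
      max_iterations = max_iterations,
      scaling = kw_value(node, "scaling", "AveStd"),
      shuffle = kw_logical(node, "shuffle", TRUE),
      seed = seed),
    stop("unknown learning method: ", node$name))
}

# ---- cross-validation driver -------------------------------------------------

#' Run seeded cross-validation
#'
#' Trains one model per fold (chunk `f` held out as monitor + independent
#' set), stores the models under `storage`, pools the per-fold independent
#' predictions, fits a localPPV calibration on the pooled predictions, and
#' reports per-fold and pooled final-objective scores.
#'
#' @param ds a (randomized) `feature_dataset`.
#' @param learning_method learning-method specification string.
#' @param n_folds number of folds.
#' @param final_objective objective-function specification used for reporting.
#' @param storage_dir directory for `model000000...` files (optional).
#' @param prefix model file prefix.
#' @param max_iterations training iterations per fold.
#' @param seed base RNG seed (fold f trains with `seed + f`).
#' @param calibrate fit a localPPV calibration on the pooled predictions and
#'   store it beside the models.
#' @return list with `models`, `predictions` (pooled independent predictions:
#'   id, per-result prediction and actual), `fold_scores`, `pooled_score`.
#' @export
run_cv <- function(ds, learning_method, n_folds = 5L,
                   final_objective = "AUC", storage_dir = NULL,
                   prefix = "model", max_iterations = 20L, seed = 1L,
                   calibrate = FALSE) {
  obj <- objective_function(final_objective)
  models <- vector("list", n_folds)
  preds <- vector("list", n_folds)
  fold_scores <- numeric(n_folds)
  for (f in seq_len(n_folds) - 1L) {
    parts <- split_cv(ds, n_folds, f)
    model <- train_model(learning_method, parts$train, parts$monitor,
                         max_iterations = max_iterations, seed = seed + f)
    models[[f + 1L]] <- model
    ind <- parts$independent
    p <- predict(model, ind)
    preds[[f + 1L]] <- prediction_frame(ind$ids, p, ind$Y)
    # a degenerate fold (e.g. single-class under AUC) scores NA; the pooled
    # score over all independents is still defined
    fold_scores[f + 1L] <- tryCatch(obj(p, ind$Y),
                                    error = function(e) NA_real_)
    if (!is.null(storage_dir)) model_save(model, storage_dir, prefix, f)
  }
  pooled <- prediction_merge(preds)
  pooled_score <- obj(as.matrix(pooled[grep("^pred", names(pooled))]),
                      as.matrix(pooled[grep("^actual", names(pooled))]))
  calib <- NULL
  if (calibrate) {
    calib <- local_ppv_fit(pooled$pred1, pooled$actual1)
    if (!is.null(storage_dir))
      saveRDS_text(calib, file.path(storage_dir,
                                    paste0(prefix, ".calibration")))
  }
  list(models = models, predictions = pooled, fold_scores = fold_scores,
       pooled_score = pooled_score, calibration = calib)
}

# calibration curves are stored as JSON text next to the models
saveRDS_text <- function(obj, path) {
  writeLines(jsonlite::toJSON(unclass(obj), digits = I(17), auto_unbox = TRUE),
             path)
}

read_calibration <- function(path) {
  s <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  structure(list(x = as.numeric(s$x), ppv = as.numeric(s$ppv),
                 parity = s$parity),
            class = "calibration_curve")
}

prediction_frame <- function(ids, pred, actual) {
  pred <- as.matrix(pred); actual <- as.matrix(actual)
  out <- data.frame(id = trimws(ids), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pred))) out[[paste0("pred", j)]] <- pred[, j]
  for (j in seq_len(ncol(actual))) out[[paste0("actual", j)]] <- actual[, j]
  out
}

#' Merge prediction sets
#'
#' Rows with identical ids are averaged (prediction and actual columns
#' alike); disjoint ids are concatenated. Output rows are ordered by first
#' appearance.
#'
#' @param prediction_sets list of prediction data frames (`id`, `pred*`,
#'   `actual*` columns), as produced by [run_cv()] or [model_test()].
#' @return merged prediction data frame.
#' @export
prediction_merge <- function(prediction_sets) {
  all <- do.call(rbind, prediction_sets)
  arity <- unique(vapply(prediction_sets, ncol, integer(1)))
  if (length(arity) != 1L) stop("prediction sets differ in result arity")
  ids <- unique(all$id)
  agg <- aggregate(all[-1], by = list(id = all$id), FUN = mean)
  agg[match(ids, agg$id), , drop = FALSE]
}

#' Apply stored models to a dataset
#'
#' @param models list of trained models (or a storage directory path).
#' @param ds a `feature_dataset`.
#' @param average return the row-wise mean across models instead of per-model
#'   predictions.
#' @return with `average`, a prediction data frame; otherwise a list of
#'   per-model prediction data frames.
#' @export
model_test <- function(models, ds, average = TRUE) {
  if (is.character(models)) models <- model_load(models)
  preds <- lapply(seq_along(models), function(i) {
    p <- tryCatch(predict(models[[i]], ds), error = function(e)
      stop("model ", i, ": ", conditionMessage(e)))
    prediction_frame(ds$ids, p, ds$Y)
  })
  if (!average) return(preds)
  out <- preds[[1]]
  pc <- grep("^pred", names(out))
  for (p in preds[-1]) out[pc] <- out[pc] + p[pc]
  out[pc] <- out[pc] / length(preds)
  out
}

# ---- prediction-backed descriptor properties ---------------------------------

# Handles PredictionMean(storage = File(directory = ..., prefix = ...)) and
# PredictionInfo(predictor = File(...), metrics(LocalPPV)) inside descriptor
# evaluation. Features are generated from the feature spec stored beside the
# models (<prefix>.features).
eval_prediction <- function(node, mol, ctx, metric) {
  storage <- get_kwarg(node, "storage") %||% get_kwarg(node, "predictor")
  if (is.null(storage) || storage$kind != "call")
    stop(node$name, " requires storage = File(directory = ..., prefix = ...)")
  dir <- as.character(kw_value(storage, "directory"))
  prefix <- as.character(kw_value(storage, "prefix", "model"))
  feat_file <- file.path(dir, paste0(prefix, ".features"))
  if (!file.exists(feat_file))
    stop("no feature specification stored at ", feat_file)
  fspec <- parse_descriptor(paste(readLines(feat_file, warn = FALSE),
                                  collapse = " "))
  x <- matrix(evaluate_descriptor(fspec, mol), nrow = 1L)
  models <- model_load(dir, prefix)
  mean_pred <- mean(vapply(models, function(m) predict(m, x)[1, 1], numeric(1)))
  if (is.null(metric)) {
    metric <- "LocalPPV"
    hits <- Filter(function(a) a$kind == "call" &&
                     normalize_key(a$name) == "metrics", node$args)
    if (length(hits) && length(hits[[1]]$args))
      metric <- hits[[1]]$args[[1]]$name
  }
  if (metric == "Mean") return(mean_pred)
  if (metric == "LocalPPV") {
    cal_file <- file.path(dir, paste0(prefix, ".calibration"))
    if (!file.exists(cal_file))
      stop("no calibration stored at ", cal_file,
           "; run run_cv(..., calibrate = TRUE) first")
    curve <- read_calibration(cal_file)
    return(local_ppv_eval(curve, mean_pred))
  }
  stop("unknown prediction metric: ", metric)
}

#' Store a feature specification beside models
#'
#' Lets `PredictionMean` / `PredictionInfo` descriptor properties regenerate
#' the model inputs from a molecule.
#'
#' @param feature_spec descriptor text used to train the models.
#' @param directory,prefix model storage location.
#' @return the path, invisibly.
#' @export
store_feature_spec <- function(feature_spec, directory, prefix = "model") {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(directory, paste0(prefix, ".features"))
  writeLines(feature_spec, path)
  invisible(path)
}
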
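# Decision tree classifier with the four split partitioners (InformationGain,
# Gini, ROC, Sequence) and four node scores, plus export of a trained tree to
# readable if/else logic and an equivalent descriptor expression.

entropy2 <- function(pos, n) {
  if (n == 0L) return(0)
  p <- pos / n
  h <- 0
  if (p > 0) h <- h - p * log2(p)
  if (p < 1) h <- h - (1 - p) * log2(1 - p)
  h
}

gini_imp <- function(pos, n) {
  if (n == 0L) return(0)
  p <- pos / n
  2 * p * (1 - p)
}

# rating of a candidate split under a partitioner; labels are 0/1
split_rating <- function(labels, left, partitioner) {
  n <- length(labels); pos <- sum(labels)
  nl <- sum(left); nr <- n - nl
  posl <- sum(labels[left]); posr <- pos - posl
  switch(partitioner,
    InformationGain =
      entropy2(pos, n) - (nl / n) * entropy2(posl, nl) -
        (nr / n) * entropy2(posr, nr),
    Gini =
      gini_imp(pos, n) - (nl / n) * gini_imp(posl, nl) -
        (nr / n) * gini_imp(posr, nr),
    ROC = {
      # local AUC of the binary predictor "row goes right": (sens + spec)/2,
      # oriented so the rating never falls below chance
      if (pos == 0L || pos == n) 0.5
      else {
        sens <- posr / pos
        spec <- (nl - posl) / (n - pos)
        max((sens + spec) / 2, 1 - (sens + spec) / 2)
      }
    },
    Sequence = {
      pure <- (posl == 0L || posl == nl) || (posr == 0L || posr == nr)
      if (!pure) -Inf
      else entropy2(pos, n) - (nl / n) * entropy2(posl, nl) -
        (nr / n) * entropy2(posr, nr)
    },
    stop("unknown partitioner: ", partitioner))
}

node_incorrect <- function(labels) min(sum(labels), sum(!labels))

#' Train a decision tree
#'
#' Greedy recursive partitioning of the feature space. Candidate thresholds
#' are midpoints between consecutive sorted unique feature values; candidate
#' splits are rated by the `partitioner` and ranked by the `node_score`
#' (ties broken by lowest feature index, then lowest threshold). Recursion
#' stops when a node's incorrect count is at most `min_split`, the node is
#' pure, or no admissible split exists. Leaves predict the active-class
#' fraction.
#'
#' @param train a `feature_dataset` (first result column used) or feature
#'   matrix.
#' @param Y result vector/matrix when `train` is a matrix.
#' @param partitioner `"InformationGain"`, `"Gini"`, `"ROC"`, or
#'   `"Sequence"` (only splits leaving at least one pure child).
#' @param node_score `"SplitRating"`, `"InitialNumIncorrect"`,
#'   `"RatingTimesInitialNumIncorrect"`, or
#'   `"InitialIncorrectPlusFinalCorrect"`.
#' @param activity_cutoff results above this value are the active class.
#' @param min_split stop when the incorrect count is at most this.
#' @param max_depth optional depth cap.
#' @return a `dtree_model` with a flat node table (`feature = 0` marks a
#'   leaf).
#' @export
dt_train <- function(train, Y = NULL, partitioner = "InformationGain",
                     node_score = "SplitRating", activity_cutoff = 0.5,
                     min_split = 0L, max_depth = 20L) {
  partitioner <- match.arg(partitioner, c("InformationGain", "Gini", "ROC",
                                          "Sequence"))
  node_score <- match.arg(node_score, c("SplitRating", "InitialNumIncorrect",
                                        "RatingTimesInitialNumIncorrect",
                                        "InitialIncorrectPlusFinalCorrect"))
  xy <- as_xy(train, Y)
  if (!nrow(xy$X)) stop("empty training set")
  labels <- as.integer(xy$Y[, 1] > activity_cutoff)
  nodes <- list()
  build <- function(rows, depth) {
    lab <- labels[rows]
    make_leaf <- function() {
      nodes[[length(nodes) + 1L]] <<- list(
        feature = 0L, threshold = 0, left = 0L, right = 0L,
        value = mean(lab), count = length(rows))
      length(nodes)
    }
    if (node_incorrect(lab) <= min_split || depth >= max_depth)
      return(make_leaf())
    best <- NULL
    init_incorrect <- node_incorrect(lab)
    for (f in seq_len(ncol(xy$X))) {
      v <- xy$X[rows, f]
      u <- sort(unique(v))
      if (length(u) < 2L) next
      for (t in (head(u, -1L) + tail(u, -1L)) / 2) {
        left <- v < t
        rating <- split_rating(lab, left, partitioner)
        if (!is.finite(rating)) next
        final_correct <- sum(lab[left] == (mean(lab[left]) > 0.5)) +
          sum(lab[!left] == (mean(lab[!left]) > 0.5))
        score <- switch(node_score,
          SplitRating = rating,
          InitialNumIncorrect = init_incorrect,
          RatingTimesInitialNumIncorrect = rating * init_incorrect,
          InitialIncorrectPlusFinalCorrect = init_incorrect + final_correct)
        if (is.null(best) || score > best$score + 1e-12) {
          best <- list(score = score, rating = rating, feature = f,
                       threshold = t, left = left)
        }
      }
    }
    if (is.null(best) || best$rating <= 0) return(make_leaf())
    li <- build(rows[best$left], depth + 1L)
    ri <- build(rows[!best$left], depth + 1L)
    nodes[[length(nodes) + 1L]] <<- list(
      feature = best$feature, threshold = best$threshold, left = li,
      right = ri, value = mean(lab), count = length(rows))
    length(nodes)
  }
  root <- build(seq_along(labels), 0L)
  structure(list(type = "DecisionTree", nodes = nodes, root = root,
                 config = list(partitioner = partitioner,
                               node_score = node_score,
                               activity_cutoff = activity_cutoff,
                               min_split = min_split, root = root),
                 scaling = scaling_fit(xy$X, "none")),
            class = c("dtree_model", "chemtk_model"))
}

#' @export
predict.dtree_model <- function(object, newdata, ...) {
  X <- as_xy(newdata)$X
  root <- object$root %||% object$config$root
  out <- vapply(seq_len(nrow(X)), function(i) {
    k <- root
    repeat {
      nd <- object$nodes[[k]]
      if (nd$feature == 0L) return(nd$value)
      k <- if (X[i, nd$feature] < nd$threshold) nd$left else nd$right
    }
  }, numeric(1))
  matrix(out, ncol = 1L)
}

#' Export a decision tree as readable logic and a descriptor expression
#'
#' The text form lists one condition per internal node, root first. The
#' descriptor expression (nested `Add`/`Multiply`/`Less`/`GreaterEqual` over
#' the feature descriptors) evaluates to the tree's thresholded class
#' prediction for every input.
#'
#' @param model a `dtree_model`.
#' @param feature_names descriptor names for the feature columns (default
#'   `f0, f1, ...`, the placeholder dataset labels).
#' @return list with `text` (character vector) and `descriptor` (expression
#'   string; evaluates to `dt_predict >= 0.5` as 1/0).
#' @export
dt_to_logic <- function(model, feature_names = NULL) {
  root <- model$root %||% model$config$root
  feature_names <- feature_names %||%
    sprintf("f%d", seq_len(max(1L, max(vapply(model$nodes, function(n)
      n$feature, numeric(1))))) - 1L)
  text_of <- function(k, indent) {
    nd <- model$nodes[[k]]
    pad <- strrep("  ", indent)
    if (nd$feature == 0L)
      return(sprintf("%spredict %g (n = %d)", pad, as.numeric(nd$value >= 0.5),
                     nd$count))
    c(sprintf("%sif %s < %g:", pad, feature_names[nd$feature], nd$threshold),
      text_of(nd$left, indent + 1L),
      sprintf("%selse:", pad),
      text_of(nd$right, indent + 1L))
  }
  expr_of <- function(k) {
    nd <- model$nodes[[k]]
    if (nd$feature == 0L)
      return(sprintf("Constant(%g)", as.numeric(nd$value >= 0.5)))
    f <- feature_names[nd$feature]
    sprintf(paste0("Add(Multiply(Less(lhs = %s, rhs = %g), %s), ",
                   "Multiply(GreaterEqual(lhs = %s, rhs = %g), %s))"),
            f, nd$threshold, expr_of(nd$left),
            f, nd$threshold, expr_of(nd$right))
  }
  list(text = text_of(root, 0L), descriptor = expr_of(root))
}
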
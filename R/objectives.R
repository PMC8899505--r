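# Virtual-screening objective functions: contingency-table metrics, ROC and
# (log-x-axis) AUC, enrichment, regression error metrics, and localPPV
# calibration of model outputs to local positive predictive values.

#' Contingency counts at a cutoff
#'
#' @param pred,actual equal-length numeric vectors; `actual` is binarized at
#'   `cutoff`.
#' @param cutoff decision/classification cutoff applied to both vectors.
#' @param parity 1 when values above the cutoff are the positive class, 0 to
#'   swap the classes.
#' @return a `contingency` list with TP, FP, TN, FN.
#' @export
contingency <- function(pred, actual, cutoff = 0.5, parity = 1) {
  stopifnot(length(pred) == length(actual))
  pos <- if (parity == 1) actual > cutoff else actual <= cutoff
  hit <- if (parity == 1) pred > cutoff else pred <= cutoff
  structure(list(TP = sum(pos & hit), FP = sum(!pos & hit),
                 TN = sum(!pos & !hit), FN = sum(pos & !hit),
                 cutoff = cutoff, parity = parity),
            class = "contingency")
}

safe_div <- function(num, den) {
  if (den == 0) { warning("division by zero; returning 0"); return(0) }
  num / den
}

#' Classification metrics from contingency counts
#'
#' Accuracy `(TP+TN)/(P+N)`, positive predictive value `TP/(TP+FP)`, and
#' Matthews correlation coefficient; degenerate denominators yield 0 with a
#' warning.
#'
#' @param ct a [contingency()] object.
#' @return numeric scalar.
#' @export
accuracy <- function(ct) safe_div(ct$TP + ct$TN, ct$TP + ct$TN + ct$FP + ct$FN)

#' @rdname accuracy
#' @export
ppv <- function(ct) safe_div(ct$TP, ct$TP + ct$FP)

#' @rdname accuracy
#' @export
mcc <- function(ct) {
  den <- sqrt((ct$TP + ct$FP)) * sqrt((ct$TP + ct$FN)) *
    sqrt((ct$TN + ct$FP)) * sqrt((ct$TN + ct$FN))
  safe_div(ct$TP * ct$TN - ct$FP * ct$FN, den)
}

#' Enrichment factor
#'
#' PPV among the top `x_percent` scored rows divided by the prevalence
#' (PPV at 100%); `EF(100) = 1` exactly.
#'
#' @param pred,actual prediction scores and activity values.
#' @param x_percent top fraction of rows, in percent.
#' @param cutoff activity cutoff.
#' @param parity positive-class parity.
#' @return enrichment factor (at most `1/prevalence`).
#' @export
enrichment <- function(pred, actual, x_percent, cutoff = 0.5, parity = 1) {
  stopifnot(length(pred) == length(actual), x_percent > 0, x_percent <= 100)
  pos <- if (parity == 1) actual > cutoff else actual <= cutoff
  ord <- order(pred, decreasing = parity == 1)
  k <- max(1L, round(length(pred) * x_percent / 100))
  top <- ord[seq_len(k)]
  safe_div(mean(pos[top]), mean(pos))
}

# ---- ROC --------------------------------------------------------------------

#' ROC curve
#'
#' Threshold sweep over unique prediction values (ties grouped), from (0,0)
#' to (1,1).
#'
#' @param pred prediction scores.
#' @param actual activity values, binarized at `cutoff`.
#' @param cutoff activity cutoff.
#' @param parity 1 if larger predictions mean more positive.
#' @return a `roc_curve`: data frame with columns `fpr`, `tpr` (both
#'   non-decreasing).
#' @export
roc_curve <- function(pred, actual, cutoff = 0.5, parity = 1) {
  pos <- if (parity == 1) actual > cutoff else actual <= cutoff
  if (all(pos) || !any(pos)) stop("ROC requires both classes present")
  s <- if (parity == 1) pred else -pred
  ord <- order(s, decreasing = TRUE)
  pos <- pos[ord]; s <- s[ord]
  grp <- cumsum(!duplicated(s))            # tie groups share a threshold
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(grp, fromLast = TRUE)
  out <- data.frame(fpr = c(0, fp[last] / sum(!pos)),
                    tpr = c(0, tp[last] / sum(pos)))
  structure(out, class = c("roc_curve", "data.frame"))
}

# linear interpolation of tpr at an fpr value
tpr_at <- function(curve, f) {
  approx(curve$fpr, curve$tpr, xout = f, ties = max, rule = 2)$y
}

#' Area under the ROC curve
#'
#' Trapezoidal integral of TPR over FPR restricted to
#' `[min_fpr, max_fpr]` and normalized by the integration span. With
#' `x_axis_log` the integration variable is `log10(FPR)` (the logAUC of
#' early-enrichment screening); the diagonal classifier then scores
#' `(max_fpr - min_fpr) / ln(max_fpr/min_fpr)`.
#'
#' @param curve a [roc_curve()].
#' @param min_fpr,max_fpr integration range (defaults: full range linear,
#'   0.001-0.1 logarithmic).
#' @param x_axis_log integrate on a log10 FPR axis.
#' @return normalized area in `[0, 1]`.
#' @export
auc <- function(curve, min_fpr = if (x_axis_log) 0.001 else 0,
                max_fpr = if (x_axis_log) 0.1 else 1, x_axis_log = FALSE) {
  if (max_fpr <= min_fpr) stop("max_fpr must exceed min_fpr")
  if (x_axis_log && min_fpr <= 0) stop("log axis requires min_fpr > 0")
  f <- sort(unique(c(min_fpr, max_fpr,
                     curve$fpr[curve$fpr > min_fpr & curve$fpr < max_fpr])))
  t <- tpr_at(curve, f)
  if (!x_axis_log) {
    area <- sum(diff(f) * (head(t, -1) + tail(t, -1)) / 2)
    return(area / (max_fpr - min_fpr))
  }
  # piecewise-linear TPR(FPR) integrated exactly on the log10(FPR) axis:
  # for t = a + b f on [f1, f2],
  # integral t dlog10(f) = (a ln(f2/f1) + b (f2 - f1)) / ln 10
  f1 <- head(f, -1); f2 <- tail(f, -1)
  t1 <- head(t, -1); t2 <- tail(t, -1)
  b <- (t2 - t1) / (f2 - f1)
  a <- t1 - b * f1
  area <- sum(a * log(f2 / f1) + b * (f2 - f1)) / log(10)
  area / (log10(max_fpr) - log10(min_fpr))
}

# ---- regression metrics -----------------------------------------------------

#' Regression error metrics
#'
#' `mae` mean absolute error; `mad_metric` mean absolute deviation of the
#' actual values around their mean; `mae_nmad = mae / mad` (1 for the
#' constant-mean predictor); `rmsd_metric` root-mean-square deviation;
#' `nrmsd = rmsd / range(actual)`; `rmsd_nstd = rmsd / sd(actual)`.
#'
#' @param pred,actual equal-length numeric vectors.
#' @return numeric scalar.
#' @export
mae <- function(pred, actual) mean(abs(pred - actual))

#' @rdname mae
#' @export
mad_metric <- function(pred, actual) mean(abs(actual - mean(actual)))

#' @rdname mae
#' @export
mae_nmad <- function(pred, actual) {
  m <- mad_metric(pred, actual)
  if (m == 0) stop("zero mean absolute deviation")
  mae(pred, actual) / m
}

#' @rdname mae
#' @export
rmsd_metric <- function(pred, actual) sqrt(mean((pred - actual)^2))

#' @rdname mae
#' @export
nrmsd <- function(pred, actual) {
  rg <- max(actual) - min(actual)
  if (rg == 0) stop("zero range in actual values")
  rmsd_metric(pred, actual) / rg
}

#' @rdname mae
#' @export
rmsd_nstd <- function(pred, actual) {
  s <- stats::sd(actual)
  if (s == 0) stop("zero standard deviation in actual values")
  rmsd_metric(pred, actual) / s
}

# ---- localPPV calibration ---------------------------------------------------

#' Calibrate model outputs to local positive predictive values
#'
#' Sliding-window PPV over prediction-sorted rows, made monotone by
#' pool-adjacent-violators (isotonic regression). Assumes the model output
#' varies monotonically with the true activity likelihood.
#'
#' @param pred,actual predictions and activities (binarized at `cutoff`).
#' @param cutoff activity cutoff.
#' @param parity 1 when larger outputs mean more active.
#' @param window sliding window size (default 1% of rows, at least 50, capped
#'   at n).
#' @return a `calibration_curve`: monotone map from output value to local PPV.
#' @export
local_ppv_fit <- function(pred, actual, cutoff = 0.5, parity = 1,
                          window = NULL) {
  stopifnot(length(pred) == length(actual))
  n <- length(pred)
  window <- as.integer(window %||% max(50L, ceiling(0.01 * n)))
  if (n < window) stop("need at least ", window, " rows for calibration")
  pos <- if (parity == 1) actual > cutoff else actual <= cutoff
  if (all(pos) || !any(pos)) stop("both classes must be present")
  ord <- order(pred)
  p_sorted <- pred[ord]; y_sorted <- as.numeric(pos[ord])
  csum <- cumsum(y_sorted)
  centers <- seq_len(n - window + 1L)
  local_ppv <- (csum[centers + window - 1L] -
                c(0, csum)[centers]) / window
  xs <- vapply(centers, function(i)
    mean(p_sorted[i:(i + window - 1L)]), numeric(1))
  if (parity != 1) local_ppv <- rev(local_ppv)
  iso <- stats::isoreg(xs, local_ppv)
  structure(list(x = iso$x, ppv = pmin(1, pmax(0, iso$yf)), parity = parity),
            class = "calibration_curve")
}

#' @rdname local_ppv_fit
#' @param curve a `calibration_curve`.
#' @param v model output value(s).
#' @export
local_ppv_eval <- function(curve, v) {
  out <- approx(curve$x, curve$ppv, xout = v, rule = 2, ties = max)$y
  pmin(1, pmax(0, out))
}

# ---- objective-function grammar ---------------------------------------------

#' Build an objective function from its specification string
#'
#' The grammar matches the training-configuration strings, e.g.
#' `"AucRocCurve (cutoff = 0.5, parity = 1, x_axis_log = 1, min fpr = 0.001,
#' max fpr = 0.1)"`, `"Accuracy (cutoff = 0.5)"`, `"RMSD"`, `"MAE_NMAD"`,
#' `"EnrichmentFactor (fraction = 0.01)"`, `"MCC"`, `"PPV"`.
#'
#' @param text objective specification.
#' @return a `function(pred, actual)`; attribute `"maximize"` says whether
#'   larger is better.
#' @export
objective_function <- function(text) {
  node <- parse_descriptor(text)
  if (node$kind == "name") node <- list(kind = "call", name = node$name,
                                        args = list(), kwargs = list())
  num_kw <- function(key, default) {
    kw <- get_kwarg(node, key)
    if (is.null(kw)) default else kw$value
  }
  mk <- function(f, maximize) structure(f, maximize = maximize)
  first_col <- function(x) if (is.matrix(x)) x[, 1] else x
  wrap <- function(g, maximize) mk(function(pred, actual) {
    p <- first_col(as.matrix(pred)); a <- first_col(as.matrix(actual))
    keep <- !is.na(a) & !is.na(p)
    g(p[keep], a[keep])
  }, maximize)
  cutoff <- num_kw("cutoff", 0.5)
  parity <- num_kw("parity", 1)
  switch(node$name,
    AUC = ,
    AucRocCurve = {
      logx <- num_kw("xaxislog", 0) == 1
      minf <- num_kw("minfpr", if (logx) 0.001 else 0)
      maxf <- num_kw("maxfpr", if (logx) 0.1 else 1)
      wrap(function(p, a)
        auc(roc_curve(p, a, cutoff, parity), minf, maxf, logx), TRUE)
    },
    Accuracy = wrap(function(p, a)
      accuracy(contingency(p, a, cutoff, parity)), TRUE),
    PPV = wrap(function(p, a) ppv(contingency(p, a, cutoff, parity)), TRUE),
    MCC = wrap(function(p, a) mcc(contingency(p, a, cutoff, parity)), TRUE),
    EnrichmentFactor = {
      pct <- num_kw("fraction", 0.01) * 100
      wrap(function(p, a) enrichment(p, a, pct, cutoff, parity), TRUE)
    },
    MAE = wrap(mae, FALSE),
    MAE_NMAD = wrap(mae_nmad, FALSE),
    RMSD = wrap(rmsd_metric, FALSE),
    NRMSD = wrap(nrmsd, FALSE),
    RMSD_NSTD = wrap(rmsd_nstd, FALSE),
    stop("unknown objective function: ", node$name))
}
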
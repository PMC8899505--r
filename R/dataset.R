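# Feature datasets: generation from molecules + descriptor specs, the
# header+binary ".bin" format, CSV interconversion, and the dataset
# transformations used around model training (randomize, chunks, combine,
# balance, PCA, k-means row reduction).

# run expr with a deterministic RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a feature dataset
#'
#' @param ids character row identifiers (padded to fixed width).
#' @param X numeric feature matrix (rows = ids).
#' @param Y numeric result matrix (`NA` marks a missing result value).
#' @param feature_labels,result_labels column labels (placeholders `f0...` /
#'   `r0...` when omitted).
#' @param id_label name of the id column.
#' @return a `feature_dataset`.
#' @export
feature_dataset <- function(ids, X, Y, feature_labels = NULL,
                            result_labels = NULL, id_label = "ID") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  ids <- as.character(ids)
  stopifnot(length(ids) == nrow(X), nrow(X) == nrow(Y))
  w <- max(1L, nchar(ids))
  ids <- formatC(ids, width = w, flag = "-")
  feature_labels <- feature_labels %||% sprintf("f%d", seq_len(ncol(X)) - 1L)
  result_labels <- result_labels %||% sprintf("r%d", seq_len(ncol(Y)) - 1L)
  stopifnot(length(feature_labels) == ncol(X),
            length(result_labels) == ncol(Y))
  structure(list(ids = ids, X = unname(X), Y = unname(Y),
                 feature_labels = as.character(feature_labels),
                 result_labels = as.character(result_labels),
                 id_label = id_label),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> %d rows x %d features, %d result column(s)\n",
              nrow(x$X), ncol(x$X), ncol(x$Y)))
  invisible(x)
}

#' @export
dim.feature_dataset <- function(x) dim(x$X)

# row subset keeping ids/X/Y aligned
ds_rows <- function(ds, idx) {
  feature_dataset(ds$ids[idx], ds$X[idx, , drop = FALSE],
                  ds$Y[idx, , drop = FALSE], ds$feature_labels,
                  ds$result_labels, ds$id_label)
}

#' Generate a feature dataset from molecules
#'
#' One row per molecule in input order; features and results are descriptor
#' specs (results typically name an MDL data-block property such as
#' `IsActive`). Missing result values become `NA`; with `forbid_incomplete`
#' rows lacking any result value are dropped.
#'
#' @param mols list of molecules.
#' @param feature_spec,result_spec descriptor text or parsed specs.
#' @param id_label id column name; row ids are the molecule names (fixed
#'   width), or `M<row>` when unnamed.
#' @param forbid_incomplete drop rows with any missing result.
#' @param strict abort on a feature evaluation failure instead of dropping
#'   the row with a warning.
#' @return a `feature_dataset`.
#' @export
generate_dataset <- function(mols, feature_spec, result_spec,
                             id_label = "ID", forbid_incomplete = FALSE,
                             strict = FALSE) {
  if (is.character(feature_spec)) feature_spec <- parse_descriptor(feature_spec)
  if (is.character(result_spec)) result_spec <- parse_descriptor(result_spec)
  rows <- list(); yrows <- list(); ids <- character()
  for (i in seq_along(mols)) {
    mol <- mols[[i]]
    x <- tryCatch(evaluate_descriptor(feature_spec, mol), error = function(e) e)
    if (inherits(x, "error")) {
      msg <- sprintf("molecule %d (%s): %s", i, mol$name, conditionMessage(x))
      if (strict) stop(msg)
      warning("feature evaluation failed, row dropped: ", msg)
      next
    }
    y <- tryCatch(evaluate_descriptor(result_spec, mol),
                  error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- x
    yrows[[length(yrows) + 1L]] <- y
    ids <- c(ids, if (nzchar(mol$name)) mol$name else sprintf("M%d", i))
  }
  if (!length(rows)) stop("no rows could be generated")
  nf <- unique(lengths(rows))
  if (length(nf) != 1L) stop("feature arity differs between molecules")
  nr <- max(lengths(yrows))
  Y <- matrix(NA_real_, length(yrows), nr)
  for (i in seq_along(yrows)) Y[i, seq_along(yrows[[i]])] <- yrows[[i]]
  ds <- feature_dataset(ids, do.call(rbind, rows), Y,
                        feature_labels = NULL, result_labels = NULL,
                        id_label = id_label)
  if (forbid_incomplete) ds <- ds_rows(ds, which(rowSums(is.na(ds$Y)) == 0L))
  ds
}

# ---- binary format ----------------------------------------------------------

.BIN_MAGIC <- "CHEMTK-DATASET 1"

#' Read and write the header+binary dataset format
#'
#' The `.bin` format is a human-readable ASCII header (magic line, id label
#' and width, feature and result labels, row count) followed by the payload:
#' per row, the fixed-width ASCII id, then features and results as
#' little-endian 32-bit floats (missing results stored as NaN). Write/read
#' round trips are bit-exact on the float32 values and exact on ids and
#' labels.
#'
#' @param ds a `feature_dataset`.
#' @param path file path.
#' @return `read_bin()` returns a `feature_dataset`; `write_bin()` returns
#'   `path` invisibly.
#' @export
write_bin <- function(ds, path) {
  stopifnot(inherits(ds, "feature_dataset"))
  con <- file(path, "wb")
  on.exit(close(con))
  w <- if (length(ds$ids)) nchar(ds$ids[1]) else 1L
  hdr <- c(.BIN_MAGIC,
           sprintf("id %s %d", ds$id_label, w),
           sprintf("features %d", ncol(ds$X)),
           sprintf("  %s", ds$feature_labels),
           sprintf("results %d", ncol(ds$Y)),
           sprintf("  %s", ds$result_labels),
           sprintf("rows %d", nrow(ds$X)))
  writeLines(hdr, con)
  for (i in seq_len(nrow(ds$X))) {
    writeBin(charToRaw(ds$ids[i]), con)
    writeBin(as.numeric(c(ds$X[i, ], ds$Y[i, ])), con, size = 4L,
             endian = "little")
  }
  invisible(path)
}

#' @rdname write_bin
#' @export
read_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_header_line <- function() {
    chars <- character()
    repeat {
      ch <- readBin(con, "raw", 1L)
      if (!length(ch)) stop("truncated header in ", path)
      if (ch == as.raw(10L)) break
      chars <- c(chars, rawToChar(ch))
    }
    paste(chars, collapse = "")
  }
  magic <- read_header_line()
  if (magic != .BIN_MAGIC)
    stop("not a dataset file (magic mismatch): ", path)
  idline <- strsplit(read_header_line(), " +")[[1]]
  id_label <- idline[2]; id_width <- as.integer(idline[3])
  nf <- as.integer(strsplit(read_header_line(), " +")[[1]][2])
  feature_labels <- vapply(seq_len(nf), function(i)
    sub("^  ", "", read_header_line()), character(1))
  nr <- as.integer(strsplit(read_header_line(), " +")[[1]][2])
  result_labels <- vapply(seq_len(nr), function(i)
    sub("^  ", "", read_header_line()), character(1))
  n <- as.integer(strsplit(read_header_line(), " +")[[1]][2])
  ids <- character(n)
  vals <- matrix(0, n, nf + nr)
  for (i in seq_len(n)) {
    raw_id <- readBin(con, "raw", id_width)
    row <- readBin(con, "numeric", nf + nr, size = 4L, endian = "little")
    if (length(raw_id) < id_width || length(row) < nf + nr)
      stop("truncated payload at row ", i, " in ", path)
    ids[i] <- rawToChar(raw_id)
    vals[i, ] <- row
  }
  X <- vals[, seq_len(nf), drop = FALSE]
  Y <- vals[, nf + seq_len(nr), drop = FALSE]
  Y[is.nan(Y)] <- NA
  feature_dataset(ids, X, Y, feature_labels, result_labels, id_label)
}

# ---- CSV --------------------------------------------------------------------

#' Read and write datasets as CSV
#'
#' Each row is the fixed-width id followed by the feature columns, with the
#' last `number_result_cols` columns holding the results. Labels are not part
#' of the CSV payload; on read, placeholder labels are generated unless
#' supplied.
#'
#' @param ds a `feature_dataset`.
#' @param path file path.
#' @param number_result_cols how many trailing columns are results.
#' @param number_id_chars expected id width (validated against the file).
#' @param feature_labels,result_labels,id_label optional labels for the
#'   reconstructed dataset.
#' @return `read_dataset_csv()` returns a `feature_dataset`.
#' @export
write_dataset_csv <- function(ds, path) {
  stopifnot(inherits(ds, "feature_dataset"))
  vals <- cbind(ds$X, ds$Y)
  lines <- vapply(seq_len(nrow(vals)), function(i) {
    paste(c(ds$ids[i], sprintf("%.17g", vals[i, ])), collapse = ",")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path, number_result_cols = 1L,
                             number_id_chars = NULL, feature_labels = NULL,
                             result_labels = NULL, id_label = "ID") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty CSV: ", path)
  parts <- strsplit(lines, ",", fixed = TRUE)
  nfield <- unique(lengths(parts))
  if (length(nfield) != 1L)
    stop("ragged CSV row (row ",
         which(lengths(parts) != lengths(parts)[1])[1], ") in ", path)
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (!is.null(number_id_chars) && any(nchar(ids) != number_id_chars))
    stop("id width mismatch at row ", which(nchar(ids) != number_id_chars)[1])
  nv <- nfield - 1L
  if (number_result_cols >= nv)
    stop("number_result_cols leaves no feature columns")
  vals <- matrix(as.numeric(unlist(lapply(parts, `[`, -1L))), ncol = nv,
                 byrow = TRUE)
  nf <- nv - number_result_cols
  Y <- vals[, nf + seq_len(number_result_cols), drop = FALSE]
  Y[is.nan(Y)] <- NA
  feature_dataset(ids, vals[, seq_len(nf), drop = FALSE], Y,
                  feature_labels, result_labels, id_label)
}

# ---- transformations --------------------------------------------------------

#' Dataset transformations
#'
#' `randomize()` applies a seeded joint row permutation. `chunks()` divides
#' the rows into `number_chunks` nearly equal contiguous blocks (block `b`,
#' 0-based, holds rows `floor(b n/k) + 1 ... floor((b+1) n/k)`) and
#' concatenates the selected blocks. `combine_datasets()` joins feature
#' columns of datasets carrying identical id sequences (keeping the first
#' dataset's results), or stacks rows with `by_rows = TRUE`.
#'
#' @param ds a `feature_dataset`.
#' @param seed integer seed.
#' @param number_chunks number of blocks.
#' @param selected 0-based block indices to keep.
#' @param datasets list of `feature_dataset` objects.
#' @param by_rows concatenate rows instead of joining columns.
#' @return a `feature_dataset`.
#' @export
randomize <- function(ds, seed) {
  perm <- with_seed(seed, sample.int(nrow(ds$X)))
  ds_rows(ds, perm)
}

#' @rdname randomize
#' @export
chunks <- function(ds, number_chunks, selected) {
  n <- nrow(ds$X)
  stopifnot(number_chunks >= 1L, number_chunks <= n)
  selected <- as.integer(selected)
  if (any(selected < 0L | selected >= number_chunks))
    stop("chunk index out of range 0..", number_chunks - 1L)
  idx <- unlist(lapply(selected, function(b) {
    lo <- floor(b * n / number_chunks) + 1L
    hi <- floor((b + 1) * n / number_chunks)
    if (lo > hi) integer(0) else seq.int(lo, hi)
  }))
  ds_rows(ds, idx)
}

#' @rdname randomize
#' @export
combine_datasets <- function(datasets, by_rows = FALSE) {
  stopifnot(length(datasets) >= 1L)
  first <- datasets[[1]]
  if (length(datasets) == 1L) return(first)
  if (by_rows) {
    for (d in datasets[-1]) {
      stopifnot(ncol(d$X) == ncol(first$X), ncol(d$Y) == ncol(first$Y))
    }
    return(feature_dataset(
      unlist(lapply(datasets, function(d) trimws(d$ids))),
      do.call(rbind, lapply(datasets, `[[`, "X")),
      do.call(rbind, lapply(datasets, `[[`, "Y")),
      first$feature_labels, first$result_labels, first$id_label))
  }
  for (d in datasets[-1]) {
    if (!identical(trimws(d$ids), trimws(first$ids)))
      stop("combine: id sequences differ between datasets")
  }
  feature_dataset(first$ids,
                  do.call(cbind, lapply(datasets, `[[`, "X")),
                  first$Y,
                  unlist(lapply(datasets, `[[`, "feature_labels")),
                  first$result_labels, first$id_label)
}

#' Oversample the minor class
#'
#' Rows of the underrepresented class (under `cutoff` on the first result
#' column) are duplicated in seeded cycling order until the minor/major count
#' ratio reaches `target_ratio`, with no row repeated more than `max_repeats`
#' times; the major class is untouched and the output is shuffled.
#'
#' @param ds a `feature_dataset` with a binary first result column.
#' @param target_ratio desired minor/major count ratio.
#' @param max_repeats maximum copies of any one row (`Inf` = unlimited).
#' @param cutoff class boundary on the result value.
#' @param seed integer seed.
#' @return a `feature_dataset`; a warning is raised when `max_repeats` makes
#'   the target unreachable.
#' @export
balance <- function(ds, target_ratio, max_repeats = Inf, cutoff = 0.5,
                    seed = 0L) {
  y <- ds$Y[, 1]
  pos <- which(y > cutoff); neg <- which(y <= cutoff)
  if (!length(pos) || !length(neg)) stop("both classes must be non-empty")
  minor <- if (length(pos) <= length(neg)) pos else neg
  major <- if (length(pos) <= length(neg)) neg else pos
  want <- ceiling(target_ratio * length(major))
  cap <- floor(max_repeats * length(minor))
  target <- min(max(want, length(minor)), cap)
  if (want > cap)
    warning("max_repeats caps the minor class below the target ratio")
  reps <- with_seed(seed, {
    order_minor <- sample(minor)
    rep_len(order_minor, target)
  })
  idx <- c(major, reps)
  perm <- with_seed(seed + 1L, sample(length(idx)))
  ds_rows(ds, idx[perm])
}

# ---- PCA --------------------------------------------------------------------

#' Principal component analysis over feature columns
#'
#' `pca_train()` eigendecomposes the covariance of the column-centered
#' features; `pca_apply()` keeps the smallest number of leading components
#' whose cumulative eigenvalue fraction reaches `fraction` and projects.
#'
#' @param ds a `feature_dataset` with at least two rows.
#' @param model a `pca_model` from `pca_train()`.
#' @param fraction target cumulative variance fraction in `(0, 1]`.
#' @return `pca_train()`: a `pca_model` (means, eigenvectors in columns,
#'   eigenvalues, non-increasing); `pca_apply()`: the projected dataset.
#' @export
pca_train <- function(ds) {
  stopifnot(nrow(ds$X) >= 2L)
  mu <- colMeans(ds$X)
  ev <- eigen(stats::cov(ds$X), symmetric = TRUE)
  structure(list(means = mu, vectors = ev$vectors,
                 values = pmax(ev$values, 0)),
            class = "pca_model")
}

#' @rdname pca_train
#' @export
pca_apply <- function(ds, model, fraction = 0.95) {
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must be in (0, 1]")
  cum <- cumsum(model$values) / sum(model$values)
  k <- which(cum >= fraction - 1e-12)[1]
  proj <- sweep(ds$X, 2, model$means) %*% model$vectors[, seq_len(k),
                                                        drop = FALSE]
  feature_dataset(ds$ids, proj, ds$Y,
                  sprintf("PC%d", seq_len(k)), ds$result_labels, ds$id_label)
}

# ---- k-means row reduction --------------------------------------------------

#' Reduce dataset rows by k-means clustering
#'
#' Lloyd's algorithm with seeded k-means++ initialization; empty clusters are
#' re-seeded from the point farthest from its centroid. The output rows are
#' the centroids with per-cluster mean results and synthesized ids.
#'
#' @param ds a `feature_dataset`.
#' @param k number of clusters (at most the row count).
#' @param seed integer seed.
#' @param max_iter Lloyd iteration cap.
#' @return a `feature_dataset` of `k` centroid rows.
#' @export
kmeans_reduce <- function(ds, k, seed = 0L, max_iter = 100L) {
  X <- ds$X
  n <- nrow(X)
  stopifnot(k >= 1L, k <= n)
  centers <- with_seed(seed, {
    # k-means++ seeding
    idx <- sample.int(n, 1L)
    cs <- X[idx, , drop = FALSE]
    while (nrow(cs) < k) {
      d2 <- apply(X, 1, function(r) min(colSums((t(cs) - r)^2)))
      if (all(d2 <= 0)) idx <- sample.int(n, 1L)
      else idx <- sample.int(n, 1L, prob = d2 / sum(d2))
      cs <- rbind(cs, X[idx, , drop = FALSE])
    }
    cs
  })
  assign_clusters <- function(cs) {
    d <- outer(rowSums(X^2), rep(1, nrow(cs))) - 2 * X %*% t(cs) +
      outer(rep(1, n), rowSums(cs^2))
    max.col(-d, ties.method = "first")
  }
  cl <- assign_clusters(centers)
  for (it in seq_len(max_iter)) {
    newc <- centers
    for (j in seq_len(k)) {
      rows <- which(cl == j)
      if (length(rows)) newc[j, ] <- colMeans(X[rows, , drop = FALSE])
      else {
        # re-seed an empty cluster from the point farthest from its centroid
        d2 <- vapply(seq_len(n), function(i)
          sum((X[i, ] - newc[cl[i], ])^2), numeric(1))
        newc[j, ] <- X[which.max(d2), ]
      }
    }
    cl2 <- assign_clusters(newc)
    conv <- identical(cl2, cl) && max(abs(newc - centers)) < 1e-12
    centers <- newc
    cl <- cl2
    if (conv) break
  }
  Ym <- do.call(rbind, lapply(seq_len(k), function(j) {
    rows <- which(cl == j)
    if (!length(rows)) rep(NA_real_, ncol(ds$Y))
    else colMeans(ds$Y[rows, , drop = FALSE])
  }))
  feature_dataset(sprintf("C%06d", seq_len(k) - 1L), centers, Ym,
                  ds$feature_labels, ds$result_labels, ds$id_label)
}

#' Dataset summary statistics
#'
#' @param ds a `feature_dataset`.
#' @return list with row/column counts, per-feature means and standard
#'   deviations, and the per-result fraction of defined values.
#' @export
dataset_summary <- function(ds) {
  list(rows = nrow(ds$X), features = ncol(ds$X), results = ncol(ds$Y),
       feature_mean = colMeans(ds$X),
       feature_sd = apply(ds$X, 2, stats::sd),
       result_density = colMeans(!is.na(ds$Y)))
}
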
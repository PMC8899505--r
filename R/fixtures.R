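# Bundled canonical structures and seeded synthetic generators: every part of
# the toolkit is testable without downloads. The drug structures (gefitinib,
# afatinib, osimertinib, dasatinib) and small molecules ship as plain-text
# V2000 connection tables under extdata/structures, generated once from their
# canonical constitutions with literature connectivity and synthetic 3D
# coordinates.

.BUILTIN_NAMES <- c("methane", "water", "ethanol", "propane", "benzene",
                    "cyclohexane", "toluene", "ethylbenzene", "pyridine",
                    "pyrrole", "naphthalene", "aniline", "piperazine",
                    "gefitinib", "afatinib", "osimertinib", "dasatinib",
                    "stereo_R", "stereo_S")

#' Load a bundled structure
#'
#' @param name one of the registry names (see `builtin_molecule_names()`):
#'   trivial molecules (methane ... naphthalene), the worked-example drugs
#'   (gefitinib, afatinib, osimertinib, dasatinib), aniline and piperazine,
#'   and an R/S stereo pair (bromochlorofluoromethane enantiomers with 3D
#'   coordinates).
#' @return a `molecule`.
#' @export
builtin_molecule <- function(name) {
  if (!name %in% .BUILTIN_NAMES)
    stop("unknown builtin molecule: ", sQuote(name), "; see ",
         "builtin_molecule_names()")
  path <- system.file("extdata", "structures", paste0(name, ".sdf"),
                      package = "chemtk", mustWork = TRUE)
  read_sdf(path)[[1]]
}

#' @rdname builtin_molecule
#' @export
builtin_molecule_names <- function() .BUILTIN_NAMES

#' The two-conformer dasatinib record pair
#'
#' One record with flat 2D coordinates and one with a 3D conformer of the
#' same constitution, for demonstrating conformation-independence of 2D
#' autocorrelations.
#' @return list of two molecules.
#' @export
dasatinib_conformers <- function() {
  path <- system.file("extdata", "structures", "dasatinibs.sdf",
                      package = "chemtk", mustWork = TRUE)
  read_sdf(path)
}

#' Generate a random valence-legal molecule
#'
#' A random tree over {C, N, O} (optionally with one extra ring-closing bond)
#' with valence-respecting bond orders: a fuzzing generator for parsers,
#' uniqueness and descriptor code. Every output passes
#' [validate_atom_types()].
#'
#' @param seed RNG seed.
#' @param size_range heavy-atom count range.
#' @param ring_prob probability of attempting one ring closure.
#' @return a `molecule`.
#' @export
random_molecule <- function(seed, size_range = c(3L, 12L), ring_prob = 0.5) {
  with_seed(seed, {
    n <- sample(size_range[1]:size_range[2], 1L)
    el <- sample(c("C", "C", "C", "N", "O"), n, replace = TRUE)
    atoms <- data.frame(element = el, charge = 0L,
                        x = rnorm(n), y = rnorm(n), z = rnorm(n),
                        aromatic = FALSE, stringsAsFactors = FALSE)
    cap <- vapply(el, function(e) max(allowed_valences(e, 0L)), numeric(1))
    used <- numeric(n)
    bonds <- NULL
    # an order-1 tree always has an unsaturated attachment point
    for (i in seq_len(n)[-1]) {
      cand <- which(seq_len(n) < i & used < cap)
      j <- if (length(cand) == 1L) cand else sample(cand, 1L)
      bonds <- rbind(bonds, data.frame(a1 = j, a2 = i, order = 1L))
      used[i] <- used[i] + 1L
      used[j] <- used[j] + 1L
    }
    if (n >= 4L && runif(1) < ring_prob) {
      free <- which(used < cap)
      if (length(free) >= 2L) {
        pair <- sample(free, 2L)
        exists <- any(bonds$a1 == min(pair) & bonds$a2 == max(pair))
        if (!exists) {
          bonds <- rbind(bonds, data.frame(a1 = min(pair), a2 = max(pair),
                                           order = 1L))
          used[pair] <- used[pair] + 1L
        }
      }
    }
    # upgrade bond orders where both endpoints retain spare valence
    for (k in sample(nrow(bonds))) {
      i <- bonds$a1[k]; j <- bonds$a2[k]
      spare <- min(cap[i] - used[i], cap[j] - used[j], 2L)
      if (spare >= 1L && runif(1) < 0.3) {
        up <- sample(seq_len(spare), 1L)
        bonds$order[k] <- bonds$order[k] + up
        used[i] <- used[i] + up
        used[j] <- used[j] + up
      }
    }
    molecule(sprintf("random_%d", seed), atoms, bonds)
  })
}

#' Generate a synthetic QSAR dataset with known ground truth
#'
#' Features are standard normal; the latent score is `w'x` (optionally
#' squashed through tanh); the label is `score > threshold`, with optional
#' label-flip noise. Class imbalance is controlled through the threshold
#' quantile, mimicking the sparse-active regime of screening datasets at
#' reduced scale.
#'
#' @param n_rows number of rows.
#' @param n_features number of features.
#' @param active_fraction target fraction of actives (threshold set at the
#'   matching latent-score quantile).
#' @param noise_sd Gaussian noise added to the latent score before
#'   thresholding.
#' @param label_noise probability of flipping a label.
#' @param nonlinear squash the latent score through tanh.
#' @param regression return the continuous latent score as the result instead
#'   of the binary label.
#' @param seed RNG seed.
#' @return a `feature_dataset`; attributes `"weights"` and `"threshold"`
#'   carry the ground truth.
#' @export
synthetic_qsar <- function(n_rows = 500L, n_features = 10L,
                           active_fraction = 0.2, noise_sd = 0,
                           label_noise = 0, nonlinear = FALSE,
                           regression = FALSE, seed = 1L) {
  stopifnot(n_rows > 0L, n_features > 0L, noise_sd >= 0)
  with_seed(seed, {
    w <- rnorm(n_features)
    X <- matrix(rnorm(n_rows * n_features), n_rows, n_features)
    score <- as.numeric(X %*% w) + rnorm(n_rows, sd = noise_sd)
    if (nonlinear) score <- tanh(score)
    if (regression) {
      Y <- matrix(score, ncol = 1L)
      thr <- NA_real_
    } else {
      thr <- quantile(score, 1 - active_fraction, names = FALSE)
      lab <- as.numeric(score > thr)
      flip <- runif(n_rows) < label_noise
      lab[flip] <- 1 - lab[flip]
      Y <- matrix(lab, ncol = 1L)
    }
    ds <- feature_dataset(sprintf("S%05d", seq_len(n_rows)), X, Y,
                          sprintf("f%d", seq_len(n_features) - 1L),
                          "IsActive", "ID")
    attr(ds, "weights") <- w
    attr(ds, "threshold") <- thr
    ds
  })
}
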
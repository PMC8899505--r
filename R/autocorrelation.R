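# Signed autocorrelation descriptors: for every ordered atom pair (i, j),
# including i = j, the product of a per-atom property P_i P_j is accumulated
# into the distance bin containing r_ij -- bond counts in 2D mode, Euclidean
# Angstrom in 3D mode -- and, when signed, into the sign-pair sub-bin of
# (sign P_i, sign P_j) with -/+ and +/- pooled. 2D autocorrelations are
# conformation-independent; 3D autocorrelations are not.

# all-pairs bond-count distances by BFS (Inf for disconnected pairs)
bond_distances <- function(mol) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]$nbr) if (!is.finite(d[s, w])) {
        d[s, w] <- d[s, v] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

#' Autocorrelation of an atomic property
#'
#' @param mol a `molecule`.
#' @param values numeric vector of per-atom property values (length =
#'   atom count), e.g. from [atom_sigma_charge()].
#' @param mode `"bonds"` (2DA, bin by bond-count separation) or
#'   `"euclidean"` (3DA, bin by 3D distance).
#' @param bin_width bin width: 1 bond (2DA) or Angstrom (3DA, default 0.25).
#' @param n_bins number of distance bins (defaults: 11 for 2DA; 24 for 3DA,
#'   reaching 6.0 Angstrom).
#' @param signed split each distance bin into the three sign-pair sub-bins
#'   (-/-, +/+, -/+); zero property values count as positive.
#' @param smooth triangular kernel of half-width one bin applied to each
#'   pair's contribution across neighbouring bins (3D mode only).
#' @return numeric vector of length `n_bins` (unsigned) or `3 * n_bins`
#'   (signed, sub-bins contiguous per distance bin, named). Pairs farther than
#'   the last bin are ignored; unreachable pairs in disconnected 2D graphs are
#'   skipped with a warning.
#' @export
autocorrelation <- function(mol, values, mode = c("bonds", "euclidean"),
                            bin_width = if (mode == "bonds") 1 else 0.25,
                            n_bins = if (mode == "bonds") 11L else 24L,
                            signed = TRUE, smooth = (mode == "euclidean")) {
  mode <- match.arg(mode)
  n <- n_atoms(mol)
  stopifnot(length(values) == n)
  d <- if (mode == "bonds") bond_distances(mol) else as.matrix(dist(coords(mol)))
  if (mode == "bonds" && any(!is.finite(d)))
    warning("disconnected molecule: unreachable atom pairs skipped")
  # sign sub-bin index per ordered pair: 1 = -/-, 2 = +/+, 3 = mixed
  sgn <- ifelse(values < 0, -1, 1)
  acc <- matrix(0, nrow = 3L, ncol = n_bins)
  centers <- (seq_len(n_bins) - 1L) * bin_width
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      r <- d[i, j]
      if (!is.finite(r)) next
      p <- values[i] * values[j]
      sub <- if (sgn[i] < 0 && sgn[j] < 0) 1L
             else if (sgn[i] > 0 && sgn[j] > 0) 2L else 3L
      if (smooth && mode == "euclidean") {
        w <- pmax(0, 1 - abs(r - centers) / bin_width)
        acc[sub, ] <- acc[sub, ] + p * w
      } else {
        b <- floor(r / bin_width) + 1L
        if (b >= 1L && b <= n_bins) acc[sub, b] <- acc[sub, b] + p
      }
    }
  }
  if (!signed) {
    out <- colSums(acc)
    names(out) <- sprintf("bin%02d", seq_len(n_bins) - 1L)
    return(out)
  }
  out <- as.numeric(acc)
  names(out) <- as.vector(outer(c("nn", "pp", "np"),
                                seq_len(n_bins) - 1L,
                                function(s, b) sprintf("bin%02d_%s", b, s)))
  out
}
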
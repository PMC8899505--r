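# Substructure-based molecular comparison: maximum common (dis)connected
# substructure, Tanimoto/Tversky indices, substructure containment, RMSD and
# symmetry-corrected RMSD, Kabsch superposition and scaffold alignment.
# Hydrogens are excluded from all substructure comparisons.

#' Comparison type configuration
#'
#' Defines the equivalence classes used for atom and bond matching in
#' substructure comparisons. At `ElementType` resolution any two carbons
#' match; at `AtomType` resolution an sp3 carbon only matches another sp3
#' carbon. Bond levels range from exact order matching to aromatic- and
#' ring-aware matching.
#'
#' @param atom_level `"ElementType"` or `"AtomType"`.
#' @param bond_level one of `"BondOrder"`, `"BondOrderOrAromatic"`,
#'   `"BondOrderAmideWithIsometryOrAromaticWithRingness"`.
#' @return a `comparison_type` object.
#' @export
comparison_type <- function(atom_level = c("ElementType", "AtomType"),
                            bond_level = c("BondOrderOrAromatic", "BondOrder",
                              "BondOrderAmideWithIsometryOrAromaticWithRingness")) {
  structure(list(atom_level = match.arg(atom_level),
                 bond_level = match.arg(bond_level)),
            class = "comparison_type")
}

# integer bond-code matrix under a bond comparison level (0 = no bond)
bond_code_matrix <- function(mol, bond_level) {
  n <- n_atoms(mol)
  m <- matrix(0L, n, n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    code <- switch(bond_level,
      BondOrder = b$order[k],
      BondOrderOrAromatic = if (b$aromatic[k]) 4L else b$order[k],
      BondOrderAmideWithIsometryOrAromaticWithRingness =
        if (b$aromatic[k]) 400L + as.integer(b$in_ring[k])
        else b$order[k] * 10L + as.integer(b$in_ring[k]) +
             100L * as.integer(b$amide[k]) +
             1000L * match(b$stereo[k], c("none", "E", "Z")))
    m[b$a1[k], b$a2[k]] <- code
    m[b$a2[k], b$a1[k]] <- code
  }
  m
}

# atom descriptor strings under an atom comparison level
atom_keys <- function(mol, atom_level) {
  el <- mol$atoms$element
  if (atom_level == "ElementType") return(el)
  adj <- adjacency(mol)
  hyb <- vapply(seq_len(n_atoms(mol)), function(i) {
    a <- adj[[i]]
    if (mol$atoms$aromatic[i]) return("sp2")
    nd <- sum(a$order == 2L)
    if (any(a$order >= 3L) || nd >= 2L) return("sp")
    if (nd == 1L) return("sp2")
    "sp3"
  }, character(1))
  paste(el, hyb)
}

atom_compat_matrix <- function(molA, molB, cmp) {
  outer(atom_keys(molA, cmp$atom_level), atom_keys(molB, cmp$atom_level), "==")
}

#' Maximum common substructure of two molecules
#'
#' Finds a maximum-cardinality common subgraph by branch-and-bound maximum
#' clique search on the modular product graph. Hydrogens are ignored.
#'
#' @param molA,molB molecules.
#' @param cmp a [comparison_type()]; the default is ElementType atoms with
#'   BondOrderOrAromatic bonds.
#' @param connected require a single connected common substructure
#'   (`TRUE`, default) or allow a disconnected union of common pieces.
#' @param budget maximum number of search-tree expansions before aborting.
#' @return an `mcs_result`: list with `mapping` (two-column matrix of heavy
#'   atom indices in A and B), `size`, `size_a`, `size_b` (heavy-atom counts)
#'   and `connected`.
#' @export
mcs <- function(molA, molB, cmp = comparison_type(), connected = TRUE,
                budget = 1e7) {
  hA <- remove_hydrogens(molA)
  hB <- remove_hydrogens(molB)
  res <- if (connected) mcs_heavy(hA, hB, cmp, connected = TRUE,
                                  budget = budget)
         else mcds_heavy(hA, hB, cmp, budget)
  map <- res$mapping
  if (nrow(map)) {
    map[, 1] <- heavy_atoms(molA)[map[, 1]]
    map[, 2] <- heavy_atoms(molB)[map[, 2]]
  }
  structure(list(mapping = map, size = res$size,
                 size_a = n_atoms(hA), size_b = n_atoms(hB),
                 connected = connected),
            class = "mcs_result")
}

# maximum common disconnected substructure: iterated connected-MCS extraction.
# Matched atoms are removed from both molecules and the connected search is
# repeated on the leftovers (pieces may be single atoms) until either leftover
# graph has fewer than two atoms or no common piece remains. The first piece
# is the connected MCS itself, so the disconnected size is never smaller.
mcds_heavy <- function(hA, hB, cmp, budget) {
  aliveA <- seq_len(n_atoms(hA))
  aliveB <- seq_len(n_atoms(hB))
  maps <- list()
  total <- 0L
  repeat {
    if (length(aliveA) < 2L || length(aliveB) < 2L) break
    piece <- mcs_heavy(extract_atoms(hA, aliveA), extract_atoms(hB, aliveB),
                       cmp, connected = TRUE, budget = budget)
    if (piece$size == 0L) break
    m <- piece$mapping
    m[, 1] <- aliveA[m[, 1]]
    m[, 2] <- aliveB[m[, 2]]
    maps[[length(maps) + 1L]] <- m
    total <- total + piece$size
    aliveA <- setdiff(aliveA, m[, 1])
    aliveB <- setdiff(aliveB, m[, 2])
  }
  mapping <- if (length(maps)) do.call(rbind, maps) else matrix(integer(), 0, 2)
  list(size = total, mapping = mapping, truncated = FALSE)
}

# McSplit partition search on already hydrogen-free molecules. The
# disconnected variant is the unconstrained maximum common induced subgraph
# (a union of disjoint common pieces, single atoms included).
mcs_heavy <- function(hA, hB, cmp, connected, budget) {
  codeA <- bond_code_matrix(hA, cmp$bond_level)
  codeB <- bond_code_matrix(hB, cmp$bond_level)
  keysA <- atom_keys(hA, cmp$atom_level)
  keysB <- atom_keys(hB, cmp$atom_level)
  lev <- unique(c(keysA, keysB))
  res <- .cpp_mcsplit(codeA, codeB, match(keysA, lev), match(keysB, lev),
                      connected, budget)
  if (res$truncated)
    stop("substructure search exceeded its resource cap; lower the atom/bond ",
         "resolution or raise `budget`")
  res
}

#' Tanimoto and Tversky similarity from a common-substructure result
#'
#' The Tanimoto coefficient is the ratio of matched to unmatched heavy atoms,
#' `|A^B| / (|A| + |B| - |A^B|)`. The Tversky index generalizes it with
#' asymmetric weights on the unmatched parts:
#' `|A^B| / (|A^B| + alpha (|A|-|A^B|) + beta (|B|-|A^B|))`;
#' `tversky(res, 1, 1)` equals `tanimoto(res)`.
#'
#' @param result an `mcs_result` from [mcs()].
#' @param alpha,beta Tversky weights on the atoms unique to A and B.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(result) tversky(result, 1, 1)

#' @rdname tanimoto
#' @export
tversky <- function(result, alpha = 1, beta = 1) {
  if (result$size_a == 0L && result$size_b == 0L)
    stop("both molecules are empty")
  i <- result$size
  i / (i + alpha * (result$size_a - i) + beta * (result$size_b - i))
}

#' Test whether a molecule contains a query substructure
#'
#' @param mol target molecule.
#' @param query query molecule (heavy atoms compared).
#' @param cmp a [comparison_type()].
#' @return `TRUE` iff a subgraph-isomorphic embedding of the query into the
#'   molecule exists under the comparison types.
#' @export
contains_substructure <- function(mol, query, cmp = comparison_type()) {
  hM <- remove_hydrogens(mol)
  hQ <- remove_hydrogens(query)
  if (n_atoms(hQ) > n_atoms(hM)) return(FALSE)
  if (n_atoms(hQ) == 0L) return(TRUE)
  codeQ <- bond_code_matrix(hQ, cmp$bond_level)
  codeT <- bond_code_matrix(hM, cmp$bond_level)
  compat <- atom_compat_matrix(hQ, hM, cmp)
  res <- .cpp_monomorphisms(codeQ, codeT, compat, FALSE, 1L, 5e6)
  length(res$mappings) > 0L
}

# All isomorphisms between two constitutionally identical heavy-atom graphs.
# Aromatic-aware bond codes so that kekule forms do not split ring symmetry
# (a benzene rotated by 60 degrees must map onto itself).
enumerate_isomorphisms <- function(hA, hB, max_count = 5000L) {
  cmp <- comparison_type("ElementType", "BondOrderOrAromatic")
  codeA <- bond_code_matrix(hA, cmp$bond_level)
  codeB <- bond_code_matrix(hB, cmp$bond_level)
  compat <- atom_compat_matrix(hA, hB, cmp)
  res <- .cpp_monomorphisms(codeA, codeB, compat, TRUE, max_count, 5e6)
  res$mappings
}

#' Coordinate RMSD between constitutionally identical molecules
#'
#' `rmsd()` compares poses in place using the identity atom order;
#' `symmetry_rmsd()` minimizes over graph automorphisms so that e.g. a benzene
#' rotated by 60 degrees about its C6 axis scores 0. No superposition is
#' applied.
#'
#' @param molA,molB molecules with the same heavy-atom constitution and 3D
#'   coordinates.
#' @param max_automorphisms cap on the automorphism enumeration; when
#'   exceeded, identity-order RMSD is returned with a warning.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(molA, molB) {
  xa <- coords(molA, heavy_only = TRUE)
  xb <- coords(molB, heavy_only = TRUE)
  if (nrow(xa) != nrow(xb))
    stop("molecules differ in heavy-atom count")
  check_same_constitution(molA, molB)
  sqrt(mean(rowSums((xa - xb)^2)))
}

#' @rdname rmsd
#' @export
symmetry_rmsd <- function(molA, molB, max_automorphisms = 5000L) {
  hA <- remove_hydrogens(molA)
  hB <- remove_hydrogens(molB)
  check_same_constitution(molA, molB)
  xa <- coords(hA)
  xb <- coords(hB)
  isos <- enumerate_isomorphisms(hA, hB, max_count = max_automorphisms)
  if (!length(isos)) stop("molecules are not constitutionally identical")
  if (length(isos) >= max_automorphisms) {
    warning("automorphism cap reached; falling back to identity-order RMSD")
    return(sqrt(mean(rowSums((xa - xb)^2))))
  }
  min(vapply(isos, function(map) {
    sqrt(mean(rowSums((xa - xb[map, , drop = FALSE])^2)))
  }, numeric(1)))
}

check_same_constitution <- function(molA, molB) {
  hA <- remove_hydrogens(molA)
  hB <- remove_hydrogens(molB)
  if (n_atoms(hA) != n_atoms(hB) ||
      !identical(sort(hA$atoms$element), sort(hB$atoms$element)) ||
      !length(enumerate_isomorphisms(hA, hB, max_count = 1L)))
    stop("molecules are not constitutionally identical")
  invisible(TRUE)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired point sets.
#'
#' @param coordsA,coordsB numeric matrices (n x 3), n >= 3, same n.
#' @return list with `rotation` (3x3, det +1), `translation` (length-3), and
#'   `rmsd` after the fit. Applying `X %*% t(rotation) + translation` maps B's
#'   frame onto A.
#' @export
kabsch_superimpose <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (nrow(coordsA) != nrow(coordsB) || nrow(coordsA) < 3L)
    stop("need equal point counts of at least 3")
  ca <- colMeans(coordsA); cb <- colMeans(coordsB)
  A <- sweep(coordsA, 2, ca); B <- sweep(coordsB, 2, cb)
  H <- t(B) %*% A
  sv <- svd(H)
  if (min(sv$d) < 1e-12 && sum(sv$d > 1e-12) < 2L)
    stop("rank-deficient point sets")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- B %*% t(R)
  list(rotation = R,
       translation = as.numeric(ca),
       rmsd = sqrt(mean(rowSums((fitted - A)^2))))
}

# apply a rigid transform (about centroids, Kabsch convention) to a molecule
transform_molecule <- function(mol, rotation, center_from, center_to) {
  x <- coords(mol)
  x <- sweep(x, 2, center_from)
  x <- x %*% t(rotation)
  x <- sweep(x, 2, center_to, "+")
  mol$atoms$x <- x[, 1]; mol$atoms$y <- x[, 2]; mol$atoms$z <- x[, 3]
  mol
}

#' Rigidly align molecules to a scaffold
#'
#' Each molecule is superimposed onto the scaffold over a set of paired atoms:
#' its maximum common substructure with the scaffold (`mode = "mcs"`), its MCS
#' with the scaffold's largest rigid component (`mode = "rigid"`; rigid
#' components arise from breaking non-ring, non-amide single bonds), or
#' user-supplied atom index lists (`mode = "explicit"`). The molecule's
#' internal geometry is unchanged.
#'
#' @param scaffold reference molecule with 3D coordinates.
#' @param mols list of molecules to transform.
#' @param mode `"mcs"`, `"rigid"`, or `"explicit"`.
#' @param cmp a [comparison_type()] for the MCS modes.
#' @param scaffold_atoms,mol_atoms equal-length atom index vectors for
#'   `mode = "explicit"`.
#' @return list of transformed molecules; molecules whose MCS with the
#'   scaffold has fewer than 3 atoms are returned untouched with a warning.
#' @export
align_to_scaffold <- function(scaffold, mols, mode = c("mcs", "rigid",
                                                       "explicit"),
                              cmp = comparison_type(),
                              scaffold_atoms = NULL, mol_atoms = NULL) {
  mode <- match.arg(mode)
  if (inherits(mols, "molecule")) mols <- list(mols)
  ref <- scaffold
  if (mode == "rigid") {
    frags <- split_molecules(scaffold, "Rigid")
    if (length(frags)) ref <- frags[[1]]
  }
  lapply(mols, function(mol) {
    if (mode == "explicit") {
      if (length(scaffold_atoms) != length(mol_atoms))
        stop("atom lists must have equal length")
      pa <- coords(scaffold)[scaffold_atoms, , drop = FALSE]
      pb <- coords(mol)[mol_atoms, , drop = FALSE]
    } else {
      res <- mcs(ref, mol, cmp = cmp, connected = TRUE)
      if (res$size < 3L) {
        warning("common substructure smaller than 3 atoms; molecule skipped")
        return(mol)
      }
      pa <- coords(ref)[res$mapping[, 1], , drop = FALSE]
      pb <- coords(mol)[res$mapping[, 2], , drop = FALSE]
    }
    fit <- kabsch_superimpose(pa, pb)
    transform_molecule(mol, fit$rotation, colMeans(pb), fit$translation)
  })
}

#' Pairwise molecule comparison matrices
#'
#' With one molecule set, all molecules are compared with one another; with
#' two sets, every molecule of `setB` is compared against every molecule of
#' `setA` (rows = `setB`, columns = `setA`).
#'
#' @param setA,setB lists of molecules (`setB` may be `NULL`).
#' @param method one of `"LargestCommonSubstructureTanimoto"`,
#'   `"LargestCommonDisconnectedSubstructureTanimoto"`, `"RMSD"`,
#'   `"SymmetryRMSD"`.
#' @param cmp a [comparison_type()] for the substructure methods.
#' @param threads accepted for interface compatibility; evaluation is serial
#'   and therefore independent of this value.
#' @return numeric score matrix; per-pair failures become `NA` with a warning.
#' @export
compare_ensembles <- function(setA, setB = NULL,
                              method = c("LargestCommonSubstructureTanimoto",
                                "LargestCommonDisconnectedSubstructureTanimoto",
                                "RMSD", "SymmetryRMSD"),
                              cmp = comparison_type(), threads = 1L) {
  method <- match.arg(method)
  if (inherits(setA, "molecule")) setA <- list(setA)
  if (inherits(setB, "molecule")) setB <- list(setB)
  pair_score <- function(a, b) {
    tryCatch(switch(method,
      LargestCommonSubstructureTanimoto =
        tanimoto(mcs(a, b, cmp, connected = TRUE)),
      LargestCommonDisconnectedSubstructureTanimoto =
        tanimoto(mcs(a, b, cmp, connected = FALSE)),
      RMSD = rmsd(a, b),
      SymmetryRMSD = symmetry_rmsd(a, b)),
      error = function(e) { warning(conditionMessage(e)); NA_real_ })
  }
  rows <- if (is.null(setB)) setA else setB
  out <- matrix(NA_real_, length(rows), length(setA))
  for (i in seq_along(rows)) for (j in seq_along(setA))
    out[i, j] <- pair_score(setA[[j]], rows[[i]])
  rownames(out) <- vapply(rows, function(m) m$name, character(1))
  colnames(out) <- vapply(setA, function(m) m$name, character(1))
  out
}
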
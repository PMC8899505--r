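# Molecule-level applications: filtering, duplicate removal at four comparison
# levels, property-based reordering, fragment splitting, and coordinate
# utilities.

#' Build a filter criterion
#'
#' @param kind `"property_compare"` (a descriptor compared to a threshold),
#'   `"contains_substructure"` / `"contains_fragments_from"` (query molecules
#'   matched as substructures), `"defined_atom_types"` (all valences valid),
#'   or `"simple_connectivity"` (single connected component).
#' @param property descriptor spec or text (for `property_compare`).
#' @param comparator one of `"less"`, `"less_equal"`, `"greater"`,
#'   `"greater_equal"`, `"equal"`.
#' @param threshold numeric threshold.
#' @param queries list of query molecules for the substructure kinds.
#' @param cmp a [comparison_type()] for substructure matching.
#' @return a `filter_criterion`.
#' @export
filter_criterion <- function(kind = c("property_compare",
                                      "contains_substructure",
                                      "contains_fragments_from",
                                      "defined_atom_types",
                                      "simple_connectivity"),
                             property = NULL, comparator = NULL,
                             threshold = NULL, queries = NULL,
                             cmp = comparison_type()) {
  kind <- match.arg(kind)
  if (kind == "property_compare") {
    stopifnot(!is.null(property), !is.null(comparator), !is.null(threshold))
    comparator <- match.arg(comparator, c("less", "less_equal", "greater",
                                          "greater_equal", "equal"))
    if (is.character(property)) property <- parse_descriptor(property)
  }
  if (kind %in% c("contains_substructure", "contains_fragments_from")) {
    if (inherits(queries, "molecule")) queries <- list(queries)
    stopifnot(length(queries) >= 1L)
  }
  structure(list(kind = kind, property = property, comparator = comparator,
                 threshold = threshold, queries = queries, cmp = cmp),
            class = "filter_criterion")
}

criterion_matches <- function(crit, mol) {
  switch(crit$kind,
    property_compare = {
      v <- evaluate_descriptor(crit$property, mol)
      if (length(v) != 1L) stop("filter property must evaluate to a scalar")
      switch(crit$comparator,
        less = v < crit$threshold,
        less_equal = v <= crit$threshold,
        greater = v > crit$threshold,
        greater_equal = v >= crit$threshold,
        equal = v == crit$threshold)
    },
    contains_substructure = ,
    contains_fragments_from =
      any(vapply(crit$queries, function(q)
        contains_substructure(mol, q, crit$cmp), logical(1))),
    defined_atom_types = length(validate_atom_types(mol)) == 0L,
    simple_connectivity = length(connected_components(mol)) == 1L)
}

#' Filter molecules by sequential criteria
#'
#' In `"all"` mode the criteria are applied sequentially and a molecule must
#' pass every one to be matched; the log records how many molecules each stage
#' eliminated among the survivors of the previous stages. In `"any"` mode a
#' molecule matching at least one criterion is matched.
#'
#' @param mols list of molecules.
#' @param criteria list of [filter_criterion()] objects (a single criterion is
#'   accepted).
#' @param mode `"all"` or `"any"`.
#' @return list with `matched`, `unmatched` (order preserved,
#'   `matched + unmatched = input`) and `log` (per-criterion counts; molecules
#'   whose descriptor evaluation fails are routed to `unmatched` and counted
#'   under `errors`).
#' @export
filter_molecules <- function(mols, criteria, mode = c("all", "any")) {
  mode <- match.arg(mode)
  if (inherits(criteria, "filter_criterion")) criteria <- list(criteria)
  stopifnot(length(criteria) >= 1L)
  n <- length(mols)
  nc <- length(criteria)
  pass <- matrix(NA, n, nc)
  errors <- integer(0)
  for (i in seq_len(n)) {
    for (k in seq_len(nc)) {
      ok <- tryCatch(criterion_matches(criteria[[k]], mols[[i]]),
                     error = function(e) NA)
      if (is.na(ok)) { errors <- c(errors, i); pass[i, ] <- FALSE; break }
      pass[i, k] <- ok
      if (mode == "all" && !ok) { pass[i, seq_len(nc) > k] <- NA; break }
    }
  }
  keep <- if (mode == "all") apply(pass, 1, function(r) all(r %in% TRUE))
          else apply(pass, 1, function(r) any(r %in% TRUE))
  removed_at_stage <- vapply(seq_len(nc), function(k)
    sum(pass[, k] %in% FALSE &
        (k == 1L | apply(pass[, seq_len(k - 1L), drop = FALSE], 1,
                         function(r) all(r %in% TRUE)))), integer(1))
  list(matched = mols[keep], unmatched = mols[!keep],
       log = list(mode = mode, removed_at_stage = removed_at_stage,
                  matched = sum(keep), unmatched = sum(!keep),
                  errors = length(unique(errors))))
}

# ---- uniqueness -------------------------------------------------------------

# Morgan-style iterative refinement labels on the heavy-atom graph; bond
# aromaticity folds kekule forms together
refinement_labels <- function(hm, rounds = NULL) {
  n <- n_atoms(hm)
  if (n == 0L) return(character(0))
  adj <- adjacency(hm)
  bcode <- ifelse(hm$bonds$aromatic, 4L, hm$bonds$order)
  lab <- paste(hm$atoms$element, hm$atoms$charge, sep = "|")
  rounds <- rounds %||% (n + 1L)
  for (r in seq_len(rounds)) {
    lab2 <- vapply(seq_len(n), function(i) {
      a <- adj[[i]]
      nb <- sort(paste(bcode[a$bond], lab[a$nbr], sep = ":"))
      paste(lab[i], paste(nb, collapse = ";"), sep = "<")
    }, character(1))
    # re-encode to keep strings short
    lab2 <- as.character(match(lab2, sort(unique(lab2))))
    if (length(unique(lab2)) == length(unique(lab))) { lab <- lab2; break }
    lab <- lab2
  }
  lab
}

constitution_key <- function(mol) {
  hm <- remove_hydrogens(mol)
  lab <- refinement_labels(hm)
  paste(sort(paste(hm$atoms$element, hm$atoms$charge, lab, sep = "/")),
        collapse = ",")
}

# stereo descriptors perceived from 3D coordinates: tetrahedral parities and
# double-bond E/Z, keyed by canonical refinement rank
stereo_key <- function(mol) {
  hm <- remove_hydrogens(mol)
  n <- n_atoms(hm)
  if (n < 3L || all(coords(hm) == 0)) return("")
  lab <- refinement_labels(hm)
  adj <- adjacency(hm)
  x <- coords(hm)
  parities <- character(0)
  for (i in seq_len(n)) {
    nbrs <- adj[[i]]$nbr
    if (length(nbrs) < 3L) next
    r <- lab[nbrs]
    if (anyDuplicated(r)) next     # symmetric neighbours: no parity
    o <- nbrs[order(as.integer(r))]
    v1 <- x[o[1], ] - x[i, ]; v2 <- x[o[2], ] - x[i, ]; v3 <- x[o[3], ] - x[i, ]
    s <- sign(det(cbind(v1, v2, v3)))
    parities <- c(parities, paste0(lab[i], ":", if (s > 0) "R" else "S"))
  }
  ez <- character(0)
  b <- hm$bonds
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 2L || b$in_ring[k]) next
    i <- b$a1[k]; j <- b$a2[k]
    ni <- setdiff(adj[[i]]$nbr, j); nj <- setdiff(adj[[j]]$nbr, i)
    if (!length(ni) || !length(nj)) next
    hi <- ni[order(as.integer(lab[ni]))][1]
    hj <- nj[order(as.integer(lab[nj]))][1]
    ang <- dihedral_angle(x[hi, ], x[i, ], x[j, ], x[hj, ])
    tag <- if (abs(ang) < pi / 2) "Z" else "E"
    ez <- c(ez, paste0(sort(c(lab[i], lab[j]))[1], "=",
                       sort(c(lab[i], lab[j]))[2], ":", tag))
  }
  paste(c(sort(parities), sort(ez)), collapse = ",")
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

molecule_level_key <- function(mol, level) {
  switch(level,
    Constitutions = constitution_key(mol),
    Configurations = paste(constitution_key(mol), stereo_key(mol), sep = "#"),
    Conformations = paste(constitution_key(mol), stereo_key(mol), sep = "#"),
    Exact = paste(format_sdf_record(mol), collapse = "\n"))
}

same_at_level <- function(a, b, level, key_a, key_b) {
  if (key_a != key_b) return(FALSE)
  if (level == "Exact") return(TRUE)
  ha <- remove_hydrogens(a); hb <- remove_hydrogens(b)
  if (n_atoms(ha) != n_atoms(hb)) return(FALSE)
  iso <- length(enumerate_isomorphisms(ha, hb, max_count = 1L)) > 0L
  if (!iso) return(FALSE)
  if (level != "Conformations") return(TRUE)
  # conformer identity: best-match RMSD after superposition below tolerance
  isos <- enumerate_isomorphisms(ha, hb)
  xa <- coords(ha); xb <- coords(hb)
  any(vapply(isos, function(map) {
    fit <- tryCatch(kabsch_superimpose(xa, xb[map, , drop = FALSE]),
                    error = function(e) list(rmsd = Inf))
    fit$rmsd < 1e-4
  }, logical(1)))
}

#' Remove duplicate molecules
#'
#' The first encounter of each molecule (at the chosen comparison level) is
#' kept; later encounters are routed to `dupes`. Comparison levels:
#' `Constitutions` (atom identities and connectivity, stereo ignored),
#' `Configurations` (adds stereochemistry perceived from coordinates),
#' `Conformations` (adds 3D identity via best-match RMSD under 1e-4 Angstrom
#' after superposition), `Exact` (field-wise record equality).
#'
#' @param mols list of molecules.
#' @param level comparison level.
#' @param dupes_policy `"first"` keeps the first record's properties; with
#'   `"merge"` all distinct duplicate properties are copied onto the kept
#'   record (first value wins on conflict); with `"overwrite"` the last value
#'   wins.
#' @return list with `unique` (first encounters, input order) and `dupes`.
#' @export
unique_molecules <- function(mols, level = c("Constitutions", "Configurations",
                                             "Conformations", "Exact"),
                             dupes_policy = c("first", "merge", "overwrite")) {
  level <- match.arg(level)
  dupes_policy <- match.arg(dupes_policy)
  if (level %in% c("Conformations", "Exact")) {
    no3d <- vapply(mols, function(m) all(coords(m) == 0) && n_atoms(m) > 1L,
                   logical(1))
    if (any(no3d))
      stop("level ", level, " requires 3D coordinates (molecule ",
           which(no3d)[1], " has none)")
  }
  kept <- list(); keys <- character(); dupes <- list()
  for (mol in mols) {
    key <- molecule_level_key(mol, level)
    hit <- 0L
    for (j in which(keys == key)) {
      if (same_at_level(kept[[j]], mol, level, keys[j], key)) { hit <- j; break }
    }
    if (hit == 0L) {
      kept[[length(kept) + 1L]] <- mol
      keys <- c(keys, key)
    } else {
      dupes[[length(dupes) + 1L]] <- mol
      if (dupes_policy == "merge") {
        for (p in names(mol$properties))
          if (is.null(kept[[hit]]$properties[[p]]))
            kept[[hit]]$properties[[p]] <- mol$properties[[p]]
      } else if (dupes_policy == "overwrite") {
        for (p in names(mol$properties))
          kept[[hit]]$properties[[p]] <- mol$properties[[p]]
      }
    }
  }
  list(unique = kept, dupes = dupes)
}

# ---- reorder ----------------------------------------------------------------

#' Sort molecules by a descriptor
#'
#' Stable sort, ascending by default (`reverse` sorts largest first), with an
#' optional cap on how many molecules are returned.
#'
#' @param mols list of molecules.
#' @param sort_key descriptor spec or text evaluating to a scalar.
#' @param reverse sort descending.
#' @param output_max return at most this many molecules.
#' @return reordered (possibly truncated) list.
#' @export
reorder_molecules <- function(mols, sort_key, reverse = FALSE,
                              output_max = NULL) {
  if (is.character(sort_key)) sort_key <- parse_descriptor(sort_key)
  keys <- vapply(mols, function(m) {
    v <- evaluate_descriptor(sort_key, m)
    if (length(v) != 1L) stop("sort key must evaluate to a scalar")
    v
  }, numeric(1))
  ord <- order(keys, decreasing = reverse)
  out <- mols[ord]
  if (!is.null(output_max)) out <- head(out, output_max)
  out
}

# ---- splitting --------------------------------------------------------------

ring_atom_flags <- function(hm) {
  flags <- logical(n_atoms(hm))
  b <- hm$bonds
  for (k in which(b$in_ring)) flags[c(b$a1[k], b$a2[k])] <- TRUE
  flags
}

murcko_scaffold_atoms <- function(hm) {
  n <- n_atoms(hm)
  if (n == 0L) return(integer(0))
  inring <- ring_atom_flags(hm)
  if (!any(inring)) return(integer(0))
  alive <- rep(TRUE, n)
  b <- hm$bonds
  repeat {
    deg <- integer(n)
    for (k in seq_len(nrow(b))) if (alive[b$a1[k]] && alive[b$a2[k]]) {
      deg[b$a1[k]] <- deg[b$a1[k]] + 1L
      deg[b$a2[k]] <- deg[b$a2[k]] + 1L
    }
    # prune terminal non-ring atoms, keeping atoms double-bonded to a ring atom
    # (ring carbonyls and the like stay on the scaffold)
    prune <- which(alive & !inring & deg <= 1L)
    prune <- prune[!vapply(prune, function(i) {
      any(vapply(seq_len(nrow(b)), function(k) {
        alive[b$a1[k]] && alive[b$a2[k]] && b$order[k] >= 2L &&
          ((b$a1[k] == i && inring[b$a2[k]]) ||
           (b$a2[k] == i && inring[b$a1[k]]))
      }, logical(1)))
    }, logical(1))]
    if (!length(prune)) break
    alive[prune] <- FALSE
  }
  which(alive)
}

#' Split a molecule into fragments
#'
#' @param mol a `molecule`.
#' @param implementation one of `"Scaffolds"` (Murcko framework),
#'   `"InverseScaffold"` (what remains once the scaffold is removed),
#'   `"Rings"` (ring systems), `"Chains"` (non-ring components), `"Isolate"`
#'   (connected components), `"Largest"` (largest component by weight),
#'   `"Rigid"` (components after breaking non-ring, non-amide single bonds),
#'   `"LargestCommonSubstructure"` (MCS fragments against `reference`).
#' @param reference molecule or list of molecules for
#'   `LargestCommonSubstructure`.
#' @param cmp a [comparison_type()] for the MCS implementation.
#' @return list of fragment molecules (heavy atoms; possibly empty, e.g.
#'   Scaffolds of an acyclic molecule).
#' @export
split_molecules <- function(mol, implementation = c("Scaffolds",
                              "InverseScaffold", "Rings", "Chains", "Isolate",
                              "Largest", "Rigid",
                              "LargestCommonSubstructure"),
                            reference = NULL, cmp = comparison_type()) {
  implementation <- match.arg(implementation)
  hm <- remove_hydrogens(mol)
  components_of <- function(keep) {
    if (!length(keep)) return(list())
    connected_components(extract_atoms(hm, keep))
  }
  switch(implementation,
    Scaffolds = {
      sc <- murcko_scaffold_atoms(hm)
      if (!length(sc)) list() else list(extract_atoms(hm, sc))
    },
    InverseScaffold = {
      sc <- murcko_scaffold_atoms(hm)
      components_of(setdiff(seq_len(n_atoms(hm)), sc))
    },
    Rings = components_of(which(ring_atom_flags(hm))),
    Chains = components_of(which(!ring_atom_flags(hm))),
    Isolate = connected_components(hm),
    Largest = connected_components(hm)[1],
    Rigid = {
      b <- hm$bonds
      cut <- b$order == 1L & !b$in_ring & !b$amide
      m2 <- hm
      m2$bonds <- b[!cut, , drop = FALSE]
      connected_components(molecule(hm$name, m2$atoms, m2$bonds,
                                    hm$properties))
    },
    LargestCommonSubstructure = {
      if (is.null(reference)) stop("LargestCommonSubstructure needs a reference")
      if (inherits(reference, "molecule")) reference <- list(reference)
      lapply(reference, function(ref) {
        res <- mcs(hm, ref, cmp = cmp, connected = TRUE)
        extract_atoms(hm, res$mapping[, 1])
      })
    })
}

# ---- coordinates ------------------------------------------------------------

#' Molecular centroid and recentering
#'
#' The centroid is the unweighted mean of the atom coordinates. `recenter()`
#' translates each molecule so its centroid is the origin.
#'
#' @param mol a `molecule`; `mols` a list of molecules.
#' @return `centroid()`: length-3 numeric vector; `recenter()`: list of
#'   translated molecules.
#' @export
centroid <- function(mol) {
  if (n_atoms(mol) == 0L) stop("molecule has no atoms")
  x <- coords(mol)
  if (all(x == 0) && n_atoms(mol) > 1L)
    stop("molecule ", sQuote(mol$name), " has no coordinates")
  colMeans(x)
}

#' @rdname centroid
#' @export
recenter <- function(mols) {
  single <- inherits(mols, "molecule")
  if (single) mols <- list(mols)
  out <- lapply(mols, function(m) {
    ctr <- centroid(m)
    m$atoms$x <- m$atoms$x - ctr[1]
    m$atoms$y <- m$atoms$y - ctr[2]
    m$atoms$z <- m$atoms$z - ctr[3]
    m
  })
  if (single) out[[1]] else out
}
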
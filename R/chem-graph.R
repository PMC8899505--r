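# Molecular graph data model and standardization.
#
# A molecule is a simple graph: atoms are nodes (element, formal charge,
# coordinates, aromatic flag), bonds are edges (kekule order 1/2/3 plus an
# aromatic flag, ring membership, amide flag, E/Z stereo). Bond orders are
# always stored kekulized; aromaticity lives in the flags, so writing a
# valence-explicit SDF never requires re-kekulization.

#' Construct a molecule graph
#'
#' @param name molecule name (SDF title line).
#' @param atoms data frame with columns `element`, `charge`, `x`, `y`, `z`,
#'   `aromatic`. Missing columns are filled with defaults.
#' @param bonds data frame with columns `a1`, `a2`, `order`, and optionally
#'   `aromatic`, `in_ring`, `amide`, `stereo`. Atom indices are 1-based.
#' @param properties named list of MDL data-block properties (character
#'   values), order preserved.
#' @param perceive if `TRUE` (default) ring membership, aromaticity and amide
#'   bonds are perceived on construction.
#' @return an object of class `molecule`.
#' @export
molecule <- function(name = "", atoms, bonds = NULL, properties = list(),
                     perceive = TRUE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  for (cc in c("x", "y", "z")) if (is.null(atoms[[cc]])) atoms[[cc]] <- 0
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  atoms <- atoms[, c("element", "charge", "x", "y", "z", "aromatic")]
  atoms$element <- as.character(atoms$element)
  atoms$charge <- as.integer(atoms$charge)
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer(),
                        aromatic = logical(), in_ring = logical(),
                        amide = logical(), stereo = character(),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
    if (is.null(bonds$in_ring)) bonds$in_ring <- FALSE
    if (is.null(bonds$amide)) bonds$amide <- FALSE
    if (is.null(bonds$stereo)) bonds$stereo <- "none"
    bonds <- bonds[, c("a1", "a2", "order", "aromatic", "in_ring", "amide",
                       "stereo")]
    bonds$a1 <- as.integer(bonds$a1)
    bonds$a2 <- as.integer(bonds$a2)
    bonds$order <- as.integer(bonds$order)
  }
  mol <- structure(list(name = name, atoms = atoms, bonds = bonds,
                        properties = properties),
                   class = "molecule")
  check_molecule(mol)
  if (perceive) mol <- perceive_molecule(mol)
  mol
}

check_molecule <- function(mol) {
  n <- nrow(mol$atoms)
  b <- mol$bonds
  if (nrow(b)) {
    if (any(b$a1 < 1L | b$a1 > n | b$a2 < 1L | b$a2 > n))
      stop("bond endpoints reference non-existent atoms")
    if (any(b$a1 == b$a2)) stop("self-bonds are not allowed")
    key <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
    if (anyDuplicated(key)) stop("duplicate bond between an atom pair")
  }
  if (any(!is.finite(as.matrix(mol$atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  invisible(mol)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms (%d heavy), %d bonds, %d properties\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              nrow(x$atoms), length(heavy_atoms(x)), nrow(x$bonds),
              length(x$properties)))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `molecule`.
#' @return integer count of explicit atoms.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Indices of heavy (non-hydrogen) atoms
#' @param mol a `molecule`.
#' @return integer vector of atom indices.
#' @export
heavy_atoms <- function(mol) which(mol$atoms$element != "H")

#' Atom coordinates as a matrix
#' @param mol a `molecule`.
#' @param heavy_only drop hydrogens.
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(mol, heavy_only = FALSE) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  if (heavy_only) m <- m[heavy_atoms(mol), , drop = FALSE]
  m
}

# ---- element data -----------------------------------------------------------

# standard atomic weights (CIAAW 2021, abridged)
.ELEMENT_MASS <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Zn = 65.38, Se = 78.971, Br = 79.904, I = 126.90)

# base valence sets per element; charge adjustments applied in allowed_valences
.ELEMENT_VALENCE <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), Cl = 1L, Se = c(2L, 4L, 6L), Br = 1L, I = 1L,
  Li = 1L, Na = 1L, K = 1L, Mg = 2L, Ca = 2L, Zn = 2L, Al = 3L)

element_mass <- function(element) {
  m <- .ELEMENT_MASS[element]
  if (anyNA(m)) stop("unknown element(s): ",
                     paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

# Allowed valences for an element given its formal charge. Group 15 and 16
# elements gain/lose a bonding site with charge (N+ -> 4, N- -> 2, O- -> 1,
# O+ -> 3); boron inverts (B- -> 4); carbon loses one either way (C+/-: 3).
allowed_valences <- function(element, charge = 0L) {
  base <- .ELEMENT_VALENCE[[element]]
  if (is.null(base)) return(NULL)
  if (charge == 0L) return(base)
  v <- switch(element,
    N = , P = , As = base + charge,
    O = , S = , Se = base + charge,
    B = base - charge,
    C = base - abs(charge),
    base)
  v <- v[v >= 0L]
  if (!length(v)) NULL else v
}

# ---- graph helpers ----------------------------------------------------------

# adjacency list: for each atom, data frame of (nbr, order, bond index)
adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(nbr = integer(), order = integer(),
                                         bond = integer())
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$a1[k]; j <- b$a2[k]
    adj[[i]]$nbr <- c(adj[[i]]$nbr, j)
    adj[[i]]$order <- c(adj[[i]]$order, b$order[k])
    adj[[i]]$bond <- c(adj[[i]]$bond, k)
    adj[[j]]$nbr <- c(adj[[j]]$nbr, i)
    adj[[j]]$order <- c(adj[[j]]$order, b$order[k])
    adj[[j]]$bond <- c(adj[[j]]$bond, k)
  }
  adj
}

# sum of kekule bond orders per atom (explicit neighbours only)
bond_order_sums <- function(mol) {
  n <- n_atoms(mol)
  s <- integer(n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    s[b$a1[k]] <- s[b$a1[k]] + b$order[k]
    s[b$a2[k]] <- s[b$a2[k]] + b$order[k]
  }
  s
}

# implicit hydrogen count per atom: fill to the smallest allowed valence that
# accommodates the explicit bond-order sum
implicit_h_counts <- function(mol) {
  s <- bond_order_sums(mol)
  vapply(seq_len(n_atoms(mol)), function(i) {
    el <- mol$atoms$element[i]
    if (el == "H") return(0L)
    v <- allowed_valences(el, mol$atoms$charge[i])
    if (is.null(v)) return(0L)
    v <- v[v >= s[i]]
    if (!length(v)) 0L else as.integer(min(v) - s[i])
  }, integer(1))
}

#' Connected components of a molecule
#'
#' Splits a multi-part record (e.g. a salt) into its connected parts.
#'
#' @param mol a `molecule`.
#' @return list of `molecule` objects, largest (by atom count, ties by
#'   molecular weight) first.
#' @export
connected_components <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(list())
  comp <- component_labels(mol)
  ids <- unique(comp)
  mols <- lapply(ids, function(id) extract_atoms(mol, which(comp == id)))
  sizes <- vapply(mols, n_atoms, integer(1))
  wts <- vapply(mols, function(m) sum(element_mass(m$atoms$element)), numeric(1))
  mols[order(-sizes, -wts)]
}

component_labels <- function(mol) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]$nbr) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

# sub-molecule induced on a set of atom indices (bonds inside the set kept)
extract_atoms <- function(mol, keep) {
  keep <- sort(unique(as.integer(keep)))
  map <- integer(n_atoms(mol))
  map[keep] <- seq_along(keep)
  b <- mol$bonds
  bk <- b[b$a1 %in% keep & b$a2 %in% keep, , drop = FALSE]
  bk$a1 <- map[bk$a1]; bk$a2 <- map[bk$a2]
  molecule(mol$name, mol$atoms[keep, , drop = FALSE], bk, mol$properties)
}

# ---- ring perception --------------------------------------------------------

# smallest set of smallest rings; returns list(rings = list of atom-index
# vectors, ring_bonds = logical per bond)
sssr <- function(mol) {
  n <- n_atoms(mol)
  b <- mol$bonds
  nb <- nrow(b)
  if (nb == 0L) return(list(rings = list(), ring_bonds = logical(0)))
  adj <- adjacency(mol)
  # a bond is a ring bond iff its endpoints stay connected without it
  ring_bonds <- vapply(seq_len(nb), function(k) {
    src <- b$a1[k]; dst <- b$a2[k]
    seen <- logical(n); seen[src] <- TRUE; queue <- src
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      a <- adj[[v]]
      for (m in seq_along(a$nbr)) {
        w <- a$nbr[m]
        if (a$bond[m] == k || seen[w]) next
        if (w == dst) return(TRUE)
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
    FALSE
  }, logical(1))
  n_rings <- nb - n + length(unique(component_labels(mol)))
  if (n_rings <= 0L) return(list(rings = list(), ring_bonds = ring_bonds))
  # candidate rings: smallest cycle through every ring bond
  cands <- list()
  for (k in which(ring_bonds)) {
    path <- bfs_path(adj, b$a1[k], b$a2[k], skip_bond = k)
    if (is.null(path)) next
    cands[[length(cands) + 1L]] <- path
  }
  keyfun <- function(r) paste(sort(r), collapse = ",")
  cands <- cands[!duplicated(vapply(cands, keyfun, character(1)))]
  cands <- cands[order(lengths(cands))]
  # greedy GF(2)-independent selection over bond incidence vectors
  basis <- matrix(FALSE, nrow = 0, ncol = nb)
  rings <- list()
  for (r in cands) {
    if (length(rings) >= n_rings) break
    vec <- ring_bond_vector(r, b)
    red <- vec
    if (nrow(basis)) for (i in seq_len(nrow(basis))) {
      piv <- which(basis[i, ])[1]
      if (red[piv]) red <- xor(red, basis[i, ])
    }
    if (any(red)) {
      basis <- rbind(basis, red)
      rings[[length(rings) + 1L]] <- r
    }
  }
  list(rings = rings, ring_bonds = ring_bonds)
}

# shortest alternative path a1 -> a2 avoiding one bond; returns ring atoms
bfs_path <- function(adj, src, dst, skip_bond) {
  n <- length(adj)
  prev <- integer(n)
  seen <- logical(n); seen[src] <- TRUE
  queue <- src
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    a <- adj[[v]]
    for (m in seq_along(a$nbr)) {
      w <- a$nbr[m]
      if (a$bond[m] == skip_bond || seen[w]) next
      prev[w] <- v
      if (w == dst) {
        path <- w
        while (path[1] != src) path <- c(prev[path[1]], path)
        return(path)
      }
      seen[w] <- TRUE
      queue <- c(queue, w)
    }
  }
  NULL
}

ring_bond_vector <- function(ring, bonds) {
  nb <- nrow(bonds)
  vec <- logical(nb)
  len <- length(ring)
  for (i in seq_len(len)) {
    u <- ring[i]; v <- ring[if (i == len) 1L else i + 1L]
    k <- which((bonds$a1 == u & bonds$a2 == v) | (bonds$a1 == v & bonds$a2 == u))
    if (length(k)) vec[k[1]] <- TRUE
  }
  vec
}

# bond indices around a ring (atom cycle)
ring_bond_indices <- function(ring, bonds) which(ring_bond_vector(ring, bonds))

# ---- aromaticity ------------------------------------------------------------

# Pi-electron contribution of one atom within a candidate aromatic ring, or NA
# when the atom breaks conjugation (sp3 centre, triple bond, exotic element).
pi_contribution <- function(mol, adj, i, ring, ring_atom_flags) {
  el <- mol$atoms$element[i]
  ch <- mol$atoms$charge[i]
  if (!el %in% c("C", "N", "O", "S", "P", "B", "Se")) return(NA_real_)
  a <- adj[[i]]
  if (any(a$order >= 3L)) return(NA_real_)
  dbl <- which(a$order == 2L)
  if (length(dbl) >= 2L) return(NA_real_)
  if (length(dbl) == 1L) {
    partner <- a$nbr[dbl]
    if (partner %in% ring) return(1)
    # exocyclic double bond: conjugated if the partner is any ring atom,
    # otherwise (e.g. a carbonyl oxygen) the centre contributes no electrons
    if (ring_atom_flags[partner]) return(1)
    return(0)
  }
  # no double bond: lone-pair donors contribute two electrons
  if (el %in% c("N", "P") && ch <= 0L) return(2)
  if (el %in% c("O", "S", "Se")) return(2)
  if (el == "C" && ch == -1L) return(2)
  if (el == "C" && ch == 1L) return(0)
  if (el == "B") return(0)
  NA_real_
}

#' Perceive ring membership and aromaticity
#'
#' Ring bonds are flagged from the smallest set of smallest rings; a ring (or
#' fused ring envelope) is marked aromatic when every member atom is
#' sp2-eligible and the ring pi-electron count satisfies the 4n+2 rule.
#' Amide bonds (C(=O)-N single bonds) are also flagged.
#'
#' @param mol a `molecule`.
#' @return the molecule with `aromatic`, `in_ring` and `amide` flags set.
#' @export
perceive_rings_and_aromaticity <- function(mol) {
  n <- n_atoms(mol)
  mol$atoms$aromatic <- logical(n)
  nb <- nrow(mol$bonds)
  mol$bonds$aromatic <- logical(nb)
  if (nb == 0L) return(mol)
  rp <- sssr(mol)
  mol$bonds$in_ring <- rp$ring_bonds
  adj <- adjacency(mol)
  ring_atom_flags <- logical(n)
  for (r in rp$rings) ring_atom_flags[r] <- TRUE
  set_aromatic <- function(mol, ring) {
    mol$atoms$aromatic[ring] <- TRUE
    mol$bonds$aromatic[ring_bond_indices(ring, mol$bonds)] <- TRUE
    mol
  }
  huckel <- function(ring) {
    pis <- vapply(ring, function(i)
      pi_contribution(mol, adj, i, ring, ring_atom_flags), numeric(1))
    if (anyNA(pis)) return(FALSE)
    tot <- sum(pis)
    tot >= 2 && (tot - 2) %% 4 == 0
  }
  failed <- list()
  for (ring in rp$rings) {
    if (huckel(ring)) mol <- set_aromatic(mol, ring)
    else failed[[length(failed) + 1L]] <- ring
  }
  # fused envelopes: union of remaining eligible rings sharing bonds
  if (length(failed) > 1L) {
    groups <- fuse_rings(failed)
    for (g in groups) {
      if (length(g) < 2L) next
      env <- unique(unlist(failed[g]))
      if (huckel(env)) {
        mol$atoms$aromatic[env] <- TRUE
        for (ri in g)
          mol$bonds$aromatic[ring_bond_indices(failed[[ri]], mol$bonds)] <- TRUE
      }
    }
  }
  mol$bonds$amide <- perceive_amide(mol, adj)
  mol
}

# group ring indices into fused systems (sharing >= 2 atoms)
fuse_rings <- function(rings) {
  k <- length(rings)
  if (k == 0L) return(list())
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k))
    if (length(intersect(rings[[i]], rings[[j]])) >= 2L)
      parent[find(j)] <- find(i)
  roots <- vapply(seq_len(k), find, integer(1))
  split(seq_len(k), roots)
}

perceive_amide <- function(mol, adj = adjacency(mol)) {
  b <- mol$bonds
  el <- mol$atoms$element
  vapply(seq_len(nrow(b)), function(k) {
    if (b$order[k] != 1L) return(FALSE)
    ij <- c(b$a1[k], b$a2[k])
    ci <- ij[el[ij] == "C"]; ni <- ij[el[ij] == "N"]
    if (length(ci) != 1L || length(ni) != 1L) return(FALSE)
    a <- adj[[ci]]
    any(a$order == 2L & el[a$nbr] == "O")
  }, logical(1))
}

perceive_molecule <- function(mol) {
  mol <- perceive_rings_and_aromaticity(mol)
  mol
}

# ---- kekulization -----------------------------------------------------------

#' Assign alternating bond orders to aromatic systems
#'
#' Bonds read with MDL order 4 (explicit aromatic) get definite single/double
#' orders via a matching over the atoms that require one double bond. Aromatic
#' nitrogens without an explicit hydrogen are assumed pyridine-type.
#'
#' @param mol a `molecule` possibly containing order-4 bonds.
#' @return the molecule with all bond orders in {1,2,3}.
#' @export
kekulize <- function(mol) {
  arom <- which(mol$bonds$order == 4L)
  if (!length(arom)) return(mol)
  atoms_in <- sort(unique(c(mol$bonds$a1[arom], mol$bonds$a2[arom])))
  adj <- adjacency(mol)
  el <- mol$atoms$element
  # does this atom need one double bond inside the aromatic system?
  needs <- vapply(atoms_in, function(i) {
    a <- adj[[i]]
    if (any(a$order == 2L)) return(FALSE)   # already has a double bond
    sigma <- sum(a$order[a$order != 4L]) + sum(a$order == 4L)
    h_exp <- sum(el[a$nbr] == "H")
    v <- allowed_valences(el[i], mol$atoms$charge[i])
    if (is.null(v)) return(FALSE)
    target <- min(v)
    switch(el[i],
      C = sigma < target,
      N = , P = (length(a$nbr) - h_exp) == 2L && h_exp == 0L,
      FALSE)                                 # O, S: lone-pair donors
  }, logical(1))
  need_atoms <- atoms_in[needs]
  # backtracking perfect matching on the aromatic subgraph restricted to atoms
  # needing a double bond
  bond_at <- function(i, j) {
    k <- arom[(mol$bonds$a1[arom] == i & mol$bonds$a2[arom] == j) |
              (mol$bonds$a1[arom] == j & mol$bonds$a2[arom] == i)]
    if (length(k)) k[1] else NA_integer_
  }
  matched <- stats::setNames(rep(NA_integer_, length(need_atoms)), need_atoms)
  assign_next <- function(matched) {
    left <- need_atoms[is.na(matched[as.character(need_atoms)])]
    if (!length(left)) return(matched)
    i <- left[1]
    nbrs <- adj[[i]]$nbr[adj[[i]]$order == 4L]
    for (j in intersect(nbrs, left[-1])) {
      m2 <- matched
      m2[as.character(i)] <- j
      m2[as.character(j)] <- i
      res <- assign_next(m2)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  res <- assign_next(matched)
  if (is.null(res))
    stop("cannot kekulize aromatic system over atoms ",
         paste(need_atoms, collapse = ", "))
  mol$bonds$order[arom] <- 1L
  for (i in need_atoms) {
    j <- res[[as.character(i)]]
    if (i < j) {
      k <- bond_at(i, j)
      mol$bonds$order[k] <- 2L
    }
  }
  perceive_molecule(mol)
}

# ---- hydrogens --------------------------------------------------------------

#' Saturate a molecule with explicit hydrogen atoms
#'
#' Every heavy atom receives explicit hydrogens filling its standard valence
#' (charge-adjusted) after accounting for its bond-order sum. Idempotent.
#'
#' @param mol a `molecule`.
#' @return the saturated molecule; added hydrogens are placed 1 A from the
#'   parent along arbitrary axes (geometry is bookkeeping only).
#' @export
add_hydrogens <- function(mol) {
  bad <- validate_atom_types(mol)
  if (length(bad))
    stop("cannot add hydrogens: atom(s) over valence: ",
         paste(bad, collapse = ", "))
  h <- implicit_h_counts(mol)
  if (!any(h > 0L)) return(mol)
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, 0, 0),
                c(0, -1, 0), c(0, 0, -1))
  new_atoms <- list(); new_bonds <- list()
  idx <- n_atoms(mol)
  for (i in which(h > 0L)) {
    for (m in seq_len(h[i])) {
      idx <- idx + 1L
      o <- offs[((m - 1L) %% 6L) + 1L, ]
      new_atoms[[length(new_atoms) + 1L]] <- data.frame(
        element = "H", charge = 0L,
        x = mol$atoms$x[i] + o[1], y = mol$atoms$y[i] + o[2],
        z = mol$atoms$z[i] + o[3], aromatic = FALSE,
        stringsAsFactors = FALSE)
      new_bonds[[length(new_bonds) + 1L]] <- data.frame(
        a1 = i, a2 = idx, order = 1L, aromatic = FALSE, in_ring = FALSE,
        amide = FALSE, stereo = "none", stringsAsFactors = FALSE)
    }
  }
  atoms <- rbind(mol$atoms, do.call(rbind, new_atoms))
  bonds <- rbind(mol$bonds, do.call(rbind, new_bonds))
  molecule(mol$name, atoms, bonds, mol$properties)
}

#' Remove explicit hydrogen atoms
#' @param mol a `molecule`.
#' @return the heavy-atom molecule.
#' @export
remove_hydrogens <- function(mol) {
  hv <- heavy_atoms(mol)
  if (length(hv) == n_atoms(mol)) return(mol)
  extract_atoms(mol, hv)
}

# ---- neutralization ---------------------------------------------------------

#' Remove formal charges where simple rules allow
#'
#' The default scheme changes protonation states (protonate anionic O/S,
#' deprotonate cationic N carrying a hydrogen) and resolves charge-separated
#' ylides by incrementing the bond order between adjacent +/- atoms when both
#' valences allow. Quaternary nitrogens and charge patterns with no removable
#' hydrogen or adjustable bond are left intact.
#'
#' @param mol a `molecule`.
#' @param scheme one of `"default"`, `"pH_only"` (protonation changes only),
#'   `"bond_order_only"`, `"none"`.
#' @return the (best-effort) neutralized molecule.
#' @export
neutralize <- function(mol, scheme = c("default", "pH_only",
                                       "bond_order_only", "none")) {
  scheme <- match.arg(scheme)
  if (scheme == "none") return(mol)
  adj <- adjacency(mol)
  el <- mol$atoms$element
  ch <- mol$atoms$charge
  impl <- implicit_h_counts(mol)
  drop_atoms <- integer()
  add_h_at <- integer()
  # bond-order adjustment for adjacent +/- pairs (ylides, nitro written as N+O-)
  if (scheme %in% c("default", "bond_order_only")) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      if (ch[i] * ch[j] >= 0L) next
      pos <- if (ch[i] > 0L) i else j
      neg <- if (ch[i] > 0L) j else i
      # skip nitro / N-oxide: N+ bonded to another O by a double bond
      if (el[pos] == "N") {
        a <- adj[[pos]]
        if (any(a$order == 2L & el[a$nbr] == "O")) next
      }
      # raising the bond order must keep both atoms within neutral valence
      s <- bond_order_sums(mol)
      ok_pos <- !is.null(allowed_valences(el[pos], 0L)) &&
        any(allowed_valences(el[pos], 0L) >= s[pos] + 1L)
      ok_neg <- !is.null(allowed_valences(el[neg], 0L)) &&
        any(allowed_valences(el[neg], 0L) >= s[neg] + 1L)
      if (ok_pos && ok_neg && mol$bonds$order[k] < 3L) {
        mol$bonds$order[k] <- mol$bonds$order[k] + 1L
        mol$atoms$charge[pos] <- ch[pos] - 1L
        mol$atoms$charge[neg] <- ch[neg] + 1L
        ch <- mol$atoms$charge
      }
    }
  }
  if (scheme %in% c("default", "pH_only")) {
    ch <- mol$atoms$charge
    for (i in seq_len(n_atoms(mol))) {
      if (ch[i] < 0L && el[i] %in% c("O", "S")) {
        # protonate: charge -> 0; hydrogen becomes implicit (or explicit if
        # the molecule carries explicit hydrogens elsewhere)
        mol$atoms$charge[i] <- ch[i] + 1L
        add_h_at <- c(add_h_at, i)
      } else if (ch[i] > 0L && el[i] == "N") {
        a <- adj[[i]]
        hs <- a$nbr[el[a$nbr] == "H"]
        if (length(hs)) {
          mol$atoms$charge[i] <- ch[i] - 1L
          drop_atoms <- c(drop_atoms, hs[1])
        } else if (impl[i] > 0L) {
          # implicit hydrogen removed by the charge change itself
          mol$atoms$charge[i] <- ch[i] - 1L
        }
      }
    }
  }
  has_explicit_h <- any(el == "H")
  if (length(drop_atoms))
    mol <- extract_atoms(mol, setdiff(seq_len(n_atoms(mol)), drop_atoms))
  if (has_explicit_h && length(add_h_at)) {
    # append explicit H for protonated sites so atom bookkeeping stays explicit
    for (i in add_h_at) {
      mol$atoms <- rbind(mol$atoms, data.frame(
        element = "H", charge = 0L, x = mol$atoms$x[i], y = mol$atoms$y[i],
        z = mol$atoms$z[i] + 1, aromatic = FALSE, stringsAsFactors = FALSE))
      mol$bonds <- rbind(mol$bonds, data.frame(
        a1 = i, a2 = nrow(mol$atoms), order = 1L, aromatic = FALSE,
        in_ring = FALSE, amide = FALSE, stereo = "none",
        stringsAsFactors = FALSE))
    }
  }
  perceive_molecule(mol)
}

# ---- atom-type validation ---------------------------------------------------

#' Find atoms with invalid valence
#'
#' @param mol a `molecule`.
#' @return integer vector of offending atom indices (empty when every atom's
#'   bond-order sum is consistent with its element/charge valence table).
#' @export
validate_atom_types <- function(mol) {
  s <- bond_order_sums(mol)
  bad <- integer()
  for (i in seq_len(n_atoms(mol))) {
    v <- allowed_valences(mol$atoms$element[i], mol$atoms$charge[i])
    if (is.null(v) || !any(v >= s[i])) bad <- c(bad, i)
  }
  bad
}
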
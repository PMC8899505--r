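# Shared fixtures for the test suite.

bm <- function(name) builtin_molecule(name)

# a geometrically exact benzene hexagon (bond length 1.39 A) in the xy plane
exact_benzene <- function(offset_deg = 0) {
  ang <- (seq_len(6) - 1L) * 60 + offset_deg
  atoms <- data.frame(element = "C", charge = 0L,
                      x = 1.39 * cospi(ang / 180),
                      y = 1.39 * sinpi(ang / 180),
                      z = 0, aromatic = FALSE)
  bonds <- data.frame(a1 = 1:6, a2 = c(2:6, 1L), order = c(2L, 1L))
  molecule("benzene_exact", atoms, bonds)
}

# tiny named linear molecule builder: elements chained by single bonds
chain_molecule <- function(elements, name = paste(elements, collapse = ""),
                           orders = rep(1L, length(elements) - 1L)) {
  n <- length(elements)
  atoms <- data.frame(element = elements, charge = 0L,
                      x = seq_len(n), y = 0, z = 0, aromatic = FALSE)
  bonds <- if (n > 1L)
    data.frame(a1 = seq_len(n - 1L), a2 = seq_len(n - 1L) + 1L,
               order = orders)
  molecule(name, atoms, bonds)
}

# rigid 3D rotation of a molecule about its centroid
rotate_molecule <- function(mol, axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  x <- coords(mol)
  ctr <- colMeans(x)
  xr <- sweep(sweep(x, 2, ctr) %*% t(R), 2, ctr, "+")
  mol$atoms$x <- xr[, 1]; mol$atoms$y <- xr[, 2]; mol$atoms$z <- xr[, 3]
  mol
}

# brute-force maximum clique on the modular product graph (independent oracle
# for the production McSplit search); connected variant included
oracle_mcs_size <- function(molA, molB, cmp = comparison_type(),
                            connected = TRUE) {
  hA <- remove_hydrogens(molA); hB <- remove_hydrogens(molB)
  codeA <- chemtk:::bond_code_matrix(hA, cmp$bond_level)
  codeB <- chemtk:::bond_code_matrix(hB, cmp$bond_level)
  compat <- chemtk:::atom_compat_matrix(hA, hB, cmp)
  res <- chemtk:::.cpp_mcs(codeA, codeB, compat, connected, 1e8)
  if (res$truncated) stop("oracle truncated")
  res$size
}
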
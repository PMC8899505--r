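# Whole-molecule scalar properties: weight, hydrogen-bond donors/acceptors,
# rotatable bonds, ring counts, TPSA, logP, and the Lipinski/Veber
# druglikeness counts built from them.

#' Molecular weight
#'
#' Sum of standard atomic weights including implicit hydrogens.
#' @param mol a `molecule`.
#' @return weight in Dalton.
#' @export
mol_weight <- function(mol) {
  sum(element_mass(mol$atoms$element)) +
    sum(implicit_h_counts(mol)) * .ELEMENT_MASS[["H"]]
}

#' Hydrogen bond donors and acceptors
#'
#' Donors are nitrogen or oxygen atoms carrying at least one hydrogen
#' (explicit or implicit, counted once per heavy atom); acceptors are all
#' nitrogen and oxygen atoms.
#' @param mol a `molecule`.
#' @return integer count.
#' @export
hbond_donors <- function(mol) {
  el <- mol$atoms$element
  impl <- implicit_h_counts(mol)
  adj <- adjacency(mol)
  sum(vapply(which(el %in% c("N", "O")), function(i) {
    impl[i] > 0L || any(el[adj[[i]]$nbr] == "H")
  }, logical(1)))
}

#' @rdname hbond_donors
#' @export
hbond_acceptors <- function(mol) sum(mol$atoms$element %in% c("N", "O"))

#' Rotatable bond count
#'
#' Non-ring single bonds between two heavy atoms each bonded to at least one
#' other heavy atom, excluding amide C-N bonds.
#' @param mol a `molecule`.
#' @return integer count.
#' @export
n_rotatable_bonds <- function(mol) {
  b <- mol$bonds
  el <- mol$atoms$element
  heavy_deg <- integer(n_atoms(mol))
  for (k in seq_len(nrow(b))) {
    if (el[b$a1[k]] != "H" && el[b$a2[k]] != "H") {
      heavy_deg[b$a1[k]] <- heavy_deg[b$a1[k]] + 1L
      heavy_deg[b$a2[k]] <- heavy_deg[b$a2[k]] + 1L
    }
  }
  sum(vapply(seq_len(nrow(b)), function(k) {
    b$order[k] == 1L && !b$in_ring[k] && !b$amide[k] &&
      el[b$a1[k]] != "H" && el[b$a2[k]] != "H" &&
      heavy_deg[b$a1[k]] >= 2L && heavy_deg[b$a2[k]] >= 2L
  }, logical(1)))
}

#' Ring counts
#'
#' `n_rings` is the smallest-set-of-smallest-rings count; `n_aromatic_rings`
#' counts SSSR rings whose bonds are all aromatic.
#' @param mol a `molecule`.
#' @return integer count.
#' @export
n_rings <- function(mol) length(sssr(mol)$rings)

#' @rdname n_rings
#' @export
n_aromatic_rings <- function(mol) {
  rp <- sssr(mol)
  sum(vapply(rp$rings, function(r) {
    all(mol$bonds$aromatic[ring_bond_indices(r, mol$bonds)])
  }, logical(1)))
}

#' Topological polar surface area
#'
#' Sum of the Ertl per-atom fragment contributions (see [atom_tpsa()]).
#' @param mol a `molecule`.
#' @return TPSA in square Angstrom.
#' @export
tpsa <- function(mol) sum(atom_tpsa(mol))

#' Atom-based logP estimate
#'
#' Mannhold's atom-count formula: `logP = 1.46 + 0.11 nC - 0.11 nHet`, where
#' `nC` is the number of carbon atoms and `nHet` the number of non-carbon,
#' non-hydrogen heavy atoms.
#' @param mol a `molecule`.
#' @return estimated water-octanol partition coefficient.
#' @export
log_p <- function(mol) {
  el <- mol$atoms$element
  1.46 + 0.11 * sum(el == "C") - 0.11 * sum(el != "C" & el != "H")
}

#' Lipinski and Veber druglikeness counts
#'
#' `lipinski_violations` counts failures of the rule of five: more than 5
#' hydrogen-bond donors, more than 10 acceptors, molecular weight of 500 Da or
#' more, logP of 5 or more (range 0-4). `lipinski_violations_veber` counts
#' Veber infractions: TPSA of 140 A^2 or more, more than 10 rotatable bonds
#' (range 0-2). `lipinski_druglike` is 1 when there are fewer than two
#' Lipinski violations.
#'
#' @param mol a `molecule`.
#' @return integer count (or 0/1 flag).
#' @export
lipinski_violations <- function(mol) {
  sum(hbond_donors(mol) > 5L, hbond_acceptors(mol) > 10L,
      mol_weight(mol) >= 500, log_p(mol) >= 5)
}

#' @rdname lipinski_violations
#' @export
lipinski_violations_veber <- function(mol) {
  sum(tpsa(mol) >= 140, n_rotatable_bonds(mol) > 10L)
}

#' @rdname lipinski_violations
#' @export
lipinski_druglike <- function(mol) as.integer(lipinski_violations(mol) < 2L)
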
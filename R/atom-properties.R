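# Per-atom properties: Gasteiger-Marsili PEOE sigma charges, Ertl
# fragment-contribution topological polar surface area, atomic masses.

# Gasteiger-Marsili electronegativity parameters chi(q) = a + b q + c q^2 by
# (element, hybridization); chi_plus (cation electronegativity, the damping
# denominator) is a + b + c except for hydrogen (20.02).
.PEOE_PARAMS <- local({
  tab <- rbind(
    `H`      = c(7.17, 6.24, -0.56),
    `C sp3`  = c(7.98, 9.18, 1.88),
    `C sp2`  = c(8.79, 9.32, 1.51),
    `C sp`   = c(10.39, 9.45, 0.73),
    `N sp3`  = c(11.54, 10.82, 1.36),
    `N sp2`  = c(12.87, 11.15, 0.85),
    `N sp`   = c(15.68, 11.70, -0.27),
    `O sp3`  = c(14.18, 12.92, 1.39),
    `O sp2`  = c(17.07, 13.79, 0.47),
    `F`      = c(14.66, 13.85, 2.31),
    `Cl`     = c(11.00, 9.69, 1.35),
    `Br`     = c(10.08, 8.47, 1.16),
    `I`      = c(9.90, 7.96, 0.96),
    `S sp3`  = c(10.14, 9.13, 1.38),
    `S sp2`  = c(10.14, 9.13, 1.38),
    `P sp3`  = c(8.90, 8.24, 0.96),
    `P sp2`  = c(8.90, 8.24, 0.96))
  colnames(tab) <- c("a", "b", "c")
  tab
})

peoe_key <- function(element, hyb) {
  if (element %in% c("H", "F", "Cl", "Br", "I")) return(element)
  paste(element, hyb)
}

#' Gasteiger-Marsili sigma charges
#'
#' Partial equalization of orbital electronegativity: charge flows along each
#' bond from the less to the more electronegative atom, damped by 0.5^k at
#' iteration k (6 iterations). Implicit hydrogens are resolved as temporary
#' explicit atoms; charges are returned for the molecule's own atoms, and on a
#' fully explicit molecule they sum to the total formal charge.
#'
#' @param mol a `molecule`.
#' @param iterations damping iterations (default 6).
#' @return numeric vector of partial charges (e), one per atom.
#' @export
atom_sigma_charge <- function(mol, iterations = 6L) {
  n0 <- n_atoms(mol)
  full <- add_hydrogens(mol)
  el <- full$atoms$element
  adj <- adjacency(full)
  hyb <- vapply(seq_len(n_atoms(full)), function(i) {
    a <- adj[[i]]
    if (full$atoms$aromatic[i]) return("sp2")
    nd <- sum(a$order == 2L)
    if (any(a$order >= 3L) || nd >= 2L) return("sp")
    if (nd == 1L) return("sp2")
    "sp3"
  }, character(1))
  keys <- mapply(peoe_key, el, hyb)
  unknown <- !(keys %in% rownames(.PEOE_PARAMS))
  if (any(unknown))
    stop("no PEOE parameters for atom type(s): ",
         paste(unique(keys[unknown]), collapse = ", "))
  P <- .PEOE_PARAMS[keys, , drop = FALSE]
  chi_plus <- rowSums(P)
  chi_plus[el == "H"] <- 20.02
  q <- as.numeric(full$atoms$charge)
  b <- full$bonds
  for (k in seq_len(iterations)) {
    chi <- P[, "a"] + P[, "b"] * q + P[, "c"] * q^2
    dq <- numeric(length(q))
    for (m in seq_len(nrow(b))) {
      i <- b$a1[m]; j <- b$a2[m]
      if (chi[i] == chi[j]) next
      lo <- if (chi[i] < chi[j]) i else j
      hi <- if (chi[i] < chi[j]) j else i
      t <- (chi[hi] - chi[lo]) / chi_plus[lo] * 0.5^k
      dq[lo] <- dq[lo] + t
      dq[hi] <- dq[hi] - t
    }
    q <- q + dq
    if (!all(is.finite(q))) stop("sigma-charge iteration diverged")
  }
  q[seq_len(n0)]
}

# Ertl TPSA fragment contributions for N and O atoms. Classification uses the
# atom's hydrogen count (explicit + implicit), aromatic bond count, heavy
# single/double/triple bond counts, charge, and 3-ring membership.
atom_tpsa_contribution <- function(el, charge, nH, nsing, ndoub, ntrip, narom,
                                   in3ring) {
  if (el == "N") {
    if (narom >= 2L) {           # aromatic nitrogen
      if (charge == 0L) {
        if (nH >= 1L) return(15.79)
        if (narom == 3L) return(4.41)
        if (nsing >= 1L) return(4.93)
        if (ndoub >= 1L) return(8.39)
        return(12.89)
      }
      if (charge == 1L) {
        if (nH >= 1L) return(14.14)
        if (narom == 3L) return(4.10)
        if (nsing >= 1L) return(3.88)
        return(12.89)
      }
      return(0)
    }
    if (charge == 0L) {
      if (nH == 0L) {
        if (ntrip == 1L && nsing == 0L) return(23.79)
        if (nsing == 1L && ndoub == 1L) return(12.36)
        if (nsing == 1L && ndoub == 2L) return(11.68)
        if (ndoub == 1L && ntrip == 1L) return(13.60)
        if (nsing == 3L) return(if (in3ring) 3.01 else 3.24)
      } else if (nH == 1L) {
        if (nsing == 2L) return(if (in3ring) 21.94 else 12.03)
        if (ndoub == 1L) return(23.85)
      } else if (nH == 2L) {
        if (nsing == 1L) return(26.02)
      }
      return(0)
    }
    if (charge == 1L) {
      if (nH == 0L) {
        if (nsing == 4L) return(0.00)
        if (nsing == 2L && ndoub == 1L) return(3.01)
        if (nsing == 1L && ntrip == 1L) return(4.36)
      } else if (nH == 1L) {
        if (nsing == 3L) return(4.44)
        if (nsing == 1L && ndoub == 1L) return(13.97)
      } else if (nH == 2L) {
        if (nsing == 2L) return(16.61)
        if (ndoub == 1L) return(25.59)
      } else if (nH == 3L) {
        return(27.64)
      }
      return(0)
    }
    return(0)
  }
  if (el == "O") {
    if (narom >= 2L) return(13.14)
    if (charge == -1L && nsing == 1L && nH == 0L) return(23.06)
    if (charge != 0L) return(0)
    if (ndoub == 1L && nsing == 0L && nH == 0L) return(17.07)
    if (nH >= 1L && nsing == 1L) return(20.23)
    if (nsing == 2L && nH == 0L) return(if (in3ring) 12.53 else 9.23)
    return(0)
  }
  0
}

#' Ertl per-atom topological polar surface area contributions
#'
#' Fragment contributions for nitrogen and oxygen environments (sulfur and
#' phosphorus excluded by default, matching the original parameterization's
#' common usage); all other atoms contribute 0. The molecular TPSA is the sum
#' of these values.
#'
#' @param mol a `molecule`.
#' @param include_sp include the S and P contributions (not implemented;
#'   reserved flag, must be `FALSE`).
#' @return numeric vector of contributions in square Angstrom, one per atom.
#' @export
atom_tpsa <- function(mol, include_sp = FALSE) {
  if (include_sp) stop("S/P TPSA contributions are not implemented")
  adj <- adjacency(mol)
  impl <- implicit_h_counts(mol)
  el <- mol$atoms$element
  rp <- sssr(mol)
  in3 <- logical(n_atoms(mol))
  for (r in rp$rings) if (length(r) == 3L) in3[r] <- TRUE
  vapply(seq_len(n_atoms(mol)), function(i) {
    if (!el[i] %in% c("N", "O")) return(0)
    a <- adj[[i]]
    arom_b <- mol$bonds$aromatic[a$bond]
    hexp <- sum(el[a$nbr] == "H")
    heavy <- el[a$nbr] != "H"
    atom_tpsa_contribution(
      el[i], mol$atoms$charge[i], hexp + impl[i],
      nsing = sum(a$order == 1L & heavy & !arom_b),
      ndoub = sum(a$order == 2L & !arom_b),
      ntrip = sum(a$order == 3L & !arom_b),
      narom = sum(arom_b),
      in3ring = in3[i])
  }, numeric(1))
}

#' Atomic masses per atom
#' @param mol a `molecule`.
#' @return numeric vector of standard atomic weights (implicit hydrogens not
#'   included; they belong to no explicit atom).
#' @export
atom_mass <- function(mol) element_mass(mol$atoms$element)
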
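# Molecular and physicochemical descriptors.
#
# The named panel separating elevated from decreased lipids:
#   nof_Rings       smallest-set-of-smallest-rings count (cyclomatic number)
#   nof_COOH        carboxylic-acid groups: C(=O) bonded to -OH or -O(-)
#   nof_OH          hydroxyls excluding carboxyl hydroxyls
#   nof_RotB        non-ring single bonds between two non-terminal heavy
#                   atoms, excluding amide C-N
#   nof_Chirals     potential tetrahedral stereocenters (assigned +
#                   unassigned), via Morgan symmetry classes
#   C_sp3           sp3-hybridised carbons
#   C_R0            carbons in no ring
#   posCharge_per_volume  sum of positive Gasteiger-Marsili partial charges
#                   (iterative electronegativity equalisation, 6 rounds)
#                   divided by an additive atomic-contribution volume
#   complexity      Bertz-type graph complexity (bond-connectivity
#                   information plus element-distribution information); a
#                   proxy for platform-reported "complexity", not identical
#                   to it
# plus a standard panel of counts, H-bond donors/acceptors, topological
# polar surface area (Ertl N/O contributions), molecular weight / volume /
# area, and a simple additive logP estimate, for ~33 features in total.

# Gasteiger-Marsili electronegativity parameters (a, b, c) by element and
# hybridisation; chi = a + b q + c q^2.
GASTEIGER_PARAMS <- list(
  H      = c(7.17, 6.24, -0.56),
  C.sp3  = c(7.98, 9.18, 1.88),
  C.sp2  = c(8.79, 9.32, 1.51),
  C.sp   = c(10.39, 9.45, 0.73),
  N.sp3  = c(11.54, 10.82, 1.36),
  N.sp2  = c(12.87, 11.15, 0.85),
  N.sp   = c(15.68, 11.70, -0.27),
  O.sp3  = c(14.18, 12.92, 1.39),
  O.sp2  = c(17.07, 13.79, 0.47),
  S.sp3  = c(10.14, 9.13, 1.38),
  P.sp3  = c(8.90, 8.24, 0.96),
  B.sp3  = c(7.5, 7.0, 0.8),
  F.sp3  = c(14.66, 13.85, 2.31),
  Cl.sp3 = c(11.00, 9.69, 1.35),
  Br.sp3 = c(10.08, 8.47, 1.16),
  I.sp3  = c(9.90, 7.96, 0.96)
)

# additive atomic volume contributions (A^3) with bond/ring corrections
# (Zhao-Abraham-Zissimos style: V = sum(v) - 5.92 B - 14.7 R_arom - 3.8 R_al)
ATOM_VOLUME <- c(H = 7.24, B = 40.48, C = 20.58, N = 15.60, O = 14.71,
                 F = 13.31, Cl = 22.45, Br = 26.52, I = 32.52,
                 P = 24.43, S = 24.43)
# crude additive surface-area contributions (A^2); a proxy for platform
# "molecular area" (strongly volume-correlated by construction, which is
# exactly why such features get pruned at the correlation step)
ATOM_AREA <- c(H = 6.0, B = 14.0, C = 9.9, N = 9.1, O = 8.2, F = 7.5,
               Cl = 11.4, Br = 13.1, I = 15.5, P = 12.6, S = 12.0)
# simple additive logP contributions per heavy atom (aromatic carbons score
# slightly lower than aliphatic); hydrogens on heteroatoms subtract
LOGP_CONTRIB <- c(C = 0.36, N = -0.60, O = -0.58, S = 0.25, P = -0.45,
                  F = 0.14, Cl = 0.64, Br = 0.82, I = 1.10, B = 0.10)

atom_hybridisation <- function(mol) {
  nb <- mol$bonds
  na <- nrow(mol$atoms)
  max_order <- rep(1, na)
  for (b in seq_len(nrow(nb))) {
    for (a in c(nb$a1[b], nb$a2[b])) {
      max_order[a] <- max(max_order[a], nb$order[b])
    }
  }
  ifelse(max_order >= 3, "sp",
         ifelse(mol$atoms$aromatic | max_order >= 1.5, "sp2", "sp3"))
}

#' Gasteiger-Marsili partial charges
#'
#' Iterative partial equalisation of orbital electronegativity on the
#' hydrogen-expanded graph; 6 damped iterations (damping `0.5^t`).
#'
#' @param mol a `molecule` from [parse_smiles()].
#' @param n_iter number of iterations.
#' @return list with `charges` (heavy atoms, implicit-H charge folded in is
#'   NOT applied; hydrogens are returned separately as `h_charges` summed per
#'   heavy atom) and `converged` flag.
#' @keywords internal
gasteiger_charges <- function(mol, n_iter = 6L) {
  hyb <- atom_hybridisation(mol)
  na <- nrow(mol$atoms)
  # expand implicit hydrogens
  h_of <- mol$atoms$h_count
  n_h <- sum(h_of)
  n_tot <- na + n_h
  elem <- c(paste(mol$atoms$element, hyb, sep = "."), rep("H", n_h))
  par <- lapply(elem, function(e) {
    GASTEIGER_PARAMS[[e]] %||% GASTEIGER_PARAMS[["C.sp3"]]
  })
  a_vec <- vapply(par, `[`, 0, 1)
  b_vec <- vapply(par, `[`, 0, 2)
  c_vec <- vapply(par, `[`, 0, 3)
  chi_plus <- ifelse(elem == "H", 20.02, a_vec + b_vec + c_vec)
  edges <- cbind(mol$bonds$a1, mol$bonds$a2)
  hi <- na
  for (a in seq_len(na)) {
    if (h_of[a] > 0) {
      for (k in seq_len(h_of[a])) {
        hi <- hi + 1L
        edges <- rbind(edges, c(a, hi))
      }
    }
  }
  q <- c(as.numeric(mol$atoms$charge), rep(0, n_h))
  converged <- TRUE
  if (nrow(edges)) {
    for (t in seq_len(n_iter)) {
      chi <- a_vec + b_vec * q + c_vec * q^2
      damp <- 0.5^t
      dq <- numeric(n_tot)
      for (e in seq_len(nrow(edges))) {
        i <- edges[e, 1]; j <- edges[e, 2]
        if (chi[i] == chi[j]) next
        donor <- if (chi[i] < chi[j]) i else j
        transfer <- abs(chi[i] - chi[j]) / chi_plus[donor] * damp
        if (!is.finite(transfer)) { converged <- FALSE; transfer <- 0 }
        if (chi[i] < chi[j]) {
          dq[i] <- dq[i] - transfer; dq[j] <- dq[j] + transfer
        } else {
          dq[i] <- dq[i] + transfer; dq[j] <- dq[j] - transfer
        }
      }
      q <- q + dq
    }
  }
  h_charge <- numeric(na)
  hi <- na
  for (a in seq_len(na)) {
    if (h_of[a] > 0) {
      idx <- hi + seq_len(h_of[a])
      h_charge[a] <- sum(q[idx])
      hi <- hi + h_of[a]
    }
  }
  list(charges = q[seq_len(na)], h_charges = h_charge, converged = converged)
}

carboxyl_atoms <- function(mol) {
  # returns list(carbons, hydroxyl_oxygens) of COOH/COO- groups
  nb <- mol$bonds
  adj_bonds <- vector("list", nrow(mol$atoms))
  for (b in seq_len(nrow(nb))) {
    adj_bonds[[nb$a1[b]]] <- c(adj_bonds[[nb$a1[b]]], b)
    adj_bonds[[nb$a2[b]]] <- c(adj_bonds[[nb$a2[b]]], b)
  }
  carbons <- integer(0); ohs <- integer(0)
  for (a in which(mol$atoms$element == "C" & !mol$atoms$aromatic)) {
    dbl_o <- FALSE; oh <- NA_integer_
    for (b in adj_bonds[[a]]) {
      other <- if (nb$a1[b] == a) nb$a2[b] else nb$a1[b]
      if (mol$atoms$element[other] != "O") next
      if (nb$order[b] == 2) dbl_o <- TRUE
      if (nb$order[b] == 1 && mol$atoms$degree[other] == 1 &&
          (mol$atoms$h_count[other] >= 1 || mol$atoms$charge[other] == -1)) {
        oh <- other
      }
    }
    if (dbl_o && !is.na(oh)) {
      carbons <- c(carbons, a)
      ohs <- c(ohs, oh)
    }
  }
  list(carbons = carbons, hydroxyl_oxygens = ohs)
}

#' Compute the molecular descriptor panel
#'
#' @param smiles SMILES string, or a pre-parsed `molecule`.
#' @param name record name for error messages.
#' @return named numeric vector of ~33 descriptors (see file header).
#' @export
compute_descriptors <- function(smiles, name = NULL) {
  mol <- if (inherits(smiles, "molecule")) smiles else {
    parse_smiles(smiles, name %||% smiles)
  }
  at <- mol$atoms; nb <- mol$bonds
  na <- nrow(at)
  hyb <- atom_hybridisation(mol)

  cooh <- carboxyl_atoms(mol)
  nof_COOH <- length(cooh$carbons)

  is_oh <- at$element == "O" & at$h_count >= 1 & at$degree == 1
  is_oh[cooh$hydroxyl_oxygens] <- FALSE
  nof_OH <- sum(is_oh)

  # rotatable bonds: single, acyclic, both ends heavy-degree >= 2, not amide
  amide_bond <- function(b) {
    i <- nb$a1[b]; j <- nb$a2[b]
    pair <- c(at$element[i], at$element[j])
    if (!("C" %in% pair && "N" %in% pair)) return(FALSE)
    cat_ <- if (at$element[i] == "C") i else j
    any(vapply(seq_len(nrow(nb)), function(bb) {
      bb != b && nb$order[bb] == 2 &&
        ((nb$a1[bb] == cat_ && at$element[nb$a2[bb]] == "O") ||
           (nb$a2[bb] == cat_ && at$element[nb$a1[bb]] == "O"))
    }, logical(1)))
  }
  rot <- vapply(seq_len(nrow(nb)), function(b) {
    nb$order[b] == 1 && !nb$in_ring[b] &&
      at$degree[nb$a1[b]] >= 2 && at$degree[nb$a2[b]] >= 2 &&
      !amide_bond(b)
  }, logical(1))
  nof_RotB <- sum(rot)

  # potential tetrahedral stereocenters
  cls <- symmetry_classes(mol)
  adj <- adjacency_list(mol)
  nof_Chirals <- sum(vapply(seq_len(na), function(a) {
    if (at$element[a] != "C" || at$aromatic[a]) return(FALSE)
    if (hyb[a] != "sp3") return(FALSE)
    if (at$degree[a] + at$h_count[a] != 4) return(FALSE)
    if (at$h_count[a] > 1) return(FALSE)
    ncls <- cls[adj[[a]]]
    length(unique(ncls)) == length(ncls)
  }, logical(1)))

  C_sp3 <- sum(at$element == "C" & !at$aromatic & hyb == "sp3")
  C_R0 <- sum(at$element == "C" & !at$in_ring)

  gq <- gasteiger_charges(mol)
  pos_charge <-sum(gq$charges[gq$charges > 0]) + sum(gq$h_charges[gq$h_charges > 0])
  neg_charge <- -(sum(gq$charges[gq$charges < 0]) + sum(gq$h_charges[gq$h_charges < 0]))
  if (!gq$converged) {
    warning("partial-charge scheme did not converge for '", mol$name,
            "'; charge features set to 0")
    pos_charge <- neg_charge <- 0
  }

  n_h_total <- sum(at$h_count)
  n_bonds_h <- nrow(nb) + n_h_total
  n_rings <- ring_count(mol)
  n_arom_rings <- aromatic_ring_count(mol)
  volume <- sum(ATOM_VOLUME[at$element]) + n_h_total * ATOM_VOLUME[["H"]] -
    5.92 * n_bonds_h - 14.7 * n_arom_rings - 3.8 * (n_rings - n_arom_rings)
  area <- sum(ATOM_AREA[at$element]) + n_h_total * ATOM_AREA[["H"]]

  # Bertz-type complexity: eta = sum over atoms of d(d-1)/2 (pairwise bond
  # connections), C = eta log2(eta) plus element-distribution information
  d <- at$degree + at$h_count
  eta <- sum(d * (d - 1) / 2)
  cplx_bonds <- if (eta > 0) eta * log2(eta) else 0
  elem_counts <- table(at$element)
  p <- as.numeric(elem_counts) / na
  cplx_elem <- -na * sum(p * log2(p))
  complexity <- cplx_bonds + cplx_elem

  mw <- sum(ATOMIC_MASS[at$element]) + n_h_total * ATOMIC_MASS[["H"]]

  hbd <- sum(at$element %in% c("O", "N") & at$h_count >= 1)
  hba <- sum(at$element %in% c("O", "N") & at$charge <= 0)
  tpsa <- tpsa_ertl(mol)

  logp <- sum(LOGP_CONTRIB[at$element]) -
    0.07 * sum(at$element == "C" & at$aromatic) -
    0.18 * sum(at$h_count[at$element %in% c("O", "N")]) -
    0.40 * sum(abs(at$charge))

  c(
    nof_Rings = n_rings,
    nof_COOH = nof_COOH,
    nof_OH = nof_OH,
    nof_RotB = nof_RotB,
    nof_Chirals = nof_Chirals,
    C_sp3 = C_sp3,
    C_R0 = C_R0,
    posCharge_per_volume = if (volume > 0) pos_charge / volume else 0,
    complexity = complexity,
    mol_weight = mw,
    mol_volume = volume,
    mol_area = area,
    heavy_atoms = na,
    n_carbons = sum(at$element == "C"),
    n_heteroatoms = sum(!at$element %in% c("C", "H")),
    n_nitrogens = sum(at$element == "N"),
    n_oxygens = sum(at$element == "O"),
    n_sulfurs = sum(at$element == "S"),
    n_hydrogens = n_h_total,
    n_bonds = nrow(nb),
    n_double_bonds = sum(nb$order == 2),
    n_triple_bonds = sum(nb$order == 3),
    n_aromatic_atoms = sum(at$aromatic),
    n_aromatic_rings = n_arom_rings,
    ring_atoms = sum(at$in_ring),
    C_sp2 = sum(at$element == "C" & (at$aromatic | hyb == "sp2")),
    frac_C_sp3 = if (any(at$element == "C")) C_sp3 / sum(at$element == "C") else 0,
    hbd = hbd,
    hba = hba,
    tpsa = tpsa,
    logp_estimate = unname(logp),
    net_charge = sum(at$charge),
    posCharge_sum = pos_charge,
    negCharge_sum = neg_charge
  )
}

# Ertl topological polar surface area, N/O contributions (the classic
# parameterisation; S and P are not counted, as in the original scheme).
tpsa_ertl <- function(mol) {
  at <- mol$atoms; nb <- mol$bonds
  total <- 0
  for (a in seq_len(nrow(at))) {
    el <- at$element[a]
    if (!el %in% c("N", "O")) next
    bonds_a <- which(nb$a1 == a | nb$a2 == a)
    orders <- nb$order[bonds_a]
    h <- at$h_count[a]
    ch <- at$charge[a]
    deg <- at$degree[a]
    arom <- at$aromatic[a]
    contrib <- if (el == "O") {
      if (arom) 13.14
      else if (ch == -1 && deg == 1) 23.06
      else if (any(orders == 2)) 17.07
      else if (h >= 1) 20.23
      else 9.23
    } else {
      if (arom) {
        if (h >= 1) 15.79 else if (deg == 3) 4.41 else 12.89
      } else if (ch == 1) {
        if (h == 3) 27.64 else if (h == 2) 16.61 else if (h == 1) 4.44 else 0.0
      } else if (any(orders == 3)) 23.79
      else if (any(orders == 2)) {
        if (h >= 1) 23.85 else 12.36
      } else {
        if (h >= 2) 26.02 else if (h == 1) 12.03 else 3.24
      }
    }
    total <- total + contrib
  }
  total
}
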
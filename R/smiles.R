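# Minimal SMILES parser and molecular-graph utilities.
#
# Supports the subset of SMILES needed for serum-lipid chemistry: the
# organic subset (B C N O P S F Cl Br I), aromatic lowercase atoms, bracket
# atoms with isotope/chirality/H-count/charge, bond symbols - = # : / \
# (directional bonds read as single), branches, ring-bond closures (1-9 and
# %nn) and dot-separated components. Implicit hydrogens follow the standard
# valence rules; aromatic bonds count 1.5 toward valence with the total
# rounded up.

SMILES_ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
SMILES_DEFAULT_VALENCE <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)
ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                 P = 30.974, S = 32.065, F = 18.998, Cl = 35.453,
                 Br = 79.904, I = 126.904)

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles SMILES string.
#' @param name optional record name used in error messages.
#' @return a `molecule`: list with `atoms` (data.frame: `element`,
#'   `aromatic`, `charge`, `h_count`, `chiral_tag`, `in_ring`, `degree`) and
#'   `bonds` (data.frame: `a1`, `a2`, `order`, `aromatic`, `in_ring`).
#' @export
parse_smiles <- function(smiles, name = smiles) {
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  atoms <- list()     # each: list(element, aromatic, charge, h_count, chiral)
  bonds <- list()     # each: c(a1, a2, order); order 1.5 = aromatic
  ring_open <- list() # closure digit -> list(atom, order)
  prev <- 0L
  pending_order <- NA_real_
  stack <- integer(0)
  i <- 1L
  err <- function(msg, pos) {
    stop("SMILES parse error in '", name, "' at position ", pos, ": ", msg)
  }
  add_atom <- function(element, aromatic, charge = 0L, h_count = NA_integer_,
                       chiral = FALSE) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, aromatic = aromatic,
                                         charge = charge, h_count = h_count,
                                         chiral = chiral)
    length(atoms)
  }
  add_bond <- function(a1, a2, order) {
    if (is.na(order)) {
      both_arom <- atoms[[a1]]$aromatic && atoms[[a2]]$aromatic
      order <- if (both_arom) 1.5 else 1
    }
    bonds[[length(bonds) + 1L]] <<- c(a1, a2, order)
  }
  close_ring <- function(key, pos) {
    if (!is.null(ring_open[[key]])) {
      opener <- ring_open[[key]]
      order <- pending_order
      if (is.na(order)) order <- opener$order
      add_bond(opener$atom, prev, order)
      ring_open[[key]] <<- NULL
    } else {
      ring_open[[key]] <<- list(atom = prev, order = pending_order)
    }
    pending_order <<- NA_real_
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (prev == 0L) err("branch with no preceding atom", i)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) err("unmatched ')'", i)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_order <- switch(ch, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5,
                              "/" = 1, "\\" = 1)
      i <- i + 1L
    } else if (ch == ".") {
      prev <- 0L
      pending_order <- NA_real_
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      if (prev == 0L) err("ring closure with no preceding atom", i)
      close_ring(ch, i)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) err("truncated %nn ring closure", i)
      key <- paste0(chars[i + 1L], chars[i + 2L])
      if (!grepl("^[0-9]{2}$", key)) err("malformed %nn ring closure", i)
      close_ring(key, i)
      i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) err("unterminated bracket atom", i)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9]*|\\+*|-*)$",
        body))[[1]]
      if (!length(m) || !nzchar(m[3])) err(paste0("bad bracket atom [", body, "]"), i)
      sym <- m[3]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
      element <- if (aromatic) toupper(sym) else sym
      if (!element %in% c(names(ATOMIC_MASS))) {
        err(paste0("unsupported element '", sym, "'"), i)
      }
      hc <- 0L
      if (!is.na(m[5]) && nzchar(m[5])) {
        hc <- if (m[5] == "H") 1L else as.integer(sub("H", "", m[5]))
      }
      charge <- 0L
      cs <- m[6]
      if (nzchar(cs)) {
        if (grepl("^[+-][0-9]+$", cs)) {
          charge <- as.integer(cs)
        } else {
          charge <- sum(strsplit(cs, "")[[1]] == "+") -
            sum(strsplit(cs, "")[[1]] == "-")
        }
      }
      a <- add_atom(element, aromatic, charge, hc, chiral = nzchar(m[4]))
      if (prev != 0L) add_bond(prev, a, pending_order)
      pending_order <- NA_real_
      prev <- a
      i <- j + 1L
    } else {
      # organic-subset atom, possibly two characters (Cl, Br)
      sym <- ch
      if (ch %in% c("C", "B") && i < n && paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
        sym <- paste0(ch, chars[i + 1L])
        i <- i + 1L
      }
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
      element <- if (aromatic) toupper(sym) else sym
      if (!element %in% SMILES_ORGANIC) {
        err(paste0("unexpected character '", ch, "'"), i)
      }
      a <- add_atom(element, aromatic)
      if (prev != 0L) add_bond(prev, a, pending_order)
      pending_order <- NA_real_
      prev <- a
      i <- i + 1L
    }
  }
  if (length(stack)) err("unclosed branch", n)
  open_keys <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_keys)) err(paste0("unclosed ring bond(s): ",
                                    paste(open_keys, collapse = ", ")), n)
  if (!length(atoms)) err("no atoms", 1L)
  finalize_molecule(atoms, bonds, name)
}

finalize_molecule <- function(atoms, bonds, name) {
  na <- length(atoms)
  atom_df <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    charge = vapply(atoms, function(a) as.integer(a$charge), 0L),
    h_count = vapply(atoms, function(a) as.integer(a$h_count), NA_integer_),
    chiral_tag = vapply(atoms, `[[`, FALSE, "chiral"),
    stringsAsFactors = FALSE
  )
  if (length(bonds)) {
    bond_df <- as.data.frame(do.call(rbind, bonds))
    names(bond_df) <- c("a1", "a2", "order")
    if (any(bond_df$a1 == bond_df$a2)) stop("self-bond in '", name, "'")
    bond_df$aromatic <- bond_df$order == 1.5
  } else {
    bond_df <- data.frame(a1 = integer(0), a2 = integer(0),
                          order = numeric(0), aromatic = logical(0))
  }
  # bond-order sums per atom (aromatic = 1.5)
  order_sum <- numeric(na)
  degree <- integer(na)
  for (b in seq_len(nrow(bond_df))) {
    for (a in c(bond_df$a1[b], bond_df$a2[b])) {
      order_sum[a] <- order_sum[a] + bond_df$order[b]
      degree[a] <- degree[a] + 1L
    }
  }
  # implicit hydrogens for non-bracket atoms
  h <- atom_df$h_count
  for (a in seq_len(na)) {
    if (!is.na(h[a])) next
    valences <- SMILES_DEFAULT_VALENCE[[atom_df$element[a]]]
    used <- ceiling(order_sum[a] - 1e-9)
    if (atom_df$aromatic[a]) used <- ceiling(order_sum[a])
    v <- valences[valences >= used]
    h[a] <- if (length(v)) as.integer(v[1] - used) else 0L
  }
  atom_df$h_count <- h
  atom_df$degree <- degree

  ring_bond <- ring_bonds(na, bond_df)
  bond_df$in_ring <- ring_bond
  in_ring_atom <- rep(FALSE, na)
  if (any(ring_bond)) {
    in_ring_atom[unique(c(bond_df$a1[ring_bond], bond_df$a2[ring_bond]))] <- TRUE
  }
  atom_df$in_ring <- in_ring_atom

  structure(list(atoms = atom_df, bonds = bond_df, name = name),
            class = "molecule")
}

# Bonds lying on a cycle = non-bridge edges (removal keeps endpoints
# connected). Molecules are tiny, so a per-edge BFS is fine.
ring_bonds <- function(n_atoms, bond_df) {
  nb <- nrow(bond_df)
  if (!nb) return(logical(0))
  adj <- vector("list", n_atoms)
  for (b in seq_len(nb)) {
    adj[[bond_df$a1[b]]] <- c(adj[[bond_df$a1[b]]], b)
    adj[[bond_df$a2[b]]] <- c(adj[[bond_df$a2[b]]], b)
  }
  vapply(seq_len(nb), function(skip) {
    from <- bond_df$a1[skip]; to <- bond_df$a2[skip]
    seen <- rep(FALSE, n_atoms)
    seen[from] <- TRUE
    queue <- from
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (b in adj[[v]]) {
        if (b == skip) next
        w <- if (bond_df$a1[b] == v) bond_df$a2[b] else bond_df$a1[b]
        if (!seen[w]) {
          if (w == to) return(TRUE)
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    FALSE
  }, logical(1))
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$name, ": ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds, ", ring_count(x), " rings\n", sep = "")
  invisible(x)
}

n_components <- function(mol) {
  na <- nrow(mol$atoms)
  comp <- integer(na)
  cur <- 0L
  adj <- adjacency_list(mol)
  for (start in seq_len(na)) {
    if (comp[start]) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!comp[w]) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  cur
}

adjacency_list <- function(mol) {
  adj <- vector("list", nrow(mol$atoms))
  for (b in seq_len(nrow(mol$bonds))) {
    adj[[mol$bonds$a1[b]]] <- c(adj[[mol$bonds$a1[b]]], mol$bonds$a2[b])
    adj[[mol$bonds$a2[b]]] <- c(adj[[mol$bonds$a2[b]]], mol$bonds$a1[b])
  }
  adj
}

# Smallest-set-of-smallest-rings count via the cyclomatic number
# (bonds - atoms + components), exact for molecular graphs.
ring_count <- function(mol) {
  nrow(mol$bonds) - nrow(mol$atoms) + n_components(mol)
}

aromatic_ring_count <- function(mol) {
  arom <- mol$bonds[mol$bonds$aromatic, , drop = FALSE]
  if (!nrow(arom)) return(0L)
  atoms_in <- unique(c(arom$a1, arom$a2))
  # cyclomatic number of the aromatic-bond subgraph
  sub_adj <- vector("list", nrow(mol$atoms))
  for (b in seq_len(nrow(arom))) {
    sub_adj[[arom$a1[b]]] <- c(sub_adj[[arom$a1[b]]], arom$a2[b])
    sub_adj[[arom$a2[b]]] <- c(sub_adj[[arom$a2[b]]], arom$a1[b])
  }
  comp <- 0L
  seen <- rep(FALSE, nrow(mol$atoms))
  for (start in atoms_in) {
    if (seen[start]) next
    comp <- comp + 1L
    queue <- start; seen[start] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in sub_adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  nrow(arom) - length(atoms_in) + comp
}

# Morgan-style symmetry classes: iterative neighbourhood refinement of atom
# invariants (element, charge, degree, H count, aromaticity). Used to decide
# whether a tetrahedral carbon's substituents are distinguishable.
symmetry_classes <- function(mol) {
  na <- nrow(mol$atoms)
  adj <- adjacency_list(mol)
  key <- paste(mol$atoms$element, mol$atoms$charge, mol$atoms$degree,
               mol$atoms$h_count, mol$atoms$aromatic)
  cls <- as.integer(factor(key))
  for (it in seq_len(na)) {
    new_key <- vapply(seq_len(na), function(a) {
      paste(cls[a], paste(sort(cls[adj[[a]]]), collapse = ","))
    }, character(1))
    new_cls <- as.integer(factor(new_key))
    if (length(unique(new_cls)) == length(unique(cls))) break
    cls <- new_cls
  }
  cls
}
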
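#' Molecular data model
#'
#' A `macro_molecule` bundles the atom table, the bond list and the two
#' labelled torsion quadruples (`phi1`, the enone ester torsion
#' O19-C2-C3-C4, and `phi2`, the central diene torsion) that the
#' classifier works from. Conformers are plain N x 3 coordinate
#' matrices (Angstrom) carrying optional `energy` (kcal/mol) and
#' `source_seed` attributes.
#'
#' @param name Molecule name.
#' @param atoms Data frame with columns `element` (one of C, H, O, Fe),
#'   `label` (e.g. "O19"), `ring_index` (1..18 for ring atoms, NA
#'   otherwise).
#' @param bonds Data frame with columns `i`, `j` (atom indices) and
#'   `order` (one of "single", "double", "ester", "coordination").
#' @param torsion_labels Named list of integer 4-vectors, entries
#'   `phi1` and `phi2` for built macrolactones.
#' @param closure_bond Integer 2-vector naming the ring-closure bond,
#'   which the force field treats as a harmonic restraint.
#' @param restraints List of torsion restraints (see [energy()]).
#' @return An object of class `macro_molecule`.
#' @export
macro_molecule <- function(name, atoms, bonds, torsion_labels = list(),
                           closure_bond = NULL, restraints = list()) {
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  stopifnot(all(c("element", "label", "ring_index") %in% names(atoms)),
            all(c("i", "j", "order") %in% names(bonds)))
  ok_el <- c("C", "H", "O", "Fe", "X")
  if (!all(atoms$element %in% ok_el)) {
    mc_stop(sprintf("unsupported element(s): %s",
                    paste(setdiff(atoms$element, ok_el), collapse = ", ")),
            "macroconf_model_error")
  }
  n <- nrow(atoms)
  if (nrow(bonds) > 0) {
    if (any(bonds$i == bonds$j) || any(bonds$i < 1) || any(bonds$j < 1) ||
        any(bonds$i > n) || any(bonds$j > n)) {
      mc_stop("invalid bond indices", "macroconf_model_error")
    }
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) {
      mc_stop("duplicate bonds in bond list", "macroconf_model_error")
    }
  }
  structure(list(name = name, atoms = atoms, bonds = bonds,
                 torsion_labels = torsion_labels,
                 closure_bond = closure_bond,
                 restraints = restraints),
            class = "macro_molecule")
}

#' @export
print.macro_molecule <- function(x, ...) {
  cat(sprintf("<macro_molecule> %s: %d atoms, %d bonds", x$name,
              nrow(x$atoms), nrow(x$bonds)))
  if (length(x$torsion_labels)) {
    cat(sprintf(", torsions: %s",
                paste(names(x$torsion_labels), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

#' Make a conformer object
#'
#' @param coords N x 3 numeric matrix, Angstrom.
#' @param energy Optional energy, kcal/mol.
#' @param source_seed Optional integer recording the RNG seed that
#'   produced this geometry.
#' @return The coordinate matrix with class `conformer` and the
#'   metadata stored as attributes.
#' @export
conformer <- function(coords, energy = NA_real_, source_seed = NA_integer_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || !all(is.finite(coords))) {
    mc_stop("conformer coordinates must be a finite N x 3 matrix",
            "macroconf_model_error")
  }
  structure(coords, energy = energy, source_seed = source_seed,
            class = c("conformer", "matrix", "array"))
}

#' @export
print.conformer <- function(x, ...) {
  e <- attr(x, "energy")
  cat(sprintf("<conformer> %d atoms%s\n", nrow(x),
              if (is.finite(e)) sprintf(", E = %.3f kcal/mol", e) else ""))
  invisible(x)
}

conf_energy <- function(conf) attr(conf, "energy")

# adjacency list over selected bond orders
adjacency <- function(mol, exclude_orders = character()) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  b <- mol$bonds
  if (length(exclude_orders)) b <- b[!(b$order %in% exclude_orders), ]
  for (r in seq_len(nrow(b))) {
    adj[[b$i[r]]] <- c(adj[[b$i[r]]], b$j[r])
    adj[[b$j[r]]] <- c(adj[[b$j[r]]], b$i[r])
  }
  adj
}

graph_connected <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0) return(TRUE)
  adj <- adjacency(mol)
  seen <- logical(n)
  stack <- 1L
  seen[1] <- TRUE
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  all(seen)
}

# ordered ring atom indices (by ring_index 1..18), checking ring bonds exist
ring_atoms <- function(mol) {
  ri <- mol$atoms$ring_index
  idx <- order(ri, na.last = NA)
  ring <- idx[!is.na(ri[idx])]
  ring
}

# sum of bond orders per atom (single/ester = 1, double = 2, coordination = 0)
valence_counts <- function(mol) {
  val <- numeric(n_atoms(mol))
  w <- c(single = 1, ester = 1, double = 2, coordination = 0)
  for (r in seq_len(nrow(mol$bonds))) {
    b <- mol$bonds[r, ]
    val[b$i] <- val[b$i] + w[[b$order]]
    val[b$j] <- val[b$j] + w[[b$order]]
  }
  val
}

# the 18 cyclic backbone torsion quadruples, used for dedup distances
ring_torsion_quads <- function(mol) {
  ring <- ring_atoms(mol)
  n <- length(ring)
  lapply(seq_len(n), function(k) {
    ring[c((k - 2) %% n + 1, (k - 1) %% n + 1, k %% n + 1, (k + 1) %% n + 1)]
  })
}

# index of the atom with a given label, error if absent
atom_by_label <- function(mol, label) {
  i <- which(mol$atoms$label == label)
  if (length(i) != 1) {
    mc_stop(sprintf("no unique atom labelled '%s'", label),
            "macroconf_model_error")
  }
  i
}

#' Chain symmetry of a built macrolactone
#'
#' A built 18-membered macrolactone is mirror-symmetric about the
#' ester-diene axis exactly when its two saturated methylene chains
#' (between the ene and the diene, and between the diene and the ester
#' oxygen) have equal length. The chain lengths are measured on the
#' bond graph by walking the ring between the two sp2 sites.
#'
#' @param mol A built `macro_molecule`.
#' @return TRUE if the two saturated chains have equal length.
#' @export
is_chain_symmetric <- function(mol) {
  lens <- chain_lengths(mol)
  lens[1] == lens[2]
}

# lengths (n2, n1) of the two saturated ring chains, from the graph
chain_lengths <- function(mol) {
  ring <- ring_atoms(mol)
  el <- mol$atoms$element[ring]
  # sp2 ring positions: bonded by a double bond to another ring atom
  dbl <- mol$bonds[mol$bonds$order == "double", ]
  in_dbl <- sort(unique(c(dbl$i, dbl$j)))
  sp2 <- ring %in% in_dbl
  is_o <- el == "O"
  sat <- !sp2 & !is_o
  runs <- rle(sat)
  lens <- runs$lengths[runs$values]
  if (length(lens) != 2) {
    mc_stop("molecule does not have the two-saturated-chain ring topology",
            "macroconf_model_error")
  }
  lens
}
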
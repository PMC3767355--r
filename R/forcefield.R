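#' Load a molecular-mechanics parameter set
#'
#' Reads the flat key-value parameter file packaged with macroconf (or a
#' user override in the same format). The set holds bond stretch, angle
#' bend, torsion, Lennard-Jones and bond-dipole constants keyed by atom
#' class (C sp3, C2 sp2, O ester oxygen, O2 carbonyl oxygen, H, FE
#' pseudo-atom).
#'
#' @param path Parameter file; defaults to the packaged set.
#' @return An object of class `ff_params`.
#' @export
load_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mm_params.txt", package = "macroconf")
  }
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  p <- list(stretch = list(), bend = list(), torsion = list(),
            vdw = list(), dipole = list(), version = NA_character_)
  for (ln in lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    kind <- f[1]
    if (kind == "version") {
      p$version <- f[2]
    } else if (kind == "stretch") {
      key <- paste(sort(f[2:3])[1], sort(f[2:3])[2], f[4], sep = ":")
      p$stretch[[key]] <- c(ks = as.numeric(f[5]), r0 = as.numeric(f[6]))
    } else if (kind == "bend") {
      p$bend[[f[2]]] <- c(kb = as.numeric(f[3]), th0 = as.numeric(f[4]))
    } else if (kind == "torsion") {
      key <- paste(sort(f[2:3])[1], sort(f[2:3])[2], f[4], sep = ":")
      p$torsion[[key]] <- c(V1 = as.numeric(f[5]), V2 = as.numeric(f[6]),
                            V3 = as.numeric(f[7]))
    } else if (kind == "vdw") {
      p$vdw[[f[2]]] <- c(eps = as.numeric(f[3]), rstar = as.numeric(f[4]))
    } else if (kind == "dipole") {
      key <- paste(f[2], f[3], f[4], sep = ":")
      p$dipole[[key]] <- as.numeric(f[5])
    } else {
      mc_stop(sprintf("unknown parameter record '%s'", kind),
              "macroconf_param_error")
    }
  }
  structure(p, class = "ff_params")
}

default_params_env <- new.env(parent = emptyenv())

#' @rdname load_params
#' @export
default_params <- function() {
  if (is.null(default_params_env$p)) {
    default_params_env$p <- load_params()
  }
  default_params_env$p
}

# per-atom force-field class
atom_classes <- function(mol) {
  el <- mol$atoms$element
  cls <- character(length(el))
  dbl <- mol$bonds[mol$bonds$order == "double", ]
  in_dbl <- unique(c(dbl$i, dbl$j))
  for (a in seq_along(el)) {
    cls[a] <- switch(el[a],
      C = if (a %in% in_dbl) "C2" else "C",
      O = if (a %in% in_dbl) "O2" else "O",
      H = "H",
      Fe = "FE",
      X = "X")
  }
  cls
}

order_token <- function(order) {
  switch(order, single = "1", ester = "1", double = "2",
         coordination = "coord")
}

lookup_or_fail <- function(tab, key, what) {
  v <- tab[[key]]
  if (is.null(v)) {
    mc_stop(sprintf("missing %s parameter for class '%s'", what, key),
            "macroconf_param_error")
  }
  v
}

#' Assemble the force-field term lists for a molecule
#'
#' Enumerates stretch, bend, torsion and van der Waals terms from the
#' bond graph and attaches restraints: the ring-closure bond is carried
#' as a harmonic distance restraint (k = 300 kcal/mol/A^2) so that
#' torsion-space moves stay simple, and any molecule-level torsion
#' restraints (e.g. the complexed diene s-cis lock) are appended.
#' Coordination bonds contribute stretch terms only. Van der Waals
#' interactions exclude 1-2 and 1-3 pairs.
#'
#' @param mol A `macro_molecule`.
#' @param params An `ff_params` set.
#' @param restraints Extra restraints: list with optional elements
#'   `torsion` (list of `list(atoms = int4, k, phi0_deg)`) and
#'   `distance` (list of `list(atoms = int2, k, r0)`).
#' @return A list of term matrices consumed by the compiled energy code.
#' @export
mm_system <- function(mol, params = default_params(), restraints = NULL) {
  cls <- atom_classes(mol)
  b <- mol$bonds
  closure <- mol$closure_bond

  is_closure <- function(i, j) {
    !is.null(closure) && all(sort(c(i, j)) == sort(closure))
  }

  bonds <- matrix(0, 0, 4)
  drestr <- matrix(0, 0, 4)
  for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]
    key <- paste(sort(cls[c(i, j)])[1], sort(cls[c(i, j)])[2],
                 order_token(b$order[r]), sep = ":")
    pr <- lookup_or_fail(params$stretch, key, "stretch")
    if (is_closure(i, j)) {
      drestr <- rbind(drestr, c(i, j, 300, pr[["r0"]]))
    } else {
      bonds <- rbind(bonds, c(i, j, pr[["ks"]], pr[["r0"]]))
    }
  }

  # covalent adjacency (no coordination) for angles/torsions;
  # full adjacency (with coordination) for vdw exclusions
  adj_cov <- adjacency(mol, exclude_orders = "coordination")
  adj_all <- adjacency(mol)

  angles <- matrix(0, 0, 5)
  for (j in seq_len(n_atoms(mol))) {
    nb <- adj_cov[[j]]
    if (length(nb) < 2) next
    pr <- lookup_or_fail(params$bend, cls[j], "bend")
    cmb <- utils::combn(nb, 2)
    for (cidx in seq_len(ncol(cmb))) {
      angles <- rbind(angles, c(cmb[1, cidx], j, cmb[2, cidx],
                                pr[["kb"]], pr[["th0"]] * pi / 180))
    }
  }

  torsions <- matrix(0, 0, 7)
  for (r in seq_len(nrow(b))) {
    if (b$order[r] == "coordination") next
    j <- b$i[r]; k <- b$j[r]
    key <- paste(sort(cls[c(j, k)])[1], sort(cls[c(j, k)])[2],
                 order_token(b$order[r]), sep = ":")
    pr <- params$torsion[[key]]
    if (is.null(pr)) {
      # terminal bonds (e.g. C2=O19) carry no torsions; only fail if a
      # quadruple actually exists for this central bond
      if (length(setdiff(adj_cov[[j]], k)) > 0 &&
          length(setdiff(adj_cov[[k]], j)) > 0) {
        mc_stop(sprintf("missing torsion parameter for class '%s'", key),
                "macroconf_param_error")
      }
      next
    }
    for (i in setdiff(adj_cov[[j]], k)) {
      for (l in setdiff(adj_cov[[k]], j)) {
        if (i == l) next
        torsions <- rbind(torsions, c(i, j, k, l, pr[["V1"]], pr[["V2"]],
                                      pr[["V3"]]))
      }
    }
  }

  # vdw pair list: all pairs minus 1-2 and 1-3 (any bond type)
  n <- n_atoms(mol)
  excl <- vector("list", n)
  for (i in seq_len(n)) {
    one2 <- adj_all[[i]]
    one3 <- unique(unlist(adj_all[one2]))
    excl[[i]] <- unique(c(i, one2, one3))
  }
  vdw <- matrix(0, 0, 4)
  vrows <- vector("list", n)
  for (i in seq_len(n - 1)) {
    js <- setdiff(seq(i + 1, n), excl[[i]])
    if (!length(js)) next
    pi_ <- lookup_or_fail(params$vdw, cls[i], "vdw")
    prs <- t(vapply(js, function(j) {
      pj <- lookup_or_fail(params$vdw, cls[j], "vdw")
      c(j, sqrt(pi_[["eps"]] * pj[["eps"]]), pi_[["rstar"]] + pj[["rstar"]])
    }, numeric(3)))
    vrows[[i]] <- cbind(i, prs)
  }
  vdw <- do.call(rbind, c(list(vdw), vrows[!vapply(vrows, is.null, logical(1))]))

  trestr <- matrix(0, 0, 6)
  all_restr <- mol$restraints
  if (!is.null(restraints)) {
    all_restr <- c(all_restr, restraints$torsion)
    for (dr in restraints$distance) {
      drestr <- rbind(drestr, c(dr$atoms, dr$k, dr$r0))
    }
  }
  for (tr in all_restr) {
    trestr <- rbind(trestr, c(tr$atoms, tr$k, tr$phi0_deg * pi / 180))
  }

  list(bonds = bonds, angles = angles, torsions = torsions, vdw = vdw,
       dist_restraints = drestr, tors_restraints = trestr,
       classes = cls)
}

#' Molecular-mechanics energy of a conformer
#'
#' Simplified Allinger-style energy: harmonic bond stretch, harmonic
#' angle bend, 3-term cosine torsions (with a large twofold term for
#' conjugated and double bonds), Lennard-Jones 6-12 van der Waals
#' excluding 1-2/1-3 pairs, plus restraint terms (ring closure, diene
#' lock). Bond dipoles are summed for the reported dipole vector but do
#' not contribute to the energy.
#'
#' @param mol A `macro_molecule`.
#' @param conf N x 3 coordinate matrix.
#' @param params An `ff_params` set.
#' @param restraints Extra restraints, see [mm_system()].
#' @param system Optional precomputed [mm_system()] (overrides
#'   `params`/`restraints`); used in hot loops.
#' @return List with components `stretch`, `bend`, `torsion`, `vdw`,
#'   `restraint`, `total` (kcal/mol) and `dipole_vector` (Debye).
#' @export
energy <- function(mol, conf, params = default_params(), restraints = NULL,
                   system = NULL) {
  if (is.null(system)) system <- mm_system(mol, params, restraints)
  out <- mm_energy_cpp(as.matrix(conf), system)
  out$dipole_vector <- dipole_vector(mol, conf, params)
  out
}

#' Analytic energy gradient
#'
#' @inheritParams energy
#' @return List with `energy` (kcal/mol) and `gradient` (N x 3,
#'   kcal/mol/A).
#' @export
energy_gradient <- function(mol, conf, params = default_params(),
                            restraints = NULL, system = NULL) {
  if (is.null(system)) system <- mm_system(mol, params, restraints)
  mm_gradient_cpp(as.matrix(conf), system)
}

#' Local energy minimisation
#'
#' Limited-memory quasi-Newton descent with a backtracking (Armijo)
#' line search; the recorded energy trace is monotone non-increasing.
#' Terminates when the gradient root-mean-square drops below `tol` or
#' at the iteration cap.
#'
#' @inheritParams energy
#' @param tol Gradient RMS threshold, kcal/mol/A.
#' @param max_iter Iteration cap.
#' @return A [conformer()] with the final energy; attributes `trace`
#'   (energy per accepted iterate) and `converged`.
#' @export
minimize <- function(mol, conf, params = default_params(), restraints = NULL,
                     tol = 0.01, max_iter = 2000, system = NULL) {
  if (is.null(system)) system <- mm_system(mol, params, restraints)
  res <- mm_minimize_cpp(as.matrix(conf), system, tol, max_iter)
  if (isTRUE(res$diverged)) {
    mc_stop(sprintf("minimisation diverged (E = %.3g kcal/mol)", res$energy),
            "macroconf_minimization_failure")
  }
  out <- conformer(res$coords, energy = res$energy,
                   source_seed = attr(conf, "source_seed"))
  attr(out, "trace") <- res$trace
  attr(out, "converged") <- res$converged
  out
}

# bond-dipole vector sum (Debye); direction from + class atom to - class atom
dipole_vector <- function(mol, conf, params = default_params()) {
  cls <- atom_classes(mol)
  conf <- as.matrix(conf)
  mu <- c(0, 0, 0)
  for (r in seq_len(nrow(mol$bonds))) {
    b <- mol$bonds[r, ]
    tok <- order_token(b$order)
    k1 <- paste(cls[b$i], cls[b$j], tok, sep = ":")
    k2 <- paste(cls[b$j], cls[b$i], tok, sep = ":")
    if (!is.null(params$dipole[[k1]])) {
      d <- conf[b$j, ] - conf[b$i, ]
      mu <- mu + params$dipole[[k1]] * d / sqrt(sum(d^2))
    } else if (!is.null(params$dipole[[k2]])) {
      d <- conf[b$i, ] - conf[b$j, ]
      mu <- mu + params$dipole[[k2]] * d / sqrt(sum(d^2))
    }
  }
  mu
}

#' Dipole moment from bond dipoles
#'
#' Vector sum of the parameterised bond dipoles (C=O, C-O, Csp3-Csp2),
#' each oriented along its bond. With a generic parameter set only the
#' ordering of dipole magnitudes between conformers is meaningful, not
#' the absolute values.
#'
#' @inheritParams energy
#' @return Magnitude in Debye, with the vector as attribute `vector`.
#' @export
dipole_moment <- function(mol, conf, params = default_params()) {
  v <- dipole_vector(mol, conf, params)
  structure(sqrt(sum(v^2)), vector = v)
}

#' Steric accessibility of the two faces of a site plane
#'
#' Sums atom volumes (4/3 pi r*^3, Lennard-Jones radius) inside an
#' approach cylinder above and below the site plane: atoms whose
#' projection lies within `lateral` Angstrom of the site centroid and
#' whose signed distance to the plane falls in
#' \[`slab[1]`, `slab[2]`\]. The defaults emulate a small reagent
#' approaching the pi face along the normal: the cylinder has the
#' lateral footprint of the site itself and extends to van der Waals
#' contact height, so distant backbone atoms that merely arch over the
#' site periphery are not counted. A face occupied by the
#' tricarbonyliron pseudo-atom scores much higher, so the clear face
#' for peripheral attack is the one with the smaller score.
#'
#' @inheritParams energy
#' @param site_plane A plane from [least_squares_plane()], with the
#'   site atom indices as attribute `atom_idx` (set by
#'   [compute_attributes()]) or passed via `exclude`.
#' @param slab Two distances (Angstrom) bounding the probe cylinder's
#'   height band.
#' @param lateral Lateral cutoff from the site centroid, Angstrom.
#' @param exclude Atom indices excluded from the occupancy sum (the
#'   site atoms themselves).
#' @return Named numeric vector `c(plus = , minus = )`, cubic Angstrom.
#' @export
face_accessibility <- function(mol, conf, site_plane,
                               slab = c(0.5, 3.0), lateral = 2.5,
                               exclude = attr(site_plane, "atom_idx"),
                               params = default_params()) {
  conf <- as.matrix(conf)
  cls <- atom_classes(mol)
  n <- sqrt(sum(site_plane$normal^2))
  nrm <- site_plane$normal / n
  rel <- sweep(conf, 2, site_plane$centroid)
  d <- as.vector(rel %*% nrm)
  lat <- sqrt(rowSums((rel - outer(d, nrm))^2))
  vol <- vapply(cls, function(cl) {
    r <- lookup_or_fail(params$vdw, cl, "vdw")[["rstar"]]
    4 / 3 * pi * r^3
  }, numeric(1))
  keep <- lat <= lateral
  if (!is.null(exclude)) keep[exclude] <- FALSE
  plus <- keep & d >= slab[1] & d <= slab[2]
  minus <- keep & d <= -slab[1] & d >= -slab[2]
  c(plus = sum(vol[plus]), minus = sum(vol[minus]))
}
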
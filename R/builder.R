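#' Macrolactone ring recipe
#'
#' The 18-membered alpha,beta-unsaturated macrolactone family studied
#' here is generated from a small recipe: ring = ester oxygen O1 +
#' carbonyl carbon C2 (with exocyclic O19) + conjugated ene C3=C4 +
#' `n2` methylenes + a 4-carbon diene + `n1` methylenes, closing back
#' onto O1. The symmetric isomer "18s" has n1 = n2 = 5 and the
#' dissymmetric "18d" has n1 = 4, n2 = 6.
#'
#' @param n1 Saturated chain length between the diene and the ester
#'   oxygen.
#' @param n2 Saturated chain length between the ene and the diene.
#' @param complexed Whether the tricarbonyliron steric model is to be
#'   attached.
#' @return An object of class `macrolactone_spec`.
#' @export
macrolactone_spec <- function(n1, n2, complexed = FALSE) {
  if (n1 < 2 || n2 < 2 || n1 + n2 + 8 != 18) {
    mc_stop(sprintf(
      "invalid ring recipe: n1 + n2 + 8 = %d, must equal ring size 18",
      n1 + n2 + 8), "macroconf_spec_error")
  }
  structure(list(ring_size = 18L, n1 = as.integer(n1), n2 = as.integer(n2),
                 complexed = isTRUE(complexed)),
            class = "macrolactone_spec")
}

#' @rdname macrolactone_spec
#' @param molecule "18s" or "18d".
#' @export
spec_by_name <- function(molecule = c("18s", "18d"), complexed = FALSE) {
  molecule <- match.arg(molecule)
  if (molecule == "18s") macrolactone_spec(5, 5, complexed)
  else macrolactone_spec(4, 6, complexed)
}

#' Tricarbonyliron steric model
#'
#' Fe(CO)3 is represented by a single pseudo-atom with an enlarged van
#' der Waals radius placed on one diene face, plus a torsional
#' restraint keeping the diene s-cis: the complex acts as a steric
#' blocker and a rigidifier, with no electronic structure.
#'
#' @param fe_height Distance of the pseudo-atom from the diene plane,
#'   Angstrom (within 1.5--2.0).
#' @param steric_radius Lennard-Jones r* of the pseudo-atom, Angstrom.
#' @param lock_diene_scis Restrain the central diene torsion near 0.
#' @param face_sign +1 or -1, which diene face is occupied.
#' @return An object of class `complex_model`.
#' @export
complex_model <- function(fe_height = 1.7, steric_radius = 2.8,
                          lock_diene_scis = TRUE, face_sign = 1) {
  if (fe_height < 1.5 || fe_height > 2.0) {
    mc_stop("fe_height must lie in [1.5, 2.0] Angstrom",
            "macroconf_spec_error")
  }
  structure(list(fe_height = fe_height, steric_radius = steric_radius,
                 lock_diene_scis = isTRUE(lock_diene_scis),
                 face_sign = sign(face_sign)),
            class = "complex_model")
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build a macrolactone and its initial conformer
#'
#' Lays the 18 ring atoms on a circle (ideal bond lengths, seeded
#' out-of-plane jitter to break planarity), attaches the exocyclic
#' carbonyl oxygen and all hydrogens from local valence geometry, then
#' relaxes the structure under the force field with the ring-closure
#' restraint. Torsion labels are set so `phi1` is the enone ester
#' torsion O19-C2-C3-C4 and `phi2` the central diene torsion (ring
#' atoms 10-11-12-13 for 18s, 11-12-13-14 for 18d).
#'
#' @param spec A [macrolactone_spec()] (complexation is applied
#'   separately via [attach_tricarbonyliron()]).
#' @param seed Integer seed for the jitter.
#' @param params Force-field parameters.
#' @param minimize_init Relax the template after construction.
#' @return List with `molecule` and `conformer`.
#' @export
build_macrolactone <- function(spec, seed = 0, params = default_params(),
                               minimize_init = TRUE) {
  stopifnot(inherits(spec, "macrolactone_spec"))
  n1 <- spec$n1; n2 <- spec$n2

  ring_el <- c("O", rep("C", 17))
  d1 <- 5 + n2                       # first diene carbon (ring index)
  sp2 <- c(2, 3, 4, d1, d1 + 1, d1 + 2, d1 + 3)

  atoms <- data.frame(
    element = ring_el,
    label = c("O1", paste0("C", 2:18)),
    ring_index = 1:18,
    stringsAsFactors = FALSE)
  atoms <- rbind(atoms, data.frame(element = "O", label = "O19",
                                   ring_index = NA, stringsAsFactors = FALSE))

  ring_orders <- character(18)       # bond ring k -> k+1 (18 closes to 1)
  for (k in 1:18) {
    nxt <- k %% 18 + 1
    ring_orders[k] <-
      if (k == 1) "ester"                                  # O1-C2
      else if (k == 3) "double"                            # C3=C4
      else if (k == d1 || k == d1 + 2) "double"            # diene doubles
      else "single"
  }
  bonds <- data.frame(i = 1:18, j = (1:18) %% 18 + 1, order = ring_orders,
                      stringsAsFactors = FALSE)
  bonds <- rbind(bonds, data.frame(i = 2, j = 19, order = "double",
                                   stringsAsFactors = FALSE))

  # hydrogens: 1 on each sp2 CH (C3, C4, diene), 2 on each methylene
  h_rows <- list()
  h_of <- list()
  nh <- 0L
  for (k in setdiff(2:18, 2)) {
    cnt <- if (k %in% sp2) 1L else 2L
    for (u in seq_len(cnt)) {
      nh <- nh + 1L
      h_rows[[nh]] <- data.frame(element = "H",
                                 label = sprintf("H%d%s", k, letters[u]),
                                 ring_index = NA, stringsAsFactors = FALSE)
      h_of[[nh]] <- k
    }
  }
  h_idx0 <- 19L
  atoms <- rbind(atoms, do.call(rbind, h_rows))
  bonds <- rbind(bonds, data.frame(i = unlist(h_of),
                                   j = h_idx0 + seq_len(nh),
                                   order = "single", stringsAsFactors = FALSE))

  torsion_labels <- list(phi1 = c(19L, 2L, 3L, 4L),
                         phi2 = as.integer(c(d1, d1 + 1, d1 + 2, d1 + 3)))

  mol <- macro_molecule(
    name = sprintf("macrolactone-18%s", if (n1 == n2) "s" else "d"),
    atoms = atoms, bonds = bonds, torsion_labels = torsion_labels,
    closure_bond = c(18L, 1L))

  conf <- with_seed(seed, initial_coordinates(mol, spec))
  attr(conf, "source_seed") <- as.integer(seed)
  if (minimize_init) {
    conf <- minimize(mol, conf, params, tol = 0.02, max_iter = 4000)
    # closure-bond contract: within 0.15 A of its equilibrium length
    r <- sqrt(sum((conf[18, ] - conf[1, ])^2))
    r0 <- params$stretch[["C:O:1"]][["r0"]]
    if (abs(r - r0) > 0.15) {
      conf <- minimize(mol, conf, params, tol = 0.005, max_iter = 8000)
      r <- sqrt(sum((conf[18, ] - conf[1, ])^2))
      if (abs(r - r0) > 0.15) {
        mc_stop(sprintf("ring closure failed: |r - r0| = %.3f A", abs(r - r0)),
                "macroconf_builder_error")
      }
    }
  }
  list(molecule = mol, conformer = conf)
}

# circle template + local-frame substituent placement
initial_coordinates <- function(mol, spec) {
  n <- 18
  rad <- 1.50 / (2 * sin(pi / n))
  th <- 2 * pi * (0:(n - 1)) / n
  ring_xy <- cbind(rad * cos(th), rad * sin(th), runif(n, -0.35, 0.35))
  coords <- matrix(0, n_atoms(mol), 3)
  coords[1:18, ] <- ring_xy

  place_subst <- function(center, nb1, nb2, len, n_out, spread = 54.75) {
    u1 <- nb1 - center; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- nb2 - center; u2 <- u2 / sqrt(sum(u2^2))
    bis <- -(u1 + u2)
    if (sqrt(sum(bis^2)) < 1e-6) bis <- cross3(u1, c(0, 0, 1))
    bis <- bis / sqrt(sum(bis^2))
    w <- cross3(u1, u2)
    if (sqrt(sum(w^2)) < 1e-6) w <- c(0, 0, 1)
    w <- w / sqrt(sum(w^2))
    a <- spread * pi / 180
    if (n_out == 1) {
      list(center + len * bis)
    } else {
      list(center + len * (cos(a) * bis + sin(a) * w),
           center + len * (cos(a) * bis - sin(a) * w))
    }
  }

  nxt <- function(k) k %% 18 + 1
  prv <- function(k) (k - 2) %% 18 + 1
  # exocyclic carbonyl oxygen on C2
  coords[19, ] <- place_subst(coords[2, ], coords[1, ], coords[3, ],
                              1.225, 1)[[1]]
  # hydrogens, in atom order as built
  h <- 19L
  hb <- mol$bonds[mol$bonds$j > 19, ]
  for (r in seq_len(nrow(hb))) {
    k <- hb$i[r]
    n_out <- sum(hb$i == k)
    which_h <- sum(hb$i[seq_len(r)] == k)
    pos <- place_subst(coords[k, ], coords[prv(k), ], coords[nxt(k), ],
                       1.09, n_out)
    coords[hb$j[r], ] <- pos[[min(which_h, length(pos))]]
  }
  conformer(coords)
}

# staged torsion driving: restrain a quadruple to a target in <=60 deg
# steps along the shorter arc, relaxing after each stage
drive_torsion <- function(mol, conf, quad, target, params = default_params(),
                          k = 40, extra_restraints = NULL, tol = 0.02) {
  cur <- dihedral_angle(conf[quad[1], ], conf[quad[2], ],
                        conf[quad[3], ], conf[quad[4], ])
  delta <- ((target - cur + 180) %% 360) - 180
  n_stage <- max(1, ceiling(abs(delta) / 60))
  for (s in seq_len(n_stage)) {
    tgt <- cur + delta * s / n_stage
    restr <- list(torsion = c(list(list(atoms = quad, k = k, phi0_deg = tgt)),
                              extra_restraints))
    conf <- minimize(mol, conf, params, restraints = restr,
                     tol = tol, max_iter = 3000)
  }
  conf
}

#' Attach the tricarbonyliron steric model to a diene
#'
#' Optionally drives the diene to s-cis (staged torsional restraint +
#' relaxation), places the Fe pseudo-atom at `fe_height` Angstrom above
#' the diene-plane centroid on the chosen face, bonds it to the four
#' diene carbons by coordination bonds (stretch terms only), and
#' registers the permanent diene s-cis lock so the subsequent search
#' keeps the complexed diene planar-cis.
#'
#' @param mol,conf A built macrolactone and a conformer.
#' @param face_sign +1 or -1 diene face (overrides `model$face_sign`).
#' @param model A [complex_model()].
#' @param params Force-field parameters.
#' @param relax Relax the complexed structure before returning.
#' @return List with the complexed `molecule` and `conformer`.
#' @export
attach_tricarbonyliron <- function(mol, conf, face_sign = NULL,
                                   model = complex_model(),
                                   params = default_params(), relax = TRUE) {
  if (is.null(mol$torsion_labels$phi2)) {
    mc_stop("no diene found: molecule lacks a phi2 torsion label",
            "macroconf_builder_error")
  }
  if (is.null(face_sign)) face_sign <- model$face_sign
  quad <- mol$torsion_labels$phi2

  if (model$lock_diene_scis) {
    conf <- drive_torsion(mol, conf, quad, 0, params, k = 50)
  }

  ring <- ring_atoms(mol)
  ring_ctr <- colMeans(conf[ring, ])
  pl <- least_squares_plane(conf[quad, ],
                            orient = colMeans(conf[quad, ]) - ring_ctr)
  fe_pos <- pl$centroid + face_sign * model$fe_height * pl$normal

  atoms <- rbind(mol$atoms,
                 data.frame(element = "Fe", label = "FE1", ring_index = NA,
                            stringsAsFactors = FALSE))
  fe <- nrow(atoms)
  bonds <- rbind(mol$bonds,
                 data.frame(i = quad, j = fe, order = "coordination",
                            stringsAsFactors = FALSE))
  restr <- mol$restraints
  if (model$lock_diene_scis) {
    restr <- c(restr, list(list(atoms = quad, k = 50, phi0_deg = 0)))
  }
  cmol <- macro_molecule(paste0(mol$name, "-Fe(CO)3"), atoms, bonds,
                         mol$torsion_labels, mol$closure_bond, restr)
  cmol$frozen_torsion_bonds <- list(quad[2:3])
  cconf <- conformer(rbind(as.matrix(conf), fe_pos),
                     source_seed = attr(conf, "source_seed"))
  if (relax) {
    cconf <- minimize(cmol, cconf, params, tol = 0.01, max_iter = 4000)
  }
  list(molecule = cmol, conformer = cconf)
}

#' Planted-geometry fixture for one conformational type
#'
#' Generates a conformer whose geometric attributes (diene s-cis or
#' s-trans, ester s-cis or s-trans, pseudoparallel or pseudoantiparallel
#' site planes) match a requested type label, by randomising the
#' saturated ring torsions, driving `phi1` and `phi2` to the class
#' targets under torsional restraints, relaxing, and verifying with the
#' classifier. Deterministic given the seed.
#'
#' @param type_label Integer 1..8.
#' @param spec A [macrolactone_spec()].
#' @param seed Integer seed.
#' @param params Force-field parameters.
#' @param max_attempts Attempt cap before a fixture error is raised.
#' @param built Optional prebuilt `list(molecule, conformer)` to reuse
#'   across labels.
#' @return A [conformer()]; the molecule is the built macrolactone.
#' @export
make_planted_conformer <- function(type_label, spec, seed = 0,
                                   params = default_params(),
                                   max_attempts = 40, built = NULL) {
  if (!(type_label %in% 1:8)) {
    mc_stop("type label must be in 1..8", "macroconf_fixture_error")
  }
  want <- type_definition(type_label)
  if (is.null(built)) built <- build_macrolactone(spec, seed = seed,
                                                  params = params)
  mol <- built$molecule
  base <- built$conformer
  phi1_t <- if (want$ester_conf == "s-cis") 0 else 180
  phi2_t <- if (want$diene_conf == "s-cis") 0 else 180

  with_seed(seed * 1000 + type_label, {
    rot <- rotatable_torsions(mol)
    sat <- Filter(function(rt) {
      !any(rt$axis %in% c(mol$torsion_labels$phi1[2:3],
                          mol$torsion_labels$phi2[2:3]))
    }, rot)
    for (att in seq_len(max_attempts)) {
      conf <- base
      for (rt in sat) {
        ang <- runif(1, -120, 120)
        conf <- apply_torsion_rotation(conf, rt, ang)
      }
      conf <- tryCatch({
        conf <- minimize(mol, conf, params, tol = 0.05, max_iter = 1500)
        conf <- drive_torsion(mol, conf, mol$torsion_labels$phi1, phi1_t,
                              params, k = 30)
        conf <- drive_torsion(mol, conf, mol$torsion_labels$phi2, phi2_t,
                              params, k = 30)
        restr <- list(torsion = list(
          list(atoms = mol$torsion_labels$phi1, k = 30, phi0_deg = phi1_t),
          list(atoms = mol$torsion_labels$phi2, k = 30, phi0_deg = phi2_t)))
        minimize(mol, conf, params, restraints = restr, tol = 0.01,
                 max_iter = 3000)
      }, macroconf_minimization_failure = function(e) NULL)
      if (is.null(conf)) next
      at <- compute_attributes(mol, conf)
      ty <- assign_type(at)
      margin_ok <- circ_diff(at$phi1, phi1_t) < 50 &&
        circ_diff(at$phi2, phi2_t) < 50 && abs(at$plane_angle - 45) > 5
      if (ty$label == type_label && margin_ok) {
        return(conf)
      }
    }
    mc_stop(sprintf("could not plant a type-%d conformer in %d attempts",
                    type_label, max_attempts), "macroconf_fixture_error")
  })
}
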
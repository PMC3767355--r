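#' Geometric attributes of a conformer
#'
#' Extracts the three attributes that define the eight conformational
#' types: the enone ester torsion `phi1` (O19-C2-C3-C4), the central
#' diene torsion `phi2`, and the mutual arrangement of the diene plane
#' (least-squares plane of the four diene carbons) and the conjugated
#' ester plane (O19, C2, O1, C3).
#'
#' Conventions, fixed and unit-tested:
#' * s-cis means |phi| < 90 degrees, s-trans |phi| >= 90 (s-trans wins
#'   the tie at exactly 90).
#' * Each site normal is oriented by the site's winding direction: the
#'   sum of cross products of consecutive edges of the four site ring
#'   atoms traversed in ring order. The oriented normal thus marks the
#'   pi face that the ring traversal winds counter-clockwise around,
#'   an intrinsic reference that does not depend on how the macrocycle
#'   folds.
#' * The planes are pseudoparallel when their mutual angle is below 45
#'   degrees *and* the winding-oriented normals point to the same side
#'   (positive dot product); otherwise pseudoantiparallel, which also
#'   wins the tie at exactly 45 degrees.
#'
#' @param mol A built `macro_molecule` (torsion labels present).
#' @param conf N x 3 coordinate matrix.
#' @return An object of class `conformer_attributes`: `phi1`, `phi2`
#'   (degrees), `ester_conf`, `diene_conf` ("s-cis"/"s-trans"),
#'   `plane_angle` (degrees, \[0, 90\]), `arrangement`
#'   ("pseudoparallel"/"pseudoantiparallel"), and the two site planes.
#' @export
compute_attributes <- function(mol, conf) {
  tl <- mol$torsion_labels
  if (is.null(tl$phi1) || is.null(tl$phi2)) {
    mc_stop("molecule lacks phi1/phi2 torsion labels",
            "macroconf_model_error")
  }
  conf <- as.matrix(conf)
  q1 <- tl$phi1; q2 <- tl$phi2
  phi1 <- dihedral_angle(conf[q1[1], ], conf[q1[2], ], conf[q1[3], ],
                         conf[q1[4], ])
  phi2 <- dihedral_angle(conf[q2[1], ], conf[q2[2], ], conf[q2[3], ],
                         conf[q2[4], ])

  ring <- ring_atoms(mol)
  ester_idx <- c(atom_by_label(mol, "O19"), atom_by_label(mol, "C2"),
                 atom_by_label(mol, "O1"), atom_by_label(mol, "C3"))
  diene_idx <- q2
  # winding references from the site ring atoms in ring order:
  # enone unit O1-C2-C3-C4 and the four diene carbons
  ester_pl <- least_squares_plane(
    conf[ester_idx, ], orient = site_winding(conf[ring[1:4], ]))
  diene_pl <- least_squares_plane(
    conf[diene_idx, ], orient = site_winding(conf[q2, ]))
  attr(ester_pl, "atom_idx") <- ester_idx
  attr(diene_pl, "atom_idx") <- diene_idx

  pa <- interplane_angle(ester_pl$normal, diene_pl$normal)
  same_side <- sum(ester_pl$normal * diene_pl$normal) > 0
  arrangement <- if (pa < 45 && same_side) "pseudoparallel"
                 else "pseudoantiparallel"

  structure(list(
    phi1 = phi1, phi2 = phi2,
    ester_conf = if (abs(phi1) < 90) "s-cis" else "s-trans",
    diene_conf = if (abs(phi2) < 90) "s-cis" else "s-trans",
    plane_angle = pa, arrangement = arrangement,
    ester_plane = ester_pl, diene_plane = diene_pl),
    class = "conformer_attributes")
}

# winding direction of a 4-atom site traversed in ring order: the sum
# of cross products of consecutive edges (the local traversal normal)
site_winding <- function(p) {
  e1 <- p[2, ] - p[1, ]
  e2 <- p[3, ] - p[2, ]
  e3 <- p[4, ] - p[3, ]
  cross3(e1, e2) + cross3(e2, e3)
}

#' The frozen attribute-to-type mapping
#'
#' The eight conformational types are the 2 x 2 x 2 cube of
#' (arrangement, diene conformation, ester conformation). Even labels
#' are pseudoparallel and odd labels pseudoantiparallel; within each
#' parity pair the label is fixed by the frozen table below. These
#' label numbers are this package's own convention: only the
#' parity rule is shared with other labelings of the same eight
#' classes.
#'
#' | label | arrangement        | diene   | ester   |
#' |------:|--------------------|---------|---------|
#' | 1     | pseudoantiparallel | s-cis   | s-cis   |
#' | 2     | pseudoparallel     | s-cis   | s-cis   |
#' | 3     | pseudoantiparallel | s-cis   | s-trans |
#' | 4     | pseudoparallel     | s-cis   | s-trans |
#' | 5     | pseudoantiparallel | s-trans | s-cis   |
#' | 6     | pseudoparallel     | s-trans | s-cis   |
#' | 7     | pseudoantiparallel | s-trans | s-trans |
#' | 8     | pseudoparallel     | s-trans | s-trans |
#'
#' @return Data frame with columns `label`, `arrangement`,
#'   `diene_conf`, `ester_conf`.
#' @export
type_map <- function() {
  g <- expand.grid(
    arrangement = c("pseudoantiparallel", "pseudoparallel"),
    ester_conf = c("s-cis", "s-trans"),
    diene_conf = c("s-cis", "s-trans"),
    stringsAsFactors = FALSE)
  g$label <- seq_len(8)
  g[, c("label", "arrangement", "diene_conf", "ester_conf")]
}

type_definition <- function(label) {
  tm <- type_map()
  as.list(tm[tm$label == label, ])
}

#' Assign a conformational type
#'
#' Total, deterministic mapping from attributes to one of the eight
#' type labels of [type_map()]. Even labels are pseudoparallel, odd
#' labels pseudoantiparallel.
#'
#' @param attrs A `conformer_attributes` object (or any list with
#'   `arrangement`, `diene_conf`, `ester_conf`).
#' @return An object of class `conformer_type` with fields `label`,
#'   `arrangement`, `diene_conf`, `ester_conf`.
#' @export
assign_type <- function(attrs) {
  d <- attrs$diene_conf == "s-trans"
  e <- attrs$ester_conf == "s-trans"
  p <- attrs$arrangement == "pseudoparallel"
  label <- 2L * (2L * d + e) + 1L + p
  structure(list(label = as.integer(label), arrangement = attrs$arrangement,
                 diene_conf = attrs$diene_conf, ester_conf = attrs$ester_conf),
            class = "conformer_type")
}

#' @export
print.conformer_type <- function(x, ...) {
  cat(sprintf("<conformer_type> %d (%s, diene %s, ester %s)\n", x$label,
              x$arrangement, x$diene_conf, x$ester_conf))
  invisible(x)
}

#' Per-type census of a conformer ensemble
#'
#' Classifies every conformer and reports, per populated type, the
#' minimum energy, the energy difference to the ensemble global
#' minimum, the conformer count, and the geometry of the type
#' representative (its lowest-energy member). Types absent from the
#' ensemble are omitted.
#'
#' @param ensemble A `conformer_ensemble` from [run_search()].
#' @return Data frame with columns `type`, `delta_e`, `count`, `phi1`,
#'   `phi2`, `plane_angle`, sorted by `delta_e`.
#' @export
type_census <- function(ensemble) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  mol <- ensemble$molecule
  confs <- ensemble$conformers
  if (!length(confs)) {
    mc_stop("empty ensemble", "macroconf_model_error")
  }
  rows <- lapply(confs, function(cf) {
    at <- compute_attributes(mol, cf)
    data.frame(type = assign_type(at)$label, energy = conf_energy(cf),
               phi1 = at$phi1, phi2 = at$phi2, plane_angle = at$plane_angle)
  })
  d <- do.call(rbind, rows)
  gmin <- min(d$energy)
  out <- do.call(rbind, lapply(split(d, d$type), function(g) {
    rep_ <- g[which.min(g$energy), ]
    data.frame(type = rep_$type, delta_e = rep_$energy - gmin,
               count = nrow(g), phi1 = rep_$phi1, phi2 = rep_$phi2,
               plane_angle = rep_$plane_angle)
  }))
  out <- out[order(out$delta_e, out$type), ]
  rownames(out) <- NULL
  out
}
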
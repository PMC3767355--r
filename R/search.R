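#' Monte-Carlo search configuration
#'
#' Sampling runs at 1000 K (the high-temperature conformational-search
#' regime), records quench-minimised structures, and keeps the
#' deduplicated ensemble within a 6 kcal/mol window above the global
#' minimum.
#'
#' @param temperature_K Metropolis sampling temperature, Kelvin.
#' @param n_steps Number of Monte-Carlo steps.
#' @param max_torsion_step Largest single torsion rotation, degrees.
#' @param quench_every Steps between full quench-minimise-and-record.
#' @param energy_window Retained window above the global minimum,
#'   kcal/mol.
#' @param dedup_threshold Torsion-space distance (degrees) below which
#'   two conformers count as duplicates.
#' @param seed Integer RNG seed.
#' @param relax_iter Iteration cap of the short relaxation applied to
#'   each proposal before the Metropolis test (the ring-closure
#'   restraint makes raw rigid-rotation energies uninformative).
#' @param n_walkers Number of independent Markov chains; the step
#'   budget `n_steps` is split across them and each starts from a
#'   torsion-randomised, quenched structure, which is how the search
#'   reaches basins (notably diene flips) that a closed ring's
#'   closure coupling makes hard to cross by single-torsion moves.
#' @return An object of class `search_config`.
#' @export
search_config <- function(temperature_K = 1000, n_steps = 20000,
                          max_torsion_step = 60, quench_every = 25,
                          energy_window = 6.0, dedup_threshold = 30,
                          seed = 0, relax_iter = 60, n_walkers = 8) {
  stopifnot(temperature_K > 0, n_steps > 0, max_torsion_step >= 0,
            quench_every > 0, energy_window > 0, dedup_threshold > 0,
            n_walkers >= 1)
  structure(list(temperature_K = temperature_K, n_steps = as.integer(n_steps),
                 max_torsion_step = max_torsion_step,
                 quench_every = as.integer(quench_every),
                 energy_window = energy_window,
                 dedup_threshold = dedup_threshold, seed = as.integer(seed),
                 relax_iter = as.integer(relax_iter),
                 n_walkers = as.integer(n_walkers)),
            class = "search_config")
}

GAS_CONSTANT_KCAL <- 1.987e-3  # kcal/mol/K

#' Metropolis acceptance rule
#'
#' Accept if the energy does not increase, otherwise with probability
#' exp(-deltaE / RT). A move with deltaE exactly 0 is accepted (the
#' documented boundary convention).
#'
#' @param delta_e Energy change, kcal/mol.
#' @param temperature_K Temperature, Kelvin.
#' @param random_draw A uniform draw in \[0, 1).
#' @return Logical.
#' @export
metropolis_accept <- function(delta_e, temperature_K, random_draw) {
  if (!is.finite(delta_e)) {
    mc_stop("non-finite energy difference", "macroconf_search_error")
  }
  stopifnot(temperature_K > 0)
  delta_e <= 0 || random_draw < exp(-delta_e / (GAS_CONSTANT_KCAL * temperature_K))
}

#' Rotatable ring torsions and their moving sets
#'
#' Enumerates the single (and ester C-O) ring bonds about which a
#' torsional move may rotate: double bonds, the ring-closure bond and
#' any frozen (complexed-diene) bond are excluded. For each bond the
#' moving set - the atoms downstream in the spanning tree obtained by
#' deleting the closure bond - is precomputed.
#'
#' @param mol A built `macro_molecule`.
#' @return List of `list(axis = c(j, k), moving)` entries; `moving` is
#'   the atom set rotated by a move about the axis (the downstream
#'   component when the closure bond and the axis bond are deleted).
#' @export
rotatable_torsions <- function(mol) {
  ring <- ring_atoms(mol)
  n <- length(ring)
  closure <- sort(mol$closure_bond)
  frozen <- lapply(mol$frozen_torsion_bonds, sort)

  b <- mol$bonds
  bond_order <- function(i, j) {
    hit <- (pmin(b$i, b$j) == min(i, j)) & (pmax(b$i, b$j) == max(i, j))
    b$order[hit][1]
  }
  # adjacency with the closure bond deleted
  keep <- !((pmin(b$i, b$j) == closure[1]) & (pmax(b$i, b$j) == closure[2]))
  bb <- b[keep, ]
  nat <- n_atoms(mol)
  adj <- vector("list", nat)
  for (r in seq_len(nrow(bb))) {
    adj[[bb$i[r]]] <- c(adj[[bb$i[r]]], bb$j[r])
    adj[[bb$j[r]]] <- c(adj[[bb$j[r]]], bb$i[r])
  }

  component_from <- function(start, banned_edge) {
    seen <- logical(nat)
    seen[start] <- TRUE
    stack <- start
    while (length(stack)) {
      v <- stack[[1]]
      stack <- stack[-1]
      for (w in adj[[v]]) {
        if (v == banned_edge[1] && w == banned_edge[2]) next
        if (v == banned_edge[2] && w == banned_edge[1]) next
        if (!seen[w]) {
          seen[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    which(seen)
  }

  out <- list()
  for (k in seq_len(n - 1)) {            # ring bonds except the closure
    j_at <- ring[k]; k_at <- ring[k + 1]
    if (all(sort(c(j_at, k_at)) == closure)) next
    ord <- bond_order(j_at, k_at)
    if (ord %in% c("double", "coordination")) next
    if (length(frozen) &&
        any(vapply(frozen, function(f) all(f == sort(c(j_at, k_at))),
                   logical(1)))) next
    moving <- component_from(k_at, c(j_at, k_at))
    if (j_at %in% moving) next           # axis sits in a residual cycle
    out[[length(out) + 1]] <- list(axis = c(j_at, k_at), moving = moving)
  }
  if (!length(out)) {
    mc_stop("empty move set: no rotatable torsions",
            "macroconf_search_error")
  }
  out
}

# rotate the moving set of a rotatable torsion by ang degrees
apply_torsion_rotation <- function(conf, rt, ang) {
  conf <- as.matrix(conf)
  a1 <- conf[rt$axis[1], ]
  a2 <- conf[rt$axis[2], ]
  axis <- a2 - a1
  moved <- sweep(conf[rt$moving, , drop = FALSE], 2, a2)
  conf[rt$moving, ] <- sweep(rotate_about_axis(moved, axis, ang), 2, a2, "+")
  conf
}

#' Propose one torsional Monte-Carlo move
#'
#' Rotates one uniformly chosen rotatable torsion by a uniform angle in
#' (-max_torsion_step, +max_torsion_step). Uses the current R RNG
#' stream.
#'
#' @param conf Coordinate matrix.
#' @param mol The molecule.
#' @param config A [search_config()].
#' @param rotatable Precomputed [rotatable_torsions()] (recomputed if
#'   omitted).
#' @return The proposed coordinate matrix, with the chosen torsion
#'   index as attribute `torsion_index`.
#' @export
propose_move <- function(conf, mol, config, rotatable = NULL) {
  if (is.null(rotatable)) rotatable <- rotatable_torsions(mol)
  idx <- sample.int(length(rotatable), 1)
  ang <- runif(1, -config$max_torsion_step, config$max_torsion_step)
  out <- apply_torsion_rotation(conf, rotatable[[idx]], ang)
  attr(out, "torsion_index") <- idx
  out
}

#' Metropolis Monte-Carlo conformational search with quenching
#'
#' Samples ring-torsion space at `temperature_K` with `n_walkers`
#' independent Markov chains sharing the `n_steps` budget. Each walker
#' starts from a torsion-randomised, quench-minimised copy of the
#' initial structure (the frozen complexed-diene bond, if any, is
#' never randomised). Each step rotates one rotatable torsion, briefly
#' relaxes the proposal (the ring-closure restraint dominates raw
#' rigid-rotation energies), and applies the Metropolis rule to the
#' relaxed energies. Every `quench_every` steps the walker's current
#' structure is fully quench-minimised and recorded (the walker itself
#' continues un-reset). The pooled records are deduplicated by
#' torsion-space distance (keeping the lower-energy member of any
#' close pair) and filtered to the energy window above the global
#' minimum.
#'
#' @param mol A built `macro_molecule`.
#' @param params Force-field parameters.
#' @param config A [search_config()].
#' @param init Starting conformer (a fresh build is used if omitted).
#' @return An object of class `conformer_ensemble`: `molecule`,
#'   `conformers` (energy-sorted), `energies`, `global_min_energy`,
#'   `provenance` (the config) and acceptance statistics.
#' @export
run_search <- function(mol, params = default_params(),
                       config = search_config(), init = NULL) {
  system <- mm_system(mol, params)
  rotatable <- rotatable_torsions(mol)
  quads <- ring_torsion_quads(mol)

  if (is.null(init)) {
    mc_stop("run_search requires an initial conformer", "macroconf_search_error")
  }

  with_seed(config$seed, {
    base <- minimize(mol, init, system = system, tol = 0.01, max_iter = 4000)
    recorded <- list()
    rec_e <- numeric(0)
    n_acc <- 0L
    steps_per_walker <- max(1L, config$n_steps %/% config$n_walkers)

    for (w in seq_len(config$n_walkers)) {
      # torsion-randomised start (first walker keeps the built geometry)
      cur <- base
      if (w > 1) {
        cand <- as.matrix(base)
        for (rt in rotatable) {
          cand <- apply_torsion_rotation(cand, rt, runif(1, -180, 180))
        }
        cur <- tryCatch(
          minimize(mol, conformer(cand), system = system, tol = 0.01,
                   max_iter = 4000),
          macroconf_minimization_failure = function(e) NULL)
        if (is.null(cur) || !closure_ok(mol, cur, system)) cur <- base
      }
      e_cur <- conf_energy(cur)

      for (step in seq_len(steps_per_walker)) {
        prop <- propose_move(cur, mol, config, rotatable)
        relaxed <- tryCatch(
          minimize(mol, conformer(prop), system = system, tol = 0.05,
                   max_iter = config$relax_iter),
          macroconf_minimization_failure = function(e) NULL)
        if (is.null(relaxed)) next   # unrelaxable clash: reject outright
        e_prop <- conf_energy(relaxed)
        if (metropolis_accept(e_prop - e_cur, config$temperature_K,
                              runif(1))) {
          cur <- relaxed
          e_cur <- e_prop
          n_acc <- n_acc + 1L
        }
        if (step %% config$quench_every == 0) {
          # record a quenched copy; the walker continues from its
          # current (hot) state so crossing progress is not reset
          q <- minimize(mol, cur, system = system, tol = 0.01,
                        max_iter = 4000)
          if (closure_ok(mol, q, system)) {
            recorded[[length(recorded) + 1]] <- q
            rec_e <- c(rec_e, conf_energy(q))
          }
        }
      }
    }
    if (!length(recorded)) {
      mc_stop(sprintf(
        "search recorded no conformers (%d steps, %d accepted)",
        config$n_steps, n_acc), "macroconf_search_error")
    }

    # deduplicate: ascending energy, keep if far from everything kept
    ord <- order(rec_e)
    tors <- t(vapply(recorded, conformer_torsions, numeric(length(quads)),
                     torsions = quads))
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept)) {
        kept <- i
        next
      }
      d <- apply(tors[kept, , drop = FALSE], 1, function(tk) {
        max(circ_diff(tk, tors[i, ]))
      })
      if (all(d >= config$dedup_threshold)) kept <- c(kept, i)
    }
    gmin <- min(rec_e[kept])
    kept <- kept[rec_e[kept] <= gmin + config$energy_window]
    kept <- kept[order(rec_e[kept])]

    structure(list(molecule = mol, conformers = recorded[kept],
                   energies = rec_e[kept], global_min_energy = gmin,
                   provenance = config,
                   n_recorded = length(recorded), n_accepted = n_acc),
              class = "conformer_ensemble")
  })
}

# closure-bond restraint satisfied (within 0.15 A of equilibrium)?
closure_ok <- function(mol, conf, system) {
  if (!nrow(system$dist_restraints)) return(TRUE)
  ok <- TRUE
  for (r in seq_len(nrow(system$dist_restraints))) {
    i <- system$dist_restraints[r, 1]
    j <- system$dist_restraints[r, 2]
    r0 <- system$dist_restraints[r, 4]
    d <- sqrt(sum((conf[i, ] - conf[j, ])^2))
    ok <- ok && abs(d - r0) <= 0.15
  }
  ok
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf(
    "<conformer_ensemble> %s: %d conformers in %.1f kcal/mol window (Emin = %.3f)\n",
    x$molecule$name, length(x$conformers), x$provenance$energy_window,
    x$global_min_energy))
  invisible(x)
}
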
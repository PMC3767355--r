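# Shared fixtures and independent oracles for the macroconf test suite.
# Expensive objects (builds, ensembles) are computed once per session and
# cached in this environment.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

built_18s <- function() fixture("built_18s",
  build_macrolactone(spec_by_name("18s"), seed = 0))
built_18d <- function() fixture("built_18d",
  build_macrolactone(spec_by_name("18d"), seed = 0))
complexed_18s <- function() fixture("complexed_18s", {
  b <- built_18s()
  attach_tricarbonyliron(b$molecule, b$conformer)
})

# full-scale search ensembles used by the search/dipole acceptance checks
ensemble_18s_full <- function() fixture("ensemble_18s_full", {
  b <- built_18s()
  run_search(b$molecule, config = search_config(n_steps = 20000, seed = 0),
             init = b$conformer)
})
ensemble_18s_cx_full <- function() fixture("ensemble_18s_cx_full", {
  cx <- complexed_18s()
  run_search(cx$molecule, config = search_config(n_steps = 20000, seed = 0),
             init = cx$conformer)
})

planted_set_18s <- function() fixture("planted_set_18s", {
  b <- built_18s()
  lapply(1:8, function(ty) {
    make_planted_conformer(ty, spec_by_name("18s"), seed = 0, built = b)
  })
})

# --- independent oracles --------------------------------------------------

# dihedral via perpendicular projections onto the central bond (a
# formulation independent of the cross-product-normal implementation)
oracle_dihedral <- function(p1, p2, p3, p4) {
  t <- p3 - p2
  t <- t / sqrt(sum(t^2))
  u <- (p1 - p2) - sum((p1 - p2) * t) * t
  v <- (p4 - p3) - sum((p4 - p3) * t) * t
  cx <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  ang <- atan2(sum(cx * t), sum(u * v)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# least-squares plane normal via eigen-decomposition of the second-moment
# matrix (implementation uses SVD)
oracle_plane_normal <- function(points) {
  x <- sweep(as.matrix(points), 2, colMeans(points))
  ev <- eigen(crossprod(x), symmetric = TRUE)
  n <- ev$vectors[, 3]
  n / sqrt(sum(n^2))
}

# brute-force torsion distance
oracle_torsion_distance <- function(ca, cb, torsions) {
  worst <- 0
  for (q in torsions) {
    a <- dihedral_angle(ca[q[1], ], ca[q[2], ], ca[q[3], ], ca[q[4], ])
    b <- dihedral_angle(cb[q[1], ], cb[q[2], ], cb[q[3], ], cb[q[4], ])
    d <- abs(a - b) %% 360
    if (d > 180) d <- 360 - d
    if (d > worst) worst <- d
  }
  worst
}

# grid-search RT calibration oracle at 1e-3 kcal/mol resolution
oracle_grid_rt <- function(delta_e_list, pct_list) {
  grid <- seq(0.1, 20, by = 1e-3)
  rss <- vapply(grid, function(rt) {
    s <- 0
    for (g in seq_along(delta_e_list)) {
      w <- exp(-delta_e_list[[g]] / rt)
      s <- s + sum((100 * w / sum(w) - pct_list[[g]])^2)
    }
    s
  }, numeric(1))
  grid[which.min(rss)]
}

# random rigid-body transform of a coordinate matrix
apply_random_rigid <- function(coords) {
  r <- macroconf:::random_rotation()
  shift <- stats::rnorm(3, sd = 5)
  sweep(as.matrix(coords) %*% t(r), 2, shift, "+")
}

expect_mc_error <- function(expr, class) {
  expect_error(expr, class = class)
}
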
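test_that("dihedral angle handles the planar cis and trans references", {
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               0)
  expect_equal(abs(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                  c(2, 1, 0))), 180)
})

test_that("dihedral angle matches the projection oracle on random quadruples", {
  set.seed(11)
  for (i in 1:100) {
    p <- matrix(rnorm(12), 4, 3)
    got <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    want <- oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    d <- abs(got - want) %% 360
    expect_lt(min(d, 360 - d), 1e-9)
  }
})

test_that("dihedral and plane operations are rigid-transform invariant", {
  set.seed(12)
  p <- matrix(rnorm(12), 4, 3)
  base <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
  cloud <- matrix(rnorm(21), 7, 3)
  cloud[, 3] <- cloud[, 3] * 0.05
  base_angle <- interplane_angle(least_squares_plane(cloud)$normal, c(0, 0, 1))
  for (i in 1:100) {
    q <- apply_random_rigid(p)
    expect_lt(abs(dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ]) - base), 1e-8)
    qc <- apply_random_rigid(cloud)
    n1 <- least_squares_plane(cloud)$normal
    n2 <- least_squares_plane(qc)$normal
    # mutual angles to a common in-cloud direction are preserved
    v1 <- cloud[2, ] - cloud[1, ]
    v2 <- qc[2, ] - qc[1, ]
    expect_lt(abs(interplane_angle(n1, v1) - interplane_angle(n2, v2)), 1e-6)
  }
  expect_true(is.finite(base_angle))
})

test_that("dihedral angle rejects collinear triples", {
  expect_mc_error(
    dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
    "macroconf_degenerate_geometry")
})

test_that("least-squares plane recovers exact and noisy planes", {
  pts <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  pl <- least_squares_plane(pts)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_lt(pl$rmsd, 1e-12)

  tri <- matrix(rnorm(9), 3, 3)
  expect_lt(least_squares_plane(tri)$rmsd, 1e-10)

  set.seed(13)
  cloud <- cbind(rnorm(40), rnorm(40), rnorm(40, sd = 0.01))
  got <- least_squares_plane(cloud)$normal
  want <- oracle_plane_normal(cloud)
  expect_lt(1 - abs(sum(got * want)), 1e-6)

  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_mc_error(least_squares_plane(line), "macroconf_degenerate_geometry")
})

test_that("interplane angle folds antiparallel normals and is symmetric", {
  expect_equal(interplane_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(interplane_angle(c(0, 0, 1), c(0, 0, -1)), 0)
  expect_equal(interplane_angle(c(0, 0, 1), c(1, 0, 0)), 90)
  set.seed(14)
  a <- rnorm(3); a <- a / sqrt(sum(a^2))
  b <- rnorm(3); b <- b / sqrt(sum(b^2))
  expect_equal(interplane_angle(a, b), interplane_angle(b, a))
  expect_mc_error(interplane_angle(c(0, 0, 0), c(0, 0, 1)),
                  "macroconf_degenerate_geometry")
})

test_that("torsion distance is a circular pseudometric matching brute force", {
  b <- built_18s()
  quads <- macroconf:::ring_torsion_quads(b$molecule)
  cf <- as.matrix(b$conformer)
  expect_equal(torsion_distance(cf, cf, quads), 0)

  # wrap-around: a torsion rotated by 350 degrees is 10 degrees away
  toy <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.3, 0), c(3.7, 1.3, 0.2))
  toy2 <- toy
  toy2[4, ] <- macroconf:::rotate_about_axis(
    rbind(toy[4, ] - toy[3, ]), toy[3, ] - toy[2, ], 350) + toy[3, ]
  expect_equal(torsion_distance(toy, toy2, list(1:4)), 10,
               tolerance = 1e-6)

  set.seed(15)
  rot <- rotatable_torsions(b$molecule)
  confs <- list(cf)
  for (k in 2:4) {
    x <- cf
    for (rt in rot) x <- macroconf:::apply_torsion_rotation(x, rt,
                                                            runif(1, -180, 180))
    confs[[k]] <- x
  }
  for (i in 1:4) for (j in 1:4) {
    dij <- torsion_distance(confs[[i]], confs[[j]], quads)
    expect_equal(dij, oracle_torsion_distance(confs[[i]], confs[[j]], quads),
                 tolerance = 1e-9)
    expect_equal(dij, torsion_distance(confs[[j]], confs[[i]], quads))
    for (k in 1:4) {
      expect_lte(dij, torsion_distance(confs[[i]], confs[[k]], quads) +
                        torsion_distance(confs[[k]], confs[[j]], quads) + 1e-9)
    }
  }
})
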
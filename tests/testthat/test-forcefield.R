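# minimal two-atom molecule for single-term checks
two_atom <- function(el = c("C", "C"), bond = TRUE, order = "single") {
  bonds <- if (bond) data.frame(i = 1, j = 2, order = order,
                                stringsAsFactors = FALSE)
  else data.frame(i = integer(0), j = integer(0), order = character(0),
                  stringsAsFactors = FALSE)
  macro_molecule("pair", data.frame(element = el, label = paste0(el, 1:2),
                                    ring_index = NA), bonds)
}

test_that("single-term energies match their closed forms", {
  p <- default_params()
  # bond at its equilibrium length: zero stretch
  mol <- two_atom()
  r0 <- p$stretch[["C:C:1"]][["r0"]]
  e <- energy(mol, conformer(rbind(c(0, 0, 0), c(r0, 0, 0))))
  expect_equal(e$stretch, 0, tolerance = 1e-12)
  expect_equal(e$total, sum(e$stretch, e$bend, e$torsion, e$vdw, e$restraint),
               tolerance = 1e-9)

  # two nonbonded atoms at r* sit at the Lennard-Jones minimum -eps
  mol2 <- two_atom(bond = FALSE)
  rstar <- 2 * p$vdw$C[["rstar"]]
  eps <- p$vdw$C[["eps"]]
  e2 <- energy(mol2, conformer(rbind(c(0, 0, 0), c(rstar, 0, 0))))
  expect_equal(e2$vdw, -eps, tolerance = 1e-12)

  # missing parameter raises a typed coverage error naming the class
  mol3 <- two_atom(el = c("X", "X"), bond = FALSE)
  err <- tryCatch(energy(mol3, conformer(matrix(c(0, 0, 0, 3, 0, 0), 2,
                                                byrow = TRUE))),
                  error = function(e) e)
  expect_s3_class(err, "macroconf_param_error")
  expect_match(conditionMessage(err), "X")
})

test_that("analytic gradient matches central finite differences on 18s", {
  b <- built_18s()
  sys <- mm_system(b$molecule)
  cm <- as.matrix(b$conformer)
  g <- energy_gradient(b$molecule, cm, system = sys)$gradient
  h <- 1e-5
  worst <- 0
  for (i in seq_len(nrow(cm))) {
    for (k in 1:3) {
      cp <- cm; cp[i, k] <- cp[i, k] + h
      cn <- cm; cn[i, k] <- cn[i, k] - h
      fd <- (macroconf:::mm_energy_cpp(cp, sys)$total -
             macroconf:::mm_energy_cpp(cn, sys)$total) / (2 * h)
      worst <- max(worst, abs(fd - g[i, k]))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("gradient check passes on random perturbed conformers", {
  b <- built_18s()
  sys <- mm_system(b$molecule)
  set.seed(21)
  for (rep in 1:20) {
    cm <- as.matrix(b$conformer) + matrix(rnorm(length(b$conformer),
                                                sd = 0.05),
                                          nrow(b$conformer), 3)
    g <- macroconf:::mm_gradient_cpp(cm, sys)$gradient
    # spot-check 6 random components per conformer
    for (s in 1:6) {
      i <- sample.int(nrow(cm), 1); k <- sample.int(3, 1)
      h <- 1e-5
      cp <- cm; cp[i, k] <- cp[i, k] + h
      cn <- cm; cn[i, k] <- cn[i, k] - h
      fd <- (macroconf:::mm_energy_cpp(cp, sys)$total -
             macroconf:::mm_energy_cpp(cn, sys)$total) / (2 * h)
      expect_lt(abs(fd - g[i, k]), 1e-3)
    }
  }
})

test_that("energy is invariant under rigid-body transforms", {
  b <- built_18s()
  sys <- mm_system(b$molecule)
  e0 <- macroconf:::mm_energy_cpp(as.matrix(b$conformer), sys)$total
  set.seed(22)
  for (i in 1:20) {
    e1 <- macroconf:::mm_energy_cpp(apply_random_rigid(b$conformer),
                                    sys)$total
    expect_lt(abs(e1 - e0), 1e-8)
  }
})

test_that("minimisation is monotone, stable at a minimum, and honours restraints", {
  b <- built_18s()
  m1 <- minimize(b$molecule, b$conformer)
  expect_true(all(diff(attr(m1, "trace")) <= 1e-9))

  # restarting from the minimum changes nothing appreciable
  m2 <- minimize(b$molecule, m1)
  expect_lt(abs(attr(m2, "energy") - attr(m1, "energy")), 1e-6)
  expect_lt(max(abs(as.matrix(m2) - as.matrix(m1))), 0.05)

  # a stretched closure bond is pulled back by its harmonic restraint
  cm <- as.matrix(b$conformer)
  rot <- rotatable_torsions(b$molecule)
  cm2 <- macroconf:::apply_torsion_rotation(cm, rot[[5]], 80)
  m3 <- minimize(b$molecule, conformer(cm2))
  r <- sqrt(sum((m3[18, ] - m3[1, ])^2))
  expect_lt(abs(r - 1.430), 0.15)
})

test_that("bond-dipole arithmetic reproduces trivial vector sums", {
  p <- default_params()
  mu0 <- p$dipole[["C2:O2:2"]]
  # one carbonyl: magnitude is the parameter itself
  mol <- macro_molecule("co",
    data.frame(element = c("C", "O"), label = c("C1", "O2"),
               ring_index = NA),
    data.frame(i = 1, j = 2, order = "double"))
  expect_equal(as.numeric(dipole_moment(mol, conformer(rbind(c(0, 0, 0),
                                                             c(1.22, 0, 0))))),
               mu0, tolerance = 1e-12)
  # two antiparallel carbonyls cancel
  mol2 <- macro_molecule("2co",
    data.frame(element = c("C", "O", "C", "O"),
               label = c("C1", "O2", "C3", "O4"), ring_index = NA),
    data.frame(i = c(1, 3), j = c(2, 4), order = "double"))
  cf <- rbind(c(0, 0, 0), c(1.22, 0, 0), c(5, 0, 0), c(5 - 1.22, 0, 0))
  expect_equal(as.numeric(dipole_moment(mol2, conformer(cf))), 0,
               tolerance = 1e-12)
})

test_that("face accessibility is symmetric for a planar toy and Fe-blocked when complexed", {
  # planar toy: all atoms inside the slab's dead zone, equal (zero) scores
  mol <- two_atom(bond = FALSE)
  pl <- list(normal = c(0, 0, 1), centroid = c(0, 0, 0))
  sc <- face_accessibility(mol, conformer(rbind(c(1, 0, 0), c(-1, 0, 0))), pl)
  expect_equal(sc[["plus"]], sc[["minus"]])

  # mirror pair of atoms across the plane: equal nonzero scores
  sc2 <- face_accessibility(mol, conformer(rbind(c(0, 0, 2), c(0, 0, -2))),
                            pl)
  expect_gt(sc2[["plus"]], 0)
  expect_equal(sc2[["plus"]], sc2[["minus"]])

  cx <- complexed_18s()
  at <- compute_attributes(cx$molecule, cx$conformer)
  fe <- which(cx$molecule$atoms$element == "Fe")
  d_fe <- sum((cx$conformer[fe, ] - at$diene_plane$centroid) *
                at$diene_plane$normal)
  sc3 <- face_accessibility(cx$molecule, cx$conformer, at$diene_plane)
  fe_side <- if (d_fe > 0) "plus" else "minus"
  other <- setdiff(c("plus", "minus"), fe_side)
  expect_gt(sc3[[fe_side]], sc3[[other]])
})

test_that("face blocking grows monotonically with the pseudo-atom radius", {
  cx <- complexed_18s()
  at <- compute_attributes(cx$molecule, cx$conformer)
  fe <- which(cx$molecule$atoms$element == "Fe")
  d_fe <- sum((cx$conformer[fe, ] - at$diene_plane$centroid) *
                at$diene_plane$normal)
  fe_side <- if (d_fe > 0) "plus" else "minus"
  other <- setdiff(c("plus", "minus"), fe_side)
  diffs <- vapply(seq(2.0, 3.5, by = 0.25), function(r) {
    p <- default_params()
    p$vdw$FE[["rstar"]] <- r
    sc <- face_accessibility(cx$molecule, cx$conformer, at$diene_plane,
                             params = p)
    sc[[fe_side]] - sc[[other]]
  }, numeric(1))
  expect_true(all(diff(diffs) > 0))
})
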
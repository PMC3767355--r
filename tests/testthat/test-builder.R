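test_that("ring recipes validate and carry the printed torsion quadruples", {
  expect_mc_error(macrolactone_spec(6, 6), "macroconf_spec_error")
  expect_mc_error(macrolactone_spec(1, 9), "macroconf_spec_error")

  s <- built_18s()
  expect_equal(sum(!is.na(s$molecule$atoms$ring_index)), 18)
  expect_identical(s$molecule$torsion_labels$phi2, c(10L, 11L, 12L, 13L))
  d <- built_18d()
  expect_identical(d$molecule$torsion_labels$phi2, c(11L, 12L, 13L, 14L))
  for (m in list(s$molecule, d$molecule)) {
    expect_identical(m$torsion_labels$phi1, c(19L, 2L, 3L, 4L))
    # one ester linkage, one conjugated ene, one diene (three ring doubles)
    expect_equal(sum(m$bonds$order == "ester"), 1)
    ring_dbl <- m$bonds$order == "double" &
      !is.na(m$atoms$ring_index[m$bonds$i]) &
      !is.na(m$atoms$ring_index[m$bonds$j])
    expect_equal(sum(ring_dbl), 3)
  }
})

test_that("built molecules satisfy valences and form a single closed ring", {
  for (b in list(built_18s(), built_18d())) {
    mol <- b$molecule
    val <- macroconf:::valence_counts(mol)
    el <- mol$atoms$element
    expect_true(all(val[el == "C"] == 4))
    expect_true(all(val[el == "O"] == 2))
    expect_true(all(val[el == "H"] == 1))
    expect_true(macroconf:::graph_connected(mol))
    # consecutive ring atoms bonded, including the closure
    ring <- macroconf:::ring_atoms(mol)
    key <- paste(pmin(mol$bonds$i, mol$bonds$j),
                 pmax(mol$bonds$i, mol$bonds$j))
    for (k in seq_along(ring)) {
      a <- ring[k]; bng <- ring[k %% 18 + 1]
      expect_true(paste(min(a, bng), max(a, bng)) %in% key)
    }
    # closure bond relaxed to near its equilibrium length
    r <- sqrt(sum((b$conformer[18, ] - b$conformer[1, ])^2))
    expect_lt(abs(r - 1.430), 0.15)
  }
})

test_that("chain symmetry distinguishes the symmetric and dissymmetric isomers", {
  expect_true(is_chain_symmetric(built_18s()$molecule))
  expect_false(is_chain_symmetric(built_18d()$molecule))
  expect_equal(sort(macroconf:::chain_lengths(built_18d()$molecule)),
               c(4, 6))
})

test_that("tricarbonyliron attachment places and restrains the pseudo-atom", {
  b <- built_18s()
  cx <- complexed_18s()
  mol <- cx$molecule
  fe <- which(mol$atoms$element == "Fe")
  expect_length(fe, 1)
  q2 <- mol$torsion_labels$phi2

  # un-relaxed, un-driven placement: Fe sits 1.5-2.0 A from the diene
  # centroid and the two face choices mirror across the diene plane
  geom_only <- complex_model(lock_diene_scis = FALSE)
  raw_p <- attach_tricarbonyliron(b$molecule, b$conformer, face_sign = 1,
                                  model = geom_only, relax = FALSE)
  raw_m <- attach_tricarbonyliron(b$molecule, b$conformer, face_sign = -1,
                                  model = geom_only, relax = FALSE)
  pl <- least_squares_plane(as.matrix(b$conformer)[q2, ])
  dp <- sum((raw_p$conformer[fe, ] - pl$centroid) * pl$normal)
  dm <- sum((raw_m$conformer[fe, ] - pl$centroid) * pl$normal)
  expect_lt(abs(dp + dm), 1e-8)          # mirror images
  expect_gte(abs(dp), 1.5)
  expect_lte(abs(dp), 2.0)

  # relaxed complexed conformer keeps the diene near s-cis
  cf <- cx$conformer
  phi2 <- dihedral_angle(cf[q2[1], ], cf[q2[2], ], cf[q2[3], ], cf[q2[4], ])
  expect_lt(abs(phi2), 20)

  expect_mc_error(
    attach_tricarbonyliron(macro_molecule("x",
      data.frame(element = "C", label = "C1", ring_index = NA),
      data.frame(i = integer(0), j = integer(0), order = character(0))),
      conformer(matrix(0, 1, 3))),
    "macroconf_builder_error")
})

test_that("planted conformers cover requested geometric classes", {
  b <- built_18s()
  cf_par <- make_planted_conformer(2, spec_by_name("18s"), seed = 0,
                                   built = b)
  at <- compute_attributes(b$molecule, cf_par)
  expect_identical(at$arrangement, "pseudoparallel")
  expect_lt(at$plane_angle, 45)

  cf_st <- make_planted_conformer(7, spec_by_name("18s"), seed = 0,
                                  built = b)
  at2 <- compute_attributes(b$molecule, cf_st)
  expect_gte(abs(at2$phi2), 90)
  expect_mc_error(make_planted_conformer(9, spec_by_name("18s")),
                  "macroconf_fixture_error")
})
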
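test_that("the Metropolis rule matches the analytic Boltzmann factor", {
  expect_true(metropolis_accept(-1, 1000, 0.999999))
  expect_true(metropolis_accept(0, 1000, 0.999999))   # boundary convention
  expect_mc_error(metropolis_accept(NaN, 1000, 0.5), "macroconf_search_error")

  rt <- 1.987e-3 * 1000
  de <- rt * log(2)
  set.seed(41)
  acc <- mean(vapply(runif(10000), function(u) metropolis_accept(de, 1000, u),
                     logical(1)))
  expect_lt(abs(acc - 0.5), 0.02)
  # direct factor check at a few energies
  for (x in c(0.5, 1, 2, 5)) {
    expect_true(metropolis_accept(x, 1000, exp(-x / rt) - 1e-12))
    expect_false(metropolis_accept(x, 1000, exp(-x / rt) + 1e-12))
  }
})

test_that("move proposals pick torsions uniformly and honour the step bound", {
  b <- built_18s()
  rot <- rotatable_torsions(b$molecule)
  cfg <- search_config()
  set.seed(42)
  picks <- integer(10000)
  for (i in seq_along(picks)) {
    picks[i] <- attr(propose_move(b$conformer, b$molecule, cfg, rot),
                     "torsion_index")
  }
  tab <- tabulate(picks, length(rot))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)

  # zero step size: identity proposals
  cfg0 <- search_config(max_torsion_step = 0)
  prop <- propose_move(b$conformer, b$molecule, cfg0, rot)
  expect_lt(max(abs(as.matrix(prop) - as.matrix(b$conformer))), 1e-12)
})

test_that("frozen complexed-diene torsions are excluded from the move set", {
  cx <- complexed_18s()
  rot_free <- rotatable_torsions(built_18s()$molecule)
  rot_cx <- rotatable_torsions(cx$molecule)
  q2 <- cx$molecule$torsion_labels$phi2
  central <- sort(q2[2:3])
  expect_true(any(vapply(rot_free, function(rt) all(sort(rt$axis) == central),
                         logical(1))))
  expect_false(any(vapply(rot_cx, function(rt) all(sort(rt$axis) == central),
                          logical(1))))
  # double bonds never rotate, for either molecule
  dbl <- cx$molecule$bonds[cx$molecule$bonds$order == "double", ]
  for (r in seq_len(nrow(dbl))) {
    key <- sort(c(dbl$i[r], dbl$j[r]))
    expect_false(any(vapply(rot_cx, function(rt) all(sort(rt$axis) == key),
                            logical(1))))
  }
})

test_that("searches are deterministic given the seed and obey ensemble invariants", {
  b <- built_18s()
  cfg <- search_config(n_steps = 480, quench_every = 20, seed = 7)
  e1 <- run_search(b$molecule, config = cfg, init = b$conformer)
  e2 <- run_search(b$molecule, config = cfg, init = b$conformer)
  expect_equal(e1$energies, e2$energies, tolerance = 1e-12)
  expect_identical(length(e1$conformers), length(e2$conformers))
  expect_lt(max(abs(as.matrix(e1$conformers[[1]]) -
                    as.matrix(e2$conformers[[1]]))), 1e-12)

  # sorted energies, dedup distance respected, window respected
  expect_true(!is.unsorted(e1$energies))
  expect_true(all(e1$energies <= e1$global_min_energy +
                    cfg$energy_window + 1e-9))
  quads <- macroconf:::ring_torsion_quads(b$molecule)
  n <- length(e1$conformers)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        expect_gte(torsion_distance(e1$conformers[[i]], e1$conformers[[j]],
                                    quads), cfg$dedup_threshold)
      }
    }
  }
  # closure restraint satisfied for every recorded conformer
  for (cf in e1$conformers) {
    expect_lt(abs(sqrt(sum((cf[18, ] - cf[1, ])^2)) - 1.430), 0.15)
  }
})

test_that("a search that never quenches raises a search failure", {
  b <- built_18s()
  cfg <- search_config(n_steps = 10, quench_every = 25, seed = 1)
  expect_mc_error(run_search(b$molecule, config = cfg, init = b$conformer),
                  "macroconf_search_error")
})

test_that("the diene lock keeps every recorded complexed conformer near s-cis", {
  cx <- complexed_18s()
  cfg <- search_config(n_steps = 800, quench_every = 20, seed = 3)
  ens <- run_search(cx$molecule, config = cfg, init = cx$conformer)
  q2 <- cx$molecule$torsion_labels$phi2
  for (cf in ens$conformers) {
    phi2 <- dihedral_angle(cf[q2[1], ], cf[q2[2], ], cf[q2[3], ],
                           cf[q2[4], ])
    expect_lt(abs(phi2), 20)
  }
})
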
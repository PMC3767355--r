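test_that("Boltzmann populations match analytic cases and invariants", {
  expect_equal(boltzmann_populations(c(0, 0, 0), 1), rep(100 / 3, 3))
  rt <- 0.7
  expect_equal(boltzmann_populations(c(0, rt * log(2)), rt),
               c(200 / 3, 100 / 3), tolerance = 1e-12)
  expect_mc_error(boltzmann_populations(numeric(0), 1),
                  "macroconf_stats_error")

  set.seed(51)
  for (i in 1:20) {
    de <- sort(runif(6, 0, 5)); de <- de - min(de)
    p <- boltzmann_populations(de, runif(1, 0.2, 8))
    expect_equal(sum(p), 100, tolerance = 1e-9)
    expect_true(all(diff(p) <= 1e-12))   # monotone: lower dE, higher pop
  }
  # temperature limits
  de <- c(0, 1, 2)
  expect_equal(boltzmann_populations(de, 1e6), rep(100 / 3, 3),
               tolerance = 1e-4)
  expect_equal(boltzmann_populations(de, 1e-6), c(100, 0, 0),
               tolerance = 1e-9)
})

test_that("RT calibration round-trips noise-free synthetic populations", {
  de <- c(0, 0.5, 1.0)
  for (rt in c(0.3, 0.6, 1, 2, 4, 8)) {
    cal <- calibrate_rt(de, boltzmann_populations(de, rt))
    expect_lt(abs(cal$rt_eff - rt) / rt, 1e-6)
  }
  # the worked round trip at RT = 0.593
  cal <- calibrate_rt(de, boltzmann_populations(de, 0.593))
  expect_lt(abs(cal$rt_eff - 0.593), 1e-6)
  # single pair: closed form RT = dE / log(p0/p1)
  de2 <- c(0, 1.3)
  p2 <- c(70, 30)
  cal2 <- calibrate_rt(de2, p2)
  expect_equal(cal2$rt_eff, 1.3 / log(70 / 30), tolerance = 1e-6)
  expect_mc_error(calibrate_rt(c(1, 1), c(50, 50)), "macroconf_stats_error")
})

test_that("grouped calibration on the printed tables matches the grid oracle", {
  tt <- printed_type_tables()
  des <- lapply(c("18s", "18d"), function(d) tt$delta_e[tt$dataset == d])
  pcs <- lapply(c("18s", "18d"), function(d) tt$pct[tt$dataset == d])
  cal <- calibrate_rt(des, pcs)
  expect_equal(cal$n_points, 16)
  oracle <- oracle_grid_rt(des, pcs)
  expect_lt(abs(cal$rt_eff - oracle), 2e-3)
  expect_gt(cal$rt_eff, 4.0)
  expect_lt(cal$rt_eff, 4.25)
})

test_that("the reproduced tables hit every printed percentage closely", {
  rep <- reproduce_tables()
  expect_equal(nrow(rep$tables), 24)
  expect_lte(rep$max_abs_error, 0.2)
  for (d in unique(rep$tables$dataset)) {
    expect_equal(sum(rep$tables$model_pct[rep$tables$dataset == d]), 100,
                 tolerance = 1e-9)
  }
  # the complexed dissymmetric column is a prediction at the uncomplexed
  # calibration, rounding to the printed precision
  d18c <- rep$tables[rep$tables$dataset == "18d-complexed", ]
  d18c <- d18c[order(d18c$delta_e), ]
  expect_equal(round(d18c$model_pct, 1), c(50.1, 18.8, 17.6, 13.5))
  # rigidification: complexed top population exceeds the uncomplexed one
  top <- function(d) max(rep$tables$model_pct[rep$tables$dataset == d])
  expect_gt(top("18d-complexed"), top("18d"))
  expect_gt(top("18s-complexed"), top("18s"))
})

test_that("evenness ranks the printed tables by flexibility", {
  uniform <- data.frame(delta_e = c(0, 0, 0, 0), pct = rep(25, 4))
  single <- data.frame(delta_e = 0, pct = 100)
  cmp <- compare_flexibility(uniform, single)
  expect_equal(cmp$evenness, c(1, 0))

  tt <- printed_type_tables()
  tab <- function(d) tt[tt$dataset == d, ]
  cmp2 <- compare_flexibility(tab("18s"), tab("18d-complexed"))
  expect_gt(cmp2$evenness[1], cmp2$evenness[2])
  # dissymmetric mobility slightly below symmetric
  cmp3 <- compare_flexibility(tab("18s"), tab("18d"))
  expect_gt(cmp3$evenness[1], cmp3$evenness[2])
})

test_that("population tables from a search ensemble satisfy table invariants", {
  b <- built_18s()
  ens <- run_search(b$molecule,
                    config = search_config(n_steps = 480, quench_every = 20,
                                           seed = 7),
                    init = b$conformer)
  pop <- population_table(ens, rt = 4.1)
  expect_equal(sum(pop$pct), 100, tolerance = 1e-9)
  expect_equal(min(pop$delta_e), 0)
  expect_true(all(diff(pop$pct) <= 1e-12))
  pop2 <- population_table(ens, rt = 4.1, mode = "sum")
  expect_equal(sum(pop2$pct), 100, tolerance = 1e-9)
})
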
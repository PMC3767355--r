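#' Boltzmann populations from relative energies
#'
#' Converts per-type energy differences to the global minimum into
#' percentage populations, `p_i = 100 exp(-dE_i/RT) / sum_j
#' exp(-dE_j/RT)`. Energies are shifted so the minimum is zero before
#' exponentiation (numerical safety; the populations are shift
#' invariant).
#'
#' @param delta_e Energies relative to the global minimum, kcal/mol.
#' @param rt Effective thermal energy RT, kcal/mol.
#' @return Percentages summing to 100.
#' @export
boltzmann_populations <- function(delta_e, rt) {
  if (!length(delta_e)) {
    mc_stop("empty energy list", "macroconf_stats_error")
  }
  stopifnot(rt > 0, all(is.finite(delta_e)))
  w <- exp(-(delta_e - min(delta_e)) / rt)
  100 * w / sum(w)
}

#' Calibrate the effective Boltzmann temperature
#'
#' Recovers the RT (kcal/mol) that best reproduces observed percentage
#' populations from their relative energies, by 1-D bounded
#' least-squares over RT in \[0.1, 20\]. Several datasets may be fitted
#' jointly (each is normalised separately; residuals are pooled), which
#' is how a single effective temperature is calibrated on both columns
#' of the uncomplexed-macrocycle table at once.
#'
#' @param delta_e Numeric vector, or list of numeric vectors (one per
#'   dataset), kcal/mol.
#' @param observed_pct Observed percentages, same shape as `delta_e`.
#' @return An object of class `rt_calibration`: `rt_eff` (kcal/mol),
#'   `rss` (squared-percentage-point residual) and `n_points`.
#' @export
calibrate_rt <- function(delta_e, observed_pct) {
  if (!is.list(delta_e)) {
    delta_e <- list(delta_e)
    observed_pct <- list(observed_pct)
  }
  stopifnot(length(delta_e) == length(observed_pct))
  npts <- sum(lengths(delta_e))
  if (npts < 2) {
    mc_stop("need at least 2 (delta_e, pct) points", "macroconf_stats_error")
  }
  if (all(vapply(delta_e, function(d) diff(range(d)) < 1e-12, logical(1)))) {
    mc_stop("RT is unidentifiable: all energy differences are equal",
            "macroconf_stats_error")
  }
  rss <- function(rt) {
    sum(vapply(seq_along(delta_e), function(g) {
      sum((boltzmann_populations(delta_e[[g]], rt) - observed_pct[[g]])^2)
    }, numeric(1)))
  }
  opt <- optimize(rss, c(0.1, 20), tol = 1e-10)
  structure(list(rt_eff = opt$minimum, rss = opt$objective,
                 n_points = npts),
            class = "rt_calibration")
}

#' @export
print.rt_calibration <- function(x, ...) {
  cat(sprintf("<rt_calibration> RT_eff = %.4f kcal/mol (rss = %.4g, n = %d)\n",
              x$rt_eff, x$rss, x$n_points))
  invisible(x)
}

#' Printed per-type energy/population tables
#'
#' The packaged fixture: per-type energy differences to the global
#' minimum (kcal/mol) and Boltzmann populations (%) for the four
#' datasets 18s, 18d, 18s-complexed and 18d-complexed, as printed in
#' published reference tables for this macrolactone family.
#'
#' @return Data frame with columns `dataset`, `type`, `delta_e`, `pct`.
#' @export
printed_type_tables <- function() {
  path <- system.file("extdata", "printed_type_tables.tsv",
                      package = "macroconf")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Reproduce the printed population tables
#'
#' Calibrates one global effective RT on the sixteen (delta_e, pct)
#' pairs of the two uncomplexed datasets, then computes model
#' populations for all four datasets from their printed delta_e values
#' (the complexed columns are predictions, not refits) and reports the
#' per-cell absolute error against the printed percentages.
#'
#' @return List with `rt` (the calibration), `tables` (data frame with
#'   model percentages and per-cell errors) and `max_abs_error`
#'   (percentage points).
#' @export
reproduce_tables <- function() {
  tt <- printed_type_tables()
  uncx <- c("18s", "18d")
  cal <- calibrate_rt(
    lapply(uncx, function(d) tt$delta_e[tt$dataset == d]),
    lapply(uncx, function(d) tt$pct[tt$dataset == d]))
  out <- do.call(rbind, lapply(split(tt, tt$dataset), function(g) {
    g$model_pct <- boltzmann_populations(g$delta_e, cal$rt_eff)
    g$abs_error <- abs(g$model_pct - g$pct)
    g
  }))
  rownames(out) <- NULL
  list(rt = cal, tables = out, max_abs_error = max(out$abs_error))
}

#' Flexibility comparison of two type tables
#'
#' Reports, for each table: the number of types within 1 kcal/mol of
#' the global minimum, the top (largest) population, and an evenness
#' index - the Shannon entropy of the population distribution
#' normalised by log(number of types), 1 for a uniform spread, 0 for a
#' single populated type (convention). Rigidification shows up as a
#' higher top population and lower evenness.
#'
#' @param table_a,table_b Data frames with columns `delta_e` and `pct`.
#' @return Data frame with one row per table.
#' @export
compare_flexibility <- function(table_a, table_b) {
  one <- function(tb, name) {
    p <- tb$pct / sum(tb$pct)
    evenness <- if (length(p) == 1) 0 else {
      -sum(ifelse(p > 0, p * log(p), 0)) / log(length(p))
    }
    data.frame(table = name, n_types = nrow(tb),
               n_within_1kcal = sum(tb$delta_e <= 1),
               top_pct = max(tb$pct), evenness = evenness)
  }
  rbind(one(table_a, "A"), one(table_b, "B"))
}

#' Population table from a search ensemble
#'
#' Convenience wrapper: classifies the ensemble ([type_census()]) and
#' attaches Boltzmann populations at the given RT (the per-type
#' delta_e are the per-type minimum energies relative to the global
#' minimum; a conformer-sum mode weighting every ensemble member is
#' available as `mode = "sum"`).
#'
#' @param ensemble A `conformer_ensemble`.
#' @param rt Effective RT, kcal/mol; `"auto"` calibrates on the
#'   packaged printed tables.
#' @param mode `"min"` (one delta_e per type, the printed-table
#'   structure) or `"sum"` (partition sum over all conformers of each
#'   type).
#' @return The census data frame with a `pct` column.
#' @export
population_table <- function(ensemble, rt = "auto", mode = c("min", "sum")) {
  mode <- match.arg(mode)
  if (identical(rt, "auto")) {
    rt <- reproduce_tables()$rt$rt_eff
  }
  cen <- type_census(ensemble)
  if (mode == "min") {
    cen$pct <- boltzmann_populations(cen$delta_e, rt)
  } else {
    mol <- ensemble$molecule
    types <- vapply(ensemble$conformers, function(cf) {
      assign_type(compute_attributes(mol, cf))$label
    }, integer(1))
    e <- ensemble$energies - min(ensemble$energies)
    w <- exp(-e / rt)
    agg <- tapply(w, types, sum)
    cen$pct <- 100 * as.numeric(agg[as.character(cen$type)]) / sum(w)
  }
  cen
}
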
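#' End-to-end pipeline configuration
#'
#' One flat configuration for the whole build-search-classify-analyze
#' chain. Round-trips losslessly through a YAML file
#' ([read_pipeline_config()] / [write_pipeline_config()]).
#'
#' @param molecule "18s" or "18d".
#' @param complexed Attach the tricarbonyliron steric model.
#' @param face +1 or -1 diene face for the complex.
#' @param n_steps,temperature_K,max_torsion_step,quench_every
#'   Search settings, see [search_config()].
#' @param energy_window,dedup_threshold More search settings.
#' @param rt `"auto"` (calibrate on the packaged printed tables) or a
#'   numeric RT in kcal/mol.
#' @param outdir Output directory.
#' @param seed Integer seed used for the build jitter and the search.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(molecule = "18s", complexed = FALSE, face = 1,
                            n_steps = 20000, temperature_K = 1000,
                            max_torsion_step = 60, quench_every = 25,
                            energy_window = 6.0, dedup_threshold = 30,
                            rt = "auto", outdir = tempfile("macroconf-run-"),
                            seed = 0) {
  structure(list(molecule = molecule, complexed = isTRUE(complexed),
                 face = sign(face), n_steps = as.integer(n_steps),
                 temperature_K = temperature_K,
                 max_torsion_step = max_torsion_step,
                 quench_every = as.integer(quench_every),
                 energy_window = energy_window,
                 dedup_threshold = dedup_threshold, rt = rt,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Config file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(pipeline_config, v)
}

#' Run the full conformational-analysis pipeline
#'
#' Build the requested macrolactone (optionally complexed), run the
#' Monte-Carlo search, classify the ensemble, compute Boltzmann
#' populations, and write all artifacts to the output directory:
#' `built.sdf`, `ensemble.sdf`, `ensemble_energies.json`,
#' `census.tsv`, `populations.tsv` and `run_log.txt` (resolved
#' configuration, seed and config hash). Outputs are deterministic for
#' a given configuration.
#'
#' @param config A [pipeline_config()].
#' @param params Force-field parameters.
#' @return Invisibly, a list with the ensemble, the census, the
#'   population table and the output directory.
#' @export
run_pipeline <- function(config, params = default_params()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  built <- stage("build", {
    b <- build_macrolactone(spec_by_name(config$molecule,
                                         config$complexed),
                            seed = config$seed, params = params)
    if (config$complexed) {
      b2 <- attach_tricarbonyliron(b$molecule, b$conformer,
                                   face_sign = config$face, params = params)
      b <- list(molecule = b2$molecule, conformer = b2$conformer)
    }
    b
  })
  write_structure(built$molecule, built$conformer,
                  file.path(config$outdir, "built.sdf"))

  ens <- stage("search", {
    sc <- search_config(temperature_K = config$temperature_K,
                        n_steps = config$n_steps,
                        max_torsion_step = config$max_torsion_step,
                        quench_every = config$quench_every,
                        energy_window = config$energy_window,
                        dedup_threshold = config$dedup_threshold,
                        seed = config$seed)
    run_search(built$molecule, params, sc, init = built$conformer)
  })
  write_structure(ens$molecule, ens$conformers,
                  file.path(config$outdir, "ensemble.sdf"))
  jsonlite::write_json(
    list(energies = round(ens$energies, 6),
         global_min_energy = round(ens$global_min_energy, 6),
         n_recorded = ens$n_recorded, n_accepted = ens$n_accepted,
         config = unclass(config)[setdiff(names(config), "outdir")]),
    file.path(config$outdir, "ensemble_energies.json"),
    auto_unbox = TRUE, digits = NA)

  cen <- stage("classify", type_census(ens))
  write_tsv_fixed(cen, file.path(config$outdir, "census.tsv"))

  pop <- stage("analyze", population_table(ens, rt = config$rt))
  write_tsv_fixed(pop, file.path(config$outdir, "populations.tsv"))

  cfg_path <- file.path(config$outdir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  log_lines <- c(
    sprintf("macroconf run, seed = %d", config$seed),
    sprintf("molecule = %s, complexed = %s, face = %+d", config$molecule,
            config$complexed, config$face),
    sprintf("search: %d steps at %g K, window %g kcal/mol",
            config$n_steps, config$temperature_K, config$energy_window),
    sprintf("conformers kept = %d, global minimum = %.6f kcal/mol",
            length(ens$conformers), ens$global_min_energy),
    sprintf("config md5 = %s", unname(tools::md5sum(cfg_path))))
  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))

  invisible(list(molecule = built$molecule, ensemble = ens, census = cen,
                 populations = pop, outdir = config$outdir))
}

# deterministic TSV writer with fixed column order and number format
write_tsv_fixed <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (k in which(num)) out[[k]] <- sprintf("%.6g", df[[k]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
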
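#' Default end-to-end run configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]: simulate a
#' library, call its mutations, tabulate the per-cycle rate, generate a
#' screening plate with implanted sensitizer clones and two control
#' populations, and call hits. All stochastic stages derive their seeds from
#' the single top-level `seed`.
#'
#' @param seed Mandatory integer seed.
#' @param outdir Output directory.
#' @param reference_length Length of the synthetic reference CDS (nt,
#'   multiple of 3).
#' @param mutation_rate Per-nt per-cycle substitution rate.
#' @param generations Reverse-transcription cycles.
#' @param population_size Genomes per generation.
#' @param n_screen_clones Clones taken forward into the screen.
#' @param n_sensitizers Implanted sensitizer clones.
#' @param concentrations Plate concentration grid (nM, must include 0).
#' @param n_experiments Replicate screening experiments.
#' @param screening_conc Concentration at which hits are called (nM).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed,
                       outdir,
                       reference_length = 783L,
                       mutation_rate = 1.14e-4,
                       generations = 17L,
                       population_size = 500L,
                       n_screen_clones = 76L,
                       n_sensitizers = 6L,
                       concentrations = c(0, 10, 35, 70),
                       n_experiments = 3L,
                       screening_conc = 10) {
  if (missing(seed)) stop("run_config() requires an explicit seed", call. = FALSE)
  if (missing(outdir)) stop("run_config() requires an output directory", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must lie in [0, 1]", call. = FALSE)
  }
  if (n_sensitizers > n_screen_clones) {
    stop("more sensitizers than screened clones", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed), outdir = outdir,
      reference_length = as.integer(reference_length),
      mutation_rate = mutation_rate,
      generations = as.integer(generations),
      population_size = as.integer(population_size),
      n_screen_clones = as.integer(n_screen_clones),
      n_sensitizers = as.integer(n_sensitizers),
      concentrations = concentrations,
      n_experiments = as.integer(n_experiments),
      screening_conc = screening_conc
    ),
    class = "run_config"
  )
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the whole pipeline: simulate, call, estimate, screen
#'
#' Desk-scale analogue of the full experimental loop: (1) simulate a
#' library of clones through the configured number of copying cycles,
#' (2) call mutations against the reference and summarize the spectrum,
#' (3) tabulate the per-cycle mutation rate, (4) generate a screening
#' viability plate in which a known subset of clones is a sensitizer, and
#' (5) call hits against the two control populations. Every artifact is
#' written to `outdir` and described in `manifest.json` (inputs, seed,
#' package version, output checksums); the same configuration and seed
#' reproduce the manifest bit-identically.
#'
#' @param config A [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @return Invisibly, a list with the in-memory artifacts (`library`,
#'   `mutations`, `rates`, `plate`, `screen`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$outdir, f)
  stage <- function(name, expr) {
    message("[retrosim] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline failed at stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  reference <- stage("reference", {
    ref <- random_reference(config$reference_length, seed = config$seed + 1L)
    write_fasta(setNames(ref$sequence, ref$name), path("reference.fasta"))
    ref
  })

  lib <- stage("simulate", {
    cfg <- evolution_config(
      mutation_rate = config$mutation_rate,
      generations = config$generations,
      population_size = config$population_size,
      seed = config$seed + 2L
    )
    lib <- simulate_library(cfg, reference)
    write_fasta(lib$sequences, path("clones.fasta"))
    lib
  })

  mutations <- stage("callmut", {
    mut <- call_mutations_all(lib$sequences, reference)
    log_cycles <- lib$mutations[, c("clone_id", "position", "cycle_introduced")]
    mut <- merge(mut, log_cycles, by = c("clone_id", "position"), all.x = TRUE,
                 sort = FALSE)
    mut <- mut[order(mut$clone_id, mut$position), ]
    write_mutations_tsv(mut, path("mutations.tsv"))
    mut
  })

  rates <- stage("rate", {
    tab <- rate_table(lib$clones, mutations, reference$length)
    write_results_tsv(tab, path("rates.tsv"))
    tab
  })

  screen <- stage("screen", {
    clone_ids <- head(lib$clones$clone_id, config$n_screen_clones)
    sens <- withr::with_seed(config$seed + 3L,
                             sample(clone_ids, config$n_sensitizers))
    controls <- c("untransduced", "wt_dCK")
    params <- plate_params(
      sensitizer_ids = sens,
      clone_ic50_nM = c(untransduced = 14, wt_dCK = 12)
    )
    plate <- generate_viability_plate(
      c(clone_ids, controls), config$concentrations, params,
      n_experiments = config$n_experiments, seed = config$seed + 4L
    )
    write_plate_tsv(plate, path("plate.tsv"))
    res <- call_hits(plate, clone_ids, controls, config$screening_conc)
    write_results_tsv(as.data.frame(res), path("screen_results.tsv"))
    list(plate = plate, result = res, implanted = sort(sens))
  })

  manifest <- stage("manifest", {
    files <- c("reference.fasta", "clones.fasta", "mutations.tsv",
               "rates.tsv", "plate.tsv", "screen_results.tsv")
    man <- list(
      package = "retrosim",
      version = as.character(utils::packageVersion("retrosim")),
      seed = config$seed,
      config = unclass(config),
      implanted_sensitizers = screen$implanted,
      checksums = as.list(tools::md5sum(vapply(files, path, character(1L))))
    )
    names(man$checksums) <- files
    jsonlite::write_json(man, path("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    man
  })

  invisible(list(
    library = lib, mutations = mutations, rates = rates,
    plate = screen$plate, screen = screen$result, manifest = manifest
  ))
}
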
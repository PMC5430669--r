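# Pipeline orchestration: a declarative run configuration and the three
# stages (simulate, fit, diversity) as functions over it.  A thin
# command-line wrapper lives in inst/scripts/demog_pipeline.R.

#' Run configuration
#'
#' Collects paths, calibration inputs, rejection settings, grid
#' overrides and diversity options for a pipeline run.  Defaults mirror
#' the study settings (epsilon = 25%, 40,000 simulations per grid point,
#' the study grid, 5,000 bootstraps).
#'
#' @param loci_dir Directory of per-locus FASTA files.
#' @param population_map Path to the population map; defaults to
#'   `population_map.tsv` inside `loci_dir`.
#' @param out_dir Output directory.
#' @param mu Fixed per-generation mutation rate, or `NULL` to calibrate
#'   from the mean synonymous divergence to the outgroup.
#' @param divergence_time_years,generation_time_years Calibration inputs.
#' @param epsilon_pct,n_sims,acceptance_mode Rejection settings (see
#'   [rejection_config()]).
#' @param models Models to fit.
#' @param grid Named list of axis overrides for [grid_spec()] (elements
#'   `T_gen`, `theta`, `m`, `tau`).
#' @param n_boot Bootstrap replicates for diversity summaries.
#' @param n_perms Permutations for the FST test.
#' @param rarefaction_g Rarefaction depth, `NULL` for the smallest
#'   sampled-allele count.
#' @param design A [study_design()] for `cmd_simulate()`.
#' @param rng_seed Master seed, recorded in every output artifact.
#' @return An object of class `run_config`.
#' @export
run_config <- function(loci_dir = NULL,
                       population_map = if (!is.null(loci_dir))
                         file.path(loci_dir, "population_map.tsv") else NULL,
                       out_dir = "gilliflow_out",
                       mu = NULL,
                       divergence_time_years = 65e6,
                       generation_time_years = 1,
                       epsilon_pct = 25, n_sims = 40000,
                       acceptance_mode = "per_component",
                       models = MODEL_KINDS,
                       grid = list(),
                       n_boot = 5000, n_perms = 10000,
                       rarefaction_g = NULL,
                       design = study_design(),
                       rng_seed = 1) {
  bad_axes <- setdiff(names(grid), c("T_gen", "theta", "m", "tau"))
  if (length(bad_axes) > 0) {
    stop("unknown grid axis override(s): ", paste(bad_axes, collapse = ", "))
  }
  if (any(lengths(grid) == 0)) stop("empty grid axis override")
  models <- match.arg(models, MODEL_KINDS, several.ok = TRUE)
  structure(list(loci_dir = loci_dir, population_map = population_map,
                 out_dir = out_dir, mu = mu,
                 divergence_time_years = divergence_time_years,
                 generation_time_years = generation_time_years,
                 epsilon_pct = epsilon_pct, n_sims = n_sims,
                 acceptance_mode = acceptance_mode,
                 models = models, grid = grid,
                 n_boot = n_boot, n_perms = n_perms,
                 rarefaction_g = rarefaction_g,
                 design = design, rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Scalar fields map directly onto [run_config()] arguments; `grid` and
#' `design` are nested sections (design parameters `model`, `theta`,
#' `T_gen`, `m`, `tau` populate the true [model_params()]).
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- study_design()
  if (!is.null(y$design)) {
    d <- y$design
    pars <- d[names(d) %in% c("model", "theta", "T_gen", "m", "tau")]
    params <- if (length(pars) > 0) do.call(model_params, pars)
      else study_design()$params
    design <- do.call(study_design, c(
      d[names(d) %in% c("n_loci", "length_range", "n_west", "n_east",
                        "scalar_sdlog", "rng_seed")],
      list(params = params)))
  }
  args <- y[names(y) %in% setdiff(names(formals(run_config)), "design")]
  do.call(run_config, c(args, list(design = design)))
}

ensure_out_dir <- function(config) {
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
    message("created output directory ", config$out_dir)
  }
  config$out_dir
}

write_log <- function(config, stage, extra = character()) {
  path <- file.path(config$out_dir, paste0(stage, "_log.txt"))
  lines <- c(paste0("stage: ", stage),
             paste0("rng_seed: ", config$rng_seed),
             paste0("R: ", R.version.string),
             paste0("gilliflow: ",
                    as.character(utils::packageVersion("gilliflow"))),
             paste0("time: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             extra)
  writeLines(lines, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline stage: generate a synthetic dataset
#'
#' Wraps [generate_dataset()]; writes the dataset under
#' `out_dir/dataset` and prints a truth summary.
#'
#' @param config A [run_config()].
#' @return Invisibly, the [generate_dataset()] result.
#' @export
cmd_simulate <- function(config) {
  ensure_out_dir(config)
  design <- config$design
  design$rng_seed <- config$rng_seed
  dir <- file.path(config$out_dir, "dataset")
  ds <- generate_dataset(design, dir)
  message("simulated ", design$n_loci, " loci under ", design$params$model,
          " (theta = ", design$params$theta, ", T = ", design$params$T_gen,
          ", m = ", design$params$m, ", tau = ", design$params$tau, ")")
  wh <- ds$truth$wh_total
  message("true Wakeley-Hey sums: private_west = ", wh$private_west,
          ", private_east = ", wh$private_east,
          ", shared = ", wh$shared, ", fixed = ", wh$fixed)
  write_log(config, "simulate", paste0("dataset_dir: ", dir))
  invisible(ds)
}

# frame inference, trimming, synonymous-site counts, scalars and mu for
# a list of alignments read from disk
prepare_loci <- function(alns, config) {
  alns <- lapply(alns, function(a) trim_to_frame(set_reading_frame(a)))
  n_syn <- vapply(alns, count_synonymous_sites, 1L)
  div <- vapply(alns, synonymous_divergence, 1.0)
  names(div) <- vapply(alns, function(a) a$locus_name, "")
  scal <- locus_scalars(div)
  mu <- if (is.null(config$mu)) {
    calibrate_mu(mean(div), config$divergence_time_years,
                 config$generation_time_years)
  } else {
    mutation_rate(config$mu, config$divergence_time_years,
                  config$generation_time_years)
  }
  specs <- locus_spec(
    locus_name = scal$locus_name,
    length = n_syn,
    scalar = scal$scalar,
    n_west = vapply(alns, function(a) sum(a$alleles$population == "west"), 1L),
    n_east = vapply(alns, function(a) sum(a$alleles$population == "east"), 1L)
  )
  list(alns = alns, specs = specs, scalars = scal, mu = mu)
}

#' Pipeline stage: fit the demographic models
#'
#' Reads the dataset, infers frames, computes the observed Wakeley-Hey
#' sums at synonymous sites, runs the rejection-sampling grid search for
#' each requested model, compares nested models, and writes tidy tables
#' (per-model surfaces, MLE table, profile-CI table, comparison table)
#' plus a run log.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `obs`, `surfaces`, `mle`, `ci`,
#'   `comparison`.
#' @export
cmd_fit <- function(config) {
  if (is.null(config$loci_dir)) stop("config$loci_dir is required for fit")
  ensure_out_dir(config)
  ds <- read_dataset(config$loci_dir)
  prep <- prepare_loci(ds$alns, config)
  obs <- wakeley_hey(prep$alns)
  if (sum(unlist(obs)) == 0) {
    stop("no polarizable synonymous variable sites in the dataset; ",
         "cannot fit demographic models")
  }
  cfg <- rejection_config(epsilon_pct = config$epsilon_pct,
                          n_sims = config$n_sims,
                          acceptance_mode = config$acceptance_mode,
                          rng_seed = config$rng_seed)
  surfaces <- lapply(setNames(config$models, config$models), function(model) {
    grid <- do.call(grid_spec, c(list(model = model), config$grid))
    surf <- grid_search(obs, model, grid, prep$specs, prep$mu, cfg)
    write_surface(surf, file.path(config$out_dir,
                                  paste0("surface_", model, ".tsv")))
    surf
  })
  mle <- dplyr::bind_rows(lapply(surfaces, glance))
  write_tsv(mle, file.path(config$out_dir, "mle_table.tsv"))
  free_axes <- list(isolation = c("theta", "T_gen"),
                    ongoing_migration = c("theta", "T_gen", "m"),
                    secondary_contact = c("theta", "T_gen", "m", "tau"))
  ci <- dplyr::bind_rows(lapply(names(surfaces), function(model) {
    dplyr::bind_rows(lapply(free_axes[[model]], function(ax) {
      dplyr::mutate(profile_ci(surfaces[[model]], ax), model = model,
                    .before = 1)
    }))
  }))
  write_tsv(ci, file.path(config$out_dir, "ci_table.tsv"))
  comparison <- if (all(MODEL_KINDS %in% names(surfaces))) {
    cmp <- compare_three_models(surfaces)
    write_tsv(cmp, file.path(config$out_dir, "comparison_table.tsv"))
    cmp
  } else NULL
  write_log(config, "fit",
            c(paste0("observed: ", paste(unlist(obs), collapse = " ")),
              paste0("mu: ", prep$mu$mu),
              paste0("models: ", paste(config$models, collapse = ", "))))
  invisible(list(obs = obs, surfaces = surfaces, mle = mle, ci = ci,
                 comparison = comparison, specs = prep$specs, mu = prep$mu))
}

#' Pipeline stage: diversity statistics
#'
#' Reads the dataset and writes per-population diversity tables
#' (per-locus and summarised pi and rarefied allelic richness) and the
#' pairwise FST permutation test.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `per_locus`, `summary`, `fst`.
#' @export
cmd_diversity <- function(config) {
  if (is.null(config$loci_dir)) stop("config$loci_dir is required for diversity")
  ensure_out_dir(config)
  ds <- read_dataset(config$loci_dir)
  for (pop in c("west", "east")) {
    n_ok <- vapply(ds$alns, function(a) sum(a$alleles$population == pop), 1L)
    if (all(n_ok < 2)) {
      warning("population ", pop,
              " has < 2 alleles at every locus; skipped from diversity")
    }
  }
  div <- diversity_tables(ds$alns, g = config$rarefaction_g,
                          n_boot = config$n_boot, rng_seed = config$rng_seed)
  fst <- pairwise_fst(ds$alns, n_perms = config$n_perms,
                      rng_seed = config$rng_seed)
  write_tsv(div$per_locus, file.path(config$out_dir, "diversity_per_locus.tsv"))
  write_tsv(div$summary, file.path(config$out_dir, "diversity_summary.tsv"))
  write_tsv(fst, file.path(config$out_dir, "fst_table.tsv"))
  write_log(config, "diversity",
            paste0("rarefaction_depth: ", div$rarefaction_depth))
  invisible(list(per_locus = div$per_locus, summary = div$summary, fst = fst))
}
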
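# Synthetic study-like datasets with known truth: per-locus FASTA of
# phased alleles plus outgroup, a population map, and a truth file.
#
# Derived alleles are embedded only at third positions of
# fourfold-degenerate codons, so the synonymous-site filter recovers the
# simulated polymorphism exactly and filter correctness is separable
# from simulator correctness.  Outgroup divergence is placed at fourfold
# third positions not carrying polymorphism, so polarisation is
# unambiguous (no back-mutation, matching infinite sites).

# codon prefixes whose third position is fourfold degenerate
FOURFOLD_PREFIXES <- c("GC", "GG", "CC", "CG", "AC", "CT", "GT", "TC")
BASES <- c("A", "C", "G", "T")

#' Synthetic study design
#'
#' Defaults emulate the study conditions: 13 exon loci of 333-770 bp,
#' 22 and 26 phased alleles in the west and east populations (11 and 13
#' diploids), lognormal mutation-rate scalars normalised to mean 1, data
#' generated under the ongoing-migration model at its reported
#' maximum-likelihood parameters (theta = 0.002, m = 0.7 migrants per
#' generation, T = 8.5e6 generations) with mu = 2.69e-9 calibrated on a
#' 65-My outgroup split and a 1-year generation time.
#'
#' @param n_loci Number of loci.
#' @param length_range Locus length bounds in bp (lengths are drawn as
#'   multiples of 3 within the range).
#' @param n_west,n_east Phased alleles per population (even, diploids).
#' @param scalar_sdlog Lognormal sd of the per-locus rate scalars.
#' @param params True [model_params()].
#' @param mu True [mutation_rate()].
#' @param rng_seed Master seed.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_loci = 13, length_range = c(333, 770),
                         n_west = 22, n_east = 26, scalar_sdlog = 0.3,
                         params = model_params("ongoing_migration",
                                               theta = 0.002, T_gen = 8.5e6,
                                               m = 0.7),
                         mu = mutation_rate(2.69e-9, 65e6, 1),
                         rng_seed = 1) {
  if (n_loci < 1) stop("need at least one locus")
  if (n_west %% 2 != 0 || n_east %% 2 != 0) {
    stop("n_west and n_east must be even (phased diploids)")
  }
  if (n_west < 2 || n_east < 2) stop("need at least 2 alleles per population")
  structure(list(n_loci = as.integer(n_loci), length_range = length_range,
                 n_west = as.integer(n_west), n_east = as.integer(n_east),
                 scalar_sdlog = scalar_sdlog, params = params, mu = mu,
                 rng_seed = as.integer(rng_seed)),
            class = "study_design")
}

# one locus: backbone of fourfold codons, simulated polymorphism at
# distinct third positions, outgroup divergence at unused third positions
generate_locus <- function(design, locus_name, scalar, max_tries = 100) {
  len_choices <- seq(ceiling(design$length_range[1] / 3) * 3,
                     design$length_range[2], by = 3)
  nw <- design$n_west
  ne <- design$n_east
  n <- nw + ne
  n_regen <- 0L
  repeat {
    L <- sample(len_choices, 1)
    n_cod <- L %/% 3
    spec <- locus_spec(locus_name, length = n_cod, scalar = scalar,
                       n_west = nw, n_east = ne)
    gen <- sim_genealogy_raw(design$params, design$mu, nw, ne)
    sim <- drop_mutations(gen, spec, design$params)
    lam_div <- 2 * design$mu$mu * scalar *
      design$mu$divergence_time_years / design$mu$generation_time_years
    n_div <- stats::rpois(1, lam_div * n_cod)
    if (nrow(sim) + n_div <= n_cod) break
    n_regen <- n_regen + 1L
    if (n_regen >= max_tries) {
      stop("design infeasible: more segregating sites than synonymous positions")
    }
    warning("locus ", locus_name,
            ": more mutations than synonymous positions; regenerating")
  }
  prefixes <- sample(FOURFOLD_PREFIXES, n_cod, replace = TRUE)
  third <- sample(BASES, n_cod, replace = TRUE)
  anc <- character(L)
  anc[seq(1, L, 3)] <- substr(prefixes, 1, 1)
  anc[seq(2, L, 3)] <- substr(prefixes, 2, 2)
  anc[seq(3, L, 3)] <- third

  S <- nrow(sim)
  used <- sample.int(n_cod, S + n_div)
  poly_cod <- used[seq_len(S)]
  div_cod <- used[S + seq_len(n_div)]

  seqs <- matrix(rep(anc, each = n), nrow = n)
  for (k in seq_len(S)) {
    col <- 3 * poly_cod[k]
    derived <- sample(setdiff(BASES, anc[col]), 1)
    seqs[sim$carriers[[k]], col] <- derived
  }
  outg <- anc
  for (cod in div_cod) {
    col <- 3 * cod
    outg[col] <- sample(setdiff(BASES, anc[col]), 1)
  }

  sample_ids <- c(sprintf("W%02d", seq_len(nw / 2)),
                  sprintf("E%02d", seq_len(ne / 2)))
  allele_ids <- as.vector(t(outer(sample_ids, c("_a1", "_a2"), paste0)))
  alleles <- tibble::tibble(
    allele_id = allele_ids,
    sample_id = rep(sample_ids, each = 2),
    population = factor(rep(c("west", "east"), c(nw, ne)),
                        levels = c("west", "east")),
    sequence = apply(seqs, 1, paste, collapse = "")
  )
  aln <- locus_alignment(locus_name, alleles,
                         outgroup_seq = paste(outg, collapse = ""),
                         frame_offset = 0L)
  wh <- vapply(WH_CLASSES, function(k) sum(sim$class == k), 1L)
  list(aln = aln, spec = spec, sim = sim, wh = wh, length_bp = L,
       n_syn_sites = n_cod, n_divergence_subs = n_div, n_regenerated = n_regen)
}

# genealogy without touching the seed (stream continues)
sim_genealogy_raw <- function(params, mu, nw, ne) {
  sc <- coalescent_scaling(params, mu)
  raw <- sim_genealogy_cpp(nw, ne, sc$T_coal, sc$M_coal, params$tau,
                           model_code(params$model))
  parent <- raw$parent + 1L
  parent[parent == 0L] <- NA_integer_
  structure(list(parent = parent, time = raw$time, n_west = nw, n_east = ne),
            class = "genealogy")
}

#' Generate a synthetic study-like dataset
#'
#' Simulates every locus under the design's true model, embeds the
#' derived alleles into a fourfold-degenerate codon backbone, writes one
#' FASTA per locus (with an `OUTGROUP` record), a tab-separated
#' population map, and a JSON truth file recording the true parameters,
#' per-locus scalars and the per-locus and total Wakeley-Hey counts.
#'
#' @param design A [study_design()].
#' @param dir Output directory (created if missing).  `NULL` keeps the
#'   dataset in memory only.
#' @return Invisibly, a list with `alns`, `specs`, `truth`, `dir`.
#' @export
generate_dataset <- function(design, dir = NULL) {
  set.seed(design$rng_seed)
  raw_scalar <- stats::rlnorm(design$n_loci, -design$scalar_sdlog^2 / 2,
                              design$scalar_sdlog)
  scalars <- raw_scalar / mean(raw_scalar)
  locus_names <- sprintf("locus_%02d", seq_len(design$n_loci))
  loci <- purrr::map2(locus_names, scalars,
                      function(nm, sc) generate_locus(design, nm, sc))
  alns <- purrr::map(loci, "aln")
  specs <- dplyr::bind_rows(purrr::map(loci, "spec"))
  by_locus <- dplyr::bind_rows(purrr::map(loci, function(l) {
    tibble::tibble(locus = l$aln$locus_name, length_bp = l$length_bp,
                   n_syn_sites = l$n_syn_sites, scalar = l$spec$scalar,
                   n_divergence_subs = l$n_divergence_subs,
                   !!!as.list(l$wh))
  }))
  totals <- as.list(colSums(by_locus[, WH_CLASSES]))
  truth <- list(
    model = design$params$model,
    theta = design$params$theta, T_gen = design$params$T_gen,
    m = design$params$m, tau = design$params$tau,
    mu = design$mu$mu,
    rng_seed = design$rng_seed,
    n_west = design$n_west, n_east = design$n_east,
    wh_total = totals,
    by_locus = by_locus,
    n_regenerated = sum(purrr::map_int(loci, "n_regenerated"))
  )
  pop_map <- tibble::tibble(
    sample_id = c(sprintf("W%02d", seq_len(design$n_west / 2)),
                  sprintf("E%02d", seq_len(design$n_east / 2))),
    species = "gilli",
    population = rep(c("west", "east"),
                     c(design$n_west / 2, design$n_east / 2)),
    year = 2013L
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (a in alns) {
      write_locus_fasta(a, file.path(dir, paste0(a$locus_name, ".fasta")))
    }
    utils::write.table(pop_map, file.path(dir, "population_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(list(alns = alns, specs = specs, truth = truth,
                 pop_map = pop_map, dir = dir))
}

#' Generate a null dataset: two samples from one panmictic deme
#'
#' Same machinery as [generate_dataset()] with the split time forced to
#' zero, so west and east labels are arbitrary; used to calibrate FST
#' permutation tests and other null behaviour.
#'
#' @inheritParams generate_dataset
#' @export
generate_null_pair <- function(design, dir = NULL) {
  design$params <- model_params("isolation", theta = design$params$theta,
                                T_gen = 0)
  generate_dataset(design, dir)
}

#' Read a dataset directory written by [generate_dataset()]
#'
#' @param dir Directory with per-locus `*.fasta` files and
#'   `population_map.tsv`.
#' @return A list with `alns` (locus alignments, frame not yet set) and
#'   `pop_map`.
#' @export
read_dataset <- function(dir) {
  map <- read_population_map(file.path(dir, "population_map.tsv"))
  files <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (length(files) == 0) stop("no FASTA files in ", dir)
  alns <- lapply(files, read_locus_fasta, population_map = map)
  list(alns = alns, pop_map = map)
}
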
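# Structured-coalescent simulation under the three demographic models,
# with infinite-sites mutation and per-locus rate scalars.

MODEL_KINDS <- c("isolation", "ongoing_migration", "secondary_contact")

#' Demographic model parameters
#'
#' One demographic hypothesis for the two-population history: a split
#' `T_gen` generations ago of an ancestral population into west and east
#' demes, all three with per-site polymorphism parameter `theta = 4*N*mu`,
#' with symmetric migration of `m` migrant individuals per generation
#' active never (`isolation`), since the split (`ongoing_migration`), or
#' only during the most recent fraction `tau` of the time since the split
#' (`secondary_contact`).
#'
#' @param model One of `"isolation"`, `"ongoing_migration"`,
#'   `"secondary_contact"`.
#' @param theta Per-site polymorphism parameter `4*N*mu`, > 0.
#' @param T_gen Split time in generations, >= 0.
#' @param m Migrants per generation (Wright's Nm); must be 0 under
#'   isolation.
#' @param tau Fraction of `T_gen` (looking backward from the present)
#'   with migration, in (0, 1]; must be 1 unless the model is secondary
#'   contact.
#' @return An object of class `model_params`.
#' @export
model_params <- function(model = MODEL_KINDS, theta, T_gen, m = 0, tau = 1) {
  model <- match.arg(model)
  if (theta <= 0) stop("theta must be > 0")
  if (T_gen < 0) stop("T_gen must be >= 0")
  if (m < 0) stop("m must be >= 0")
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  if (model == "isolation" && m != 0) stop("isolation model requires m = 0")
  if (model == "ongoing_migration" && tau != 1) {
    stop("ongoing_migration model requires tau = 1")
  }
  structure(list(model = model, theta = theta, T_gen = T_gen,
                 m = m, tau = tau),
            class = "model_params")
}

#' Per-locus simulation specification
#'
#' @param locus_name Locus labels.
#' @param length Locus length in synonymous sites subject to mutation.
#' @param scalar Per-locus mutation-rate scalar (mean 1 across loci).
#' @param n_west,n_east Sampled allele counts per population.
#' @return A tibble with one row per locus.
#' @export
locus_spec <- function(locus_name, length, scalar = 1, n_west, n_east) {
  spec <- tibble::tibble(locus_name = locus_name, length = length,
                         scalar = scalar, n_west = n_west, n_east = n_east)
  if (any(spec$length <= 0)) stop("length must be > 0")
  if (any(spec$scalar <= 0)) stop("scalar must be > 0")
  if (any(spec$n_west + spec$n_east < 2)) stop("need at least 2 sampled alleles")
  spec
}

#' Convert model parameters to coalescent scalings
#'
#' Returns the effective population size `N_e = theta / (4 mu)`, the
#' split time in coalescent units `T_coal = T_gen / (4 N_e)` (the unit in
#' which a pair of lineages within a deme coalesces at rate 1), and the
#' scaled migration rate `M_coal`.  Under the default Wright convention
#' `m` is the number of migrant individuals per generation (Nm) and
#' `M_coal = 4 m`; the `"direct"` convention sets `M_coal = m`.
#'
#' @param params A [model_params()].
#' @param mu A [mutation_rate()].
#' @param migration_convention `"wright"` (default) or `"direct"`.
#' @return A tibble with columns `N_e`, `T_coal`, `M_coal`.
#' @export
coalescent_scaling <- function(params, mu,
                               migration_convention = c("wright", "direct")) {
  migration_convention <- match.arg(migration_convention)
  if (mu$mu <= 0) stop("mu must be > 0")
  N_e <- params$theta / (4 * mu$mu)
  T_coal <- params$T_gen / (4 * N_e)
  M_coal <- if (migration_convention == "wright") 4 * params$m else params$m
  tibble::tibble(N_e = N_e, T_coal = T_coal, M_coal = M_coal)
}

model_code <- function(model) match(model, MODEL_KINDS) - 1L

#' Simulate one genealogy under a two-population model
#'
#' Structured coalescent with two demes of equal size, symmetric lineage
#' migration at rate `M_coal / 2` per lineage while migration is active,
#' and a merge of all lineages into a single ancestral deme at
#' `T_coal`.  Times are in units in which a pair of lineages within a
#' deme coalesces at rate 1.
#'
#' @inheritParams coalescent_scaling
#' @param spec A single row of a [locus_spec()] table (or a list with
#'   `n_west`, `n_east`).
#' @param rng_seed Optional integer seed.
#' @return An object of class `genealogy`: leaf nodes `1:(n_west+n_east)`
#'   (west first), internal nodes above, fields `parent` (NA at the
#'   root), `time`, `n_west`, `n_east`.
#' @export
simulate_genealogy <- function(params, spec, mu, rng_seed = NULL,
                               migration_convention = c("wright", "direct")) {
  nw <- as.integer(spec$n_west)
  ne <- as.integer(spec$n_east)
  if (nw + ne < 2) stop("need at least 2 sampled alleles")
  if (!is.null(rng_seed)) {
    if (!is.finite(rng_seed)) stop("invalid rng_seed")
    set.seed(as.integer(rng_seed))
  }
  sc <- coalescent_scaling(params, mu, migration_convention)
  raw <- sim_genealogy_cpp(nw, ne, sc$T_coal, sc$M_coal, params$tau,
                           model_code(params$model))
  parent <- raw$parent + 1L
  parent[parent == 0L] <- NA_integer_
  structure(list(parent = parent, time = raw$time,
                 n_west = nw, n_east = ne),
            class = "genealogy")
}

genealogy_n_leaves <- function(gen) gen$n_west + gen$n_east

# total branch length and per-class lengths (private_west, private_east,
# shared, fixed, total)
genealogy_class_lengths <- function(gen) {
  raw_parent <- ifelse(is.na(gen$parent), 0L, gen$parent) - 1L
  wh_branch_lengths_cpp(raw_parent, gen$time, gen$n_west, gen$n_east)
}

# leaves below each node, as a list of integer vectors
descendant_leaves <- function(gen) {
  n <- genealogy_n_leaves(gen)
  desc <- vector("list", 2 * n - 1)
  for (i in seq_len(n)) desc[[i]] <- i
  for (i in seq_len(2 * n - 2)) {
    p <- gen$parent[i]
    desc[[p]] <- c(desc[[p]], desc[[i]])
  }
  desc
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' The number of mutations is Poisson with mean
#' `theta_locus / 2 * total branch length`, where
#' `theta_locus = theta * scalar * length`; each mutation falls on a
#' branch chosen proportionally to its length and is carried by every
#' leaf below it; positions are i.i.d. uniform on \[0, 1).
#'
#' @param gen A genealogy from [simulate_genealogy()].
#' @inheritParams simulate_genealogy
#' @return An object of class `sim_locus`: a tibble with columns
#'   `position`, `node`, `n_west_carriers`, `n_east_carriers`, `class`
#'   and a list column `carriers`, plus attributes `n_west`, `n_east`.
#' @export
drop_mutations <- function(gen, spec, params, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  theta_locus <- params$theta * spec$scalar * spec$length
  lens <- genealogy_class_lengths(gen)
  total_len <- lens[5]
  n_mut <- stats::rpois(1, theta_locus / 2 * total_len)
  nw <- gen$n_west
  ne <- gen$n_east
  n <- nw + ne
  edge_len <- gen$time[gen$parent[seq_len(2 * n - 2)]] - gen$time[seq_len(2 * n - 2)]
  if (n_mut == 0) {
    sim <- tibble::tibble(position = numeric(0), node = integer(0),
                          n_west_carriers = integer(0),
                          n_east_carriers = integer(0),
                          class = character(0), carriers = list())
  } else {
    nodes <- sample.int(2 * n - 2, n_mut, replace = TRUE, prob = edge_len)
    desc <- descendant_leaves(gen)
    carriers <- desc[nodes]
    cw <- vapply(carriers, function(d) sum(d <= nw), 1L)
    ce <- vapply(carriers, function(d) sum(d > nw), 1L)
    sim <- tibble::tibble(
      position = sort(stats::runif(n_mut)),
      node = nodes,
      n_west_carriers = cw,
      n_east_carriers = ce,
      class = wh_class_from_counts(cw, ce, nw, ne),
      carriers = carriers
    )
  }
  structure(sim, n_west = nw, n_east = ne,
            class = c("sim_locus", class(sim)))
}

# Wakeley-Hey class of a derived mutation carried by cw west and ce east
# alleles out of nw and ne sampled
wh_class_from_counts <- function(cw, ce, nw, ne) {
  poly_w <- cw > 0 & cw < nw
  poly_e <- ce > 0 & ce < ne
  dplyr::case_when(
    poly_w & poly_e ~ "shared",
    poly_w ~ "private_west",
    poly_e ~ "private_east",
    (cw == nw & ce == 0) | (cw == 0 & ce == ne) ~ "fixed",
    .default = "monomorphic"
  )
}

#' Simulate the four across-locus Wakeley-Hey sums in batch
#'
#' Runs `n_sims` independent multi-locus simulations under one parameter
#' combination and returns, per replicate, the four summary statistics
#' summed across loci.  All loci share the demographic scaling; their
#' mutation targets are `theta * scalar * length`.
#'
#' @inheritParams coalescent_scaling
#' @param specs A [locus_spec()] table.
#' @param n_sims Number of replicate multi-locus simulations.
#' @param rng_seed Optional integer seed.
#' @return A tibble with `n_sims` rows and columns `private_west`,
#'   `private_east`, `shared`, `fixed`.
#' @export
simulate_wh <- function(params, specs, mu, n_sims, rng_seed = NULL,
                        migration_convention = c("wright", "direct")) {
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  sc <- coalescent_scaling(params, mu, migration_convention)
  theta_locus <- params$theta * specs$scalar * specs$length
  m <- sim_wh_batch_cpp(as.integer(specs$n_west), as.integer(specs$n_east),
                        theta_locus, sc$T_coal, sc$M_coal, params$tau,
                        model_code(params$model), as.integer(n_sims))
  colnames(m) <- c("private_west", "private_east", "shared", "fixed")
  tibble::as_tibble(m)
}

#' Render simulated loci as ms-style text
#'
#' Writes the conventional `//` / `segsites:` / `positions:` block with a
#' 0/1 haplotype matrix (west alleles first), for cross-tool validation.
#'
#' @param sim_loci A `sim_locus` or list of them.
#' @return A character scalar.
#' @export
as_ms_text <- function(sim_loci) {
  if (inherits(sim_loci, "sim_locus")) sim_loci <- list(sim_loci)
  blocks <- vapply(sim_loci, function(sim) {
    nw <- attr(sim, "n_west")
    ne <- attr(sim, "n_east")
    n <- nw + ne
    s <- nrow(sim)
    if (s == 0) return("//\nsegsites: 0\n")
    hap <- matrix(0L, n, s)
    for (k in seq_len(s)) hap[sim$carriers[[k]], k] <- 1L
    paste0("//\nsegsites: ", s, "\npositions: ",
           paste(sprintf("%.5f", sim$position), collapse = " "), "\n",
           paste(apply(hap, 1, paste, collapse = ""), collapse = "\n"), "\n")
  }, "")
  paste(blocks, collapse = "\n")
}
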
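# Per-population genetic diversity: nucleotide diversity with
# length-weighted bootstrap confidence intervals, rarefied allelic
# richness, and pairwise FST with permutation tests.

#' Per-locus nucleotide diversity
#'
#' Mean pairwise difference per comparable site over all allele pairs,
#' computed from raw pairwise distances with pairwise deletion of sites
#' containing gaps or ambiguous bases.
#'
#' @param seqs Character vector of aligned sequences (>= 2, equal
#'   lengths), or the `alleles` tibble of a [locus_alignment()].
#' @return Nucleotide diversity per site.
#' @export
nucleotide_diversity <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- seqs$sequence
  if (length(seqs) < 2) stop("need at least 2 alleles")
  if (length(unique(nchar(seqs))) != 1) stop("sequences must be equal length")
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
  mean(d, na.rm = TRUE)
}

#' Length-weighted mean diversity with a bootstrap CI
#'
#' The point estimate is the gene-length-weighted mean of the per-locus
#' values; the confidence interval is the percentile bootstrap over loci
#' (resampled with replacement, same count).  With `weights = NULL` an
#' unweighted mean is used (as for rarefied allelic richness).
#'
#' @param values Per-locus statistic values.
#' @param weights Per-locus weights (gene lengths), or `NULL`.
#' @param n_boot Bootstrap replicates.
#' @param rng_seed Optional integer seed.
#' @param statistic Label stored in the result.
#' @param level Confidence level.
#' @return A one-row tibble: `statistic`, `point`, `ci_low`, `ci_high`,
#'   `n_boot`, `n_loci`.
#' @export
bootstrap_mean <- function(values, weights = NULL, n_boot = 5000,
                           rng_seed = NULL, statistic = "pi", level = 0.95) {
  if (length(values) < 1) stop("need at least one locus")
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(weights) == length(values))
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  point <- stats::weighted.mean(values, weights)
  idx <- matrix(sample.int(length(values), length(values) * n_boot,
                           replace = TRUE), nrow = n_boot)
  boots <- apply(idx, 1, function(i) stats::weighted.mean(values[i], weights[i]))
  alpha <- (1 - level) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  tibble::tibble(statistic = statistic, point = point,
                 ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot), n_loci = length(values))
}

#' @rdname bootstrap_mean
#' @param pi Per-locus nucleotide diversities.
#' @param lengths Per-locus gene lengths (weights).
#' @export
weighted_mean_pi <- function(pi, lengths, n_boot = 5000, rng_seed = NULL) {
  bootstrap_mean(pi, weights = lengths, n_boot = n_boot, rng_seed = rng_seed,
                 statistic = "pi")
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` of
#' the `N` sampled allele copies, from the hypergeometric expectation
#' `sum_i (1 - choose(N - N_i, g) / choose(N, g))`.
#'
#' @param allele_counts Counts of each distinct allele at one locus.
#' @param g Rarefaction depth, `1 <= g <= sum(allele_counts)`.
#' @return Expected number of distinct alleles.
#' @export
rarefied_richness <- function(allele_counts, g) {
  allele_counts <- allele_counts[allele_counts > 0]
  N <- sum(allele_counts)
  if (g < 1 || g > N) stop("g must be between 1 and ", N)
  sum(1 - exp(lchoose(N - allele_counts, g) - lchoose(N, g)))
}

# counts of distinct haplotype sequences among a set of alleles
haplotype_counts <- function(seqs) {
  as.integer(table(seqs))
}

#' Per-population diversity table for a multi-locus dataset
#'
#' Computes, per population, per-locus nucleotide diversity and rarefied
#' allelic richness, then summarises each with a bootstrap CI over loci
#' (pi weighted by locus length, richness unweighted).
#'
#' @param alns List of [locus_alignment()] objects.
#' @param g Rarefaction depth; defaults to the smallest number of
#'   sampled alleles over populations and loci (the study rule).
#' @param n_boot Bootstrap replicates.
#' @param rng_seed Optional integer seed.
#' @return A list with `per_locus` (population, locus, length, n_alleles,
#'   pi, richness) and `summary` (one row per population x statistic).
#' @export
diversity_tables <- function(alns, g = NULL, n_boot = 5000, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  per_locus <- purrr::map_dfr(alns, function(aln) {
    purrr::map_dfr(c("west", "east"), function(pop) {
      seqs <- aln$alleles$sequence[aln$alleles$population == pop]
      tibble::tibble(
        population = pop, locus = aln$locus_name, length = aln$length,
        n_alleles = length(seqs),
        pi = if (length(seqs) >= 2) nucleotide_diversity(seqs) else NA_real_,
        haplotypes = list(haplotype_counts(seqs))
      )
    })
  })
  if (is.null(g)) g <- min(per_locus$n_alleles)
  per_locus$richness <- vapply(per_locus$haplotypes, function(h) {
    if (sum(h) >= g) rarefied_richness(h, g) else NA_real_
  }, 1.0)
  per_locus$haplotypes <- NULL
  summary <- purrr::map_dfr(c("west", "east"), function(pop) {
    d <- per_locus[per_locus$population == pop & !is.na(per_locus$pi), ]
    dr <- per_locus[per_locus$population == pop & !is.na(per_locus$richness), ]
    dplyr::bind_rows(
      dplyr::mutate(
        weighted_mean_pi(d$pi, d$length, n_boot = n_boot),
        population = pop, .before = 1),
      dplyr::mutate(
        bootstrap_mean(dr$richness, n_boot = n_boot,
                       statistic = "allelic_richness"),
        population = pop, .before = 1)
    )
  })
  list(per_locus = per_locus, summary = summary,
       rarefaction_depth = as.integer(g))
}

# Pairwise difference and comparable-site counts between all allele
# pairs, aggregated per unordered sample pair and pooled across loci.
# Pairs of the two phased alleles of one individual appear as the
# diagonal pair (s, s) and remain within-population under any
# permutation of individuals.
fst_pair_table <- function(alns) {
  s1 <- s2 <- character(0)
  d <- n_comp <- integer(0)
  for (aln in alns) {
    m <- alignment_matrix(aln)
    code <- matrix(match(m, c("A", "C", "G", "T"), nomatch = 0L), nrow(m))
    samp <- aln$alleles$sample_id
    n <- nrow(code)
    np <- n * (n - 1) / 2
    a <- b <- character(np); dd <- nc <- integer(np)
    k <- 0L
    for (i in seq_len(n - 1)) {
      xi <- code[i, ]
      for (j in (i + 1):n) {
        xj <- code[j, ]
        comp <- xi > 0L & xj > 0L
        k <- k + 1L
        a[k] <- min(samp[i], samp[j])
        b[k] <- max(samp[i], samp[j])
        dd[k] <- sum(xi[comp] != xj[comp])
        nc[k] <- sum(comp)
      }
    }
    s1 <- c(s1, a); s2 <- c(s2, b); d <- c(d, dd); n_comp <- c(n_comp, nc)
  }
  df <- tibble::tibble(s1 = s1, s2 = s2, d = d, n_comp = n_comp)
  dplyr::summarise(dplyr::group_by(df, .data$s1, .data$s2),
                   d = sum(.data$d), n_comp = sum(.data$n_comp),
                   .groups = "drop")
}

# FST = 1 - Hw/Hb for one labelling of samples
fst_from_pairs <- function(pairs, pop_of) {
  within <- pop_of[pairs$s1] == pop_of[pairs$s2]
  den_w <- sum(pairs$n_comp[within])
  den_b <- sum(pairs$n_comp[!within])
  Hw <- if (den_w > 0) sum(pairs$d[within]) / den_w else 0
  Hb <- if (den_b > 0) sum(pairs$d[!within]) / den_b else 0
  if (Hb <= 0) 0 else 1 - Hw / Hb
}

#' Pairwise FST with a permutation test
#'
#' Hudson-style multi-locus `FST = 1 - Hw / Hb`, where `Hw` and `Hb` are
#' the mean within- and between-population pairwise differences per
#' comparable site pooled across loci.  Significance is assessed by
#' permuting individuals (both phased alleles together) between the two
#' populations; `p = (# permutations with FST >= observed + 1) /
#' (n_perms + 1)`.
#'
#' @param alns List of [locus_alignment()] objects carrying west/east
#'   population labels.
#' @param n_perms Number of permutations.
#' @param rng_seed Optional integer seed.
#' @return A one-row tibble: `pop_pair`, `fst`, `p_value`, `n_perms`.
#' @export
pairwise_fst <- function(alns, n_perms = 10000, rng_seed = NULL) {
  if (inherits(alns, "locus_alignment")) alns <- list(alns)
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  ind <- unique(dplyr::bind_rows(
    lapply(alns, function(a) a$alleles[, c("sample_id", "population")])))
  if (length(unique(ind$population)) < 2) {
    stop("both populations need sampled alleles")
  }
  pairs <- fst_pair_table(alns)
  pop_of <- setNames(as.character(ind$population), ind$sample_id)
  obs <- fst_from_pairs(pairs, pop_of)
  ids <- ind$sample_id
  labs <- as.character(ind$population)
  perm_ge <- 0L
  for (b in seq_len(n_perms)) {
    perm <- setNames(sample(labs), ids)
    perm_ge <- perm_ge + (fst_from_pairs(pairs, perm) >= obs)
  }
  tibble::tibble(pop_pair = "west_vs_east",
                 fst = obs,
                 p_value = (perm_ge + 1) / (n_perms + 1),
                 n_perms = as.integer(n_perms))
}
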
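# Reading phased multi-locus alignments, reading-frame inference,
# synonymous-site classification, and mutation-rate calibration.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Read a sample/population map
#'
#' The map is tab-separated text with header
#' `sample_id species population year`; `population` must be `east` or
#' `west`.
#'
#' @param path Path to the tab-separated map file.
#' @return A tibble with columns `sample_id`, `species`, `population`
#'   (factor east/west) and `year`.
#' @export
read_population_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  required <- c("sample_id", "species", "population", "year")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("population map is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in population map: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$population), c("east", "west"))
  if (length(bad) > 0) {
    stop("population must be 'east' or 'west'; found: ",
         paste(bad, collapse = ", "))
  }
  tibble::tibble(
    sample_id = df$sample_id,
    species = df$species,
    population = factor(df$population, levels = c("west", "east")),
    year = as.integer(df$year)
  )
}

#' Construct a locus alignment object
#'
#' Holds the phased alleles of one exon locus, an optional outgroup
#' sequence of the same length, and the reading-frame offset.
#'
#' @param locus_name Locus label.
#' @param alleles Tibble with columns `allele_id`, `sample_id`,
#'   `population`, `sequence` (upper-case over A,C,G,T,N,-; equal lengths).
#' @param outgroup_seq Outgroup sequence of the same length, or `NA`.
#' @param frame_offset Reading-frame offset in 0:2, or `NA` if not yet set.
#' @return An object of class `locus_alignment`.
#' @export
locus_alignment <- function(locus_name, alleles, outgroup_seq = NA_character_,
                            frame_offset = NA_integer_) {
  stopifnot(is.data.frame(alleles),
            all(c("allele_id", "sample_id", "population", "sequence") %in%
                  names(alleles)))
  widths <- nchar(alleles$sequence)
  if (length(unique(widths)) != 1) {
    bad <- alleles$allele_id[widths != widths[1]]
    stop("ragged alignment: sequence length differs for ",
         paste(bad, collapse = ", "))
  }
  len <- widths[1]
  if (!is.na(outgroup_seq) && nchar(outgroup_seq) != len) {
    stop("ragged alignment: outgroup length ", nchar(outgroup_seq),
         " differs from allele length ", len)
  }
  structure(
    list(locus_name = locus_name,
         alleles = tibble::as_tibble(alleles),
         outgroup_seq = outgroup_seq,
         frame_offset = as.integer(frame_offset),
         length = len),
    class = "locus_alignment"
  )
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus_name, ": ", nrow(x$alleles),
      " alleles x ", x$length, " bp",
      if (!is.na(x$outgroup_seq)) ", outgroup present" else "",
      if (!is.na(x$frame_offset)) paste0(", frame ", x$frame_offset) else "",
      "\n", sep = "")
  invisible(x)
}

#' Read one locus FASTA and join population labels
#'
#' Headers follow the convention `sampleID_a1` / `sampleID_a2` for the two
#' phased alleles of a diploid individual; a record named `OUTGROUP` is
#' stored as the outgroup sequence and not counted among the alleles.
#'
#' @param path FASTA file for one locus.
#' @param population_map Tibble from [read_population_map()].
#' @param locus_name Locus label; defaults to the file name without
#'   extension.
#' @return A [locus_alignment()].
#' @export
read_locus_fasta <- function(path, population_map,
                             locus_name = sub("\\.[^.]*$", "", basename(path))) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) != 1) {
    bad <- nm[widths != widths[1]]
    stop("ragged alignment in ", path, ": record(s) ",
         paste(bad, collapse = ", "), " differ in length")
  }
  chr <- as.character(seqs)
  is_out <- nm == "OUTGROUP"
  outgroup_seq <- if (any(is_out)) unname(chr[is_out][1]) else NA_character_
  nm <- nm[!is_out]
  chr <- chr[!is_out]
  m <- regmatches(nm, regexec("^(.*)_a([12])$", nm))
  bad_hdr <- nm[vapply(m, length, 1L) != 3]
  if (length(bad_hdr) > 0) {
    stop("FASTA header(s) not of the form sampleID_a1/sampleID_a2: ",
         paste(bad_hdr, collapse = ", "))
  }
  sample_id <- vapply(m, `[`, "", 2)
  unmatched <- setdiff(unique(sample_id), population_map$sample_id)
  if (length(unmatched) > 0) {
    stop("sample(s) in FASTA absent from population map: ",
         paste(unmatched, collapse = ", "))
  }
  alleles <- tibble::tibble(allele_id = nm, sample_id = sample_id,
                            sequence = toupper(unname(chr)))
  alleles <- dplyr::left_join(
    alleles, population_map[, c("sample_id", "population")], by = "sample_id")
  alleles <- alleles[, c("allele_id", "sample_id", "population", "sequence")]
  locus_alignment(locus_name, alleles, outgroup_seq)
}

#' Write a locus alignment as FASTA
#'
#' Inverse of [read_locus_fasta()]; the outgroup, if present, is written
#' as a record named `OUTGROUP`.
#'
#' @param aln A [locus_alignment()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(aln, path) {
  seqs <- aln$alleles$sequence
  nms <- aln$alleles$allele_id
  if (!is.na(aln$outgroup_seq)) {
    seqs <- c(seqs, aln$outgroup_seq)
    nms <- c(nms, "OUTGROUP")
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- nms
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Infer the reading frame by minimising stop codons
#'
#' Gaps are removed, the sequence is read in each of the three offsets,
#' and complete codons are checked against the standard stop codons
#' (TAA, TAG, TGA).  The offset with the fewest stops wins; ties go to
#' the smallest offset.  Incomplete trailing codons are ignored.
#'
#' @param seq A nucleotide sequence (character scalar).
#' @return Integer offset in 0:2.
#' @export
infer_reading_frame <- function(seq) {
  s <- gsub("-", "", toupper(seq))
  if (nchar(s) == 0) stop("degenerate input: sequence is all gaps")
  if (nchar(s) < 3) stop("sequence shorter than one codon after gap removal")
  counts <- vapply(0:2, function(off) count_stop_codons(s, off), 1L)
  as.integer(which.min(counts) - 1L)
}

#' @rdname infer_reading_frame
#' @param offset Frame offset in 0:2.
#' @return `count_stop_codons()`: number of stop codons among the complete
#'   codons at the given offset.
#' @export
count_stop_codons <- function(seq, offset) {
  s <- gsub("-", "", toupper(seq))
  n_cod <- (nchar(s) - offset) %/% 3
  if (n_cod <= 0) return(0L)
  starts <- offset + 1 + 3 * (seq_len(n_cod) - 1)
  codons <- substring(s, starts, starts + 2)
  sum(codons %in% STOP_CODONS)
}

#' Majority consensus of the ingroup alleles
#'
#' Per column, the most frequent base among A,C,G,T (ties to the
#' alphabetically first); columns with no unambiguous base become N.
#'
#' @param aln A [locus_alignment()].
#' @return A character scalar of the alignment length.
#' @export
consensus_sequence <- function(aln) {
  m <- alignment_matrix(aln)
  apply_cols <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(factor(m[, j], levels = c("A", "C", "G", "T")))
    if (sum(tab) == 0) "N" else names(tab)[which.max(tab)]
  }, "")
  paste(apply_cols, collapse = "")
}

#' Set (or infer) the reading frame of an alignment
#'
#' When `offset` is `NULL` the frame is inferred from the majority
#' consensus of the ingroup alleles via [infer_reading_frame()].
#'
#' @inheritParams consensus_sequence
#' @param offset Frame offset in 0:2, or `NULL` to infer.
#' @return The alignment with `frame_offset` set.
#' @export
set_reading_frame <- function(aln, offset = NULL) {
  if (is.null(offset)) offset <- infer_reading_frame(consensus_sequence(aln))
  stopifnot(offset %in% 0:2)
  aln$frame_offset <- as.integer(offset)
  aln
}

#' Trim an alignment to whole codons
#'
#' Drops the leading `frame_offset` columns and any incomplete trailing
#' codon, so the result begins at the first and ends at the third codon
#' position.
#'
#' @inheritParams consensus_sequence
#' @return A trimmed [locus_alignment()] with `frame_offset = 0`.
#' @export
trim_to_frame <- function(aln) {
  if (is.na(aln$frame_offset)) stop("frame_offset not set; call set_reading_frame()")
  off <- aln$frame_offset
  n_keep <- ((aln$length - off) %/% 3) * 3
  if (n_keep < 3) stop("alignment too short to retain a single codon")
  crop <- function(s) substr(s, off + 1, off + n_keep)
  aln$alleles$sequence <- vapply(aln$alleles$sequence, crop, "", USE.NAMES = FALSE)
  if (!is.na(aln$outgroup_seq)) aln$outgroup_seq <- crop(aln$outgroup_seq)
  aln$length <- n_keep
  aln$frame_offset <- 0L
  aln
}

# character matrix: rows = alleles (+ optional outgroup), cols = sites
alignment_matrix <- function(aln, with_outgroup = FALSE) {
  seqs <- aln$alleles$sequence
  if (with_outgroup && !is.na(aln$outgroup_seq)) seqs <- c(seqs, aln$outgroup_seq)
  do.call(rbind, strsplit(seqs, ""))
}

#' Classify alignment sites by their coding effect
#'
#' Each site is assigned one of `synonymous_variable`,
#' `nonsynonymous_variable`, `monomorphic` or `excluded`.  Classification
#' is by observed whole-codon variants over ingroup plus outgroup: a
#' variable site is synonymous only if every observed codon variant in
#' its codon column translates to the same amino acid; codon variants
#' containing N, a gap or a stop exclude all three sites of that codon.
#'
#' @param aln A [locus_alignment()] with `frame_offset` set and length
#'   divisible by 3 after the offset (see [trim_to_frame()]).
#' @return A tibble with columns `site` (1-based) and `class`.
#' @export
classify_synonymous_sites <- function(aln) {
  if (is.na(aln$frame_offset)) stop("frame_offset not set")
  if ((aln$length - aln$frame_offset) %% 3 != 0) {
    stop("alignment not trimmed to whole codons: length ", aln$length,
         " minus offset ", aln$frame_offset, " is not divisible by 3")
  }
  m <- alignment_matrix(aln, with_outgroup = TRUE)
  L <- aln$length
  cls <- rep("excluded", L)
  off <- aln$frame_offset
  n_cod <- (L - off) %/% 3
  gc <- Biostrings::GENETIC_CODE
  for (k in seq_len(n_cod)) {
    j <- off + 3 * (k - 1) + 1:3
    codons <- unique(paste0(m[, j[1]], m[, j[2]], m[, j[3]]))
    if (any(grepl("[^ACGT]", codons)) || any(codons %in% STOP_CODONS)) {
      cls[j] <- "excluded"
      next
    }
    aas <- unname(gc[codons])
    same_aa <- length(unique(aas)) == 1
    for (p in 1:3) {
      variable <- length(unique(m[, j[p]])) > 1
      cls[j[p]] <- if (!variable) "monomorphic"
        else if (same_aa) "synonymous_variable"
        else "nonsynonymous_variable"
    }
  }
  tibble::tibble(site = seq_len(L), class = cls)
}

# TRUE for codon-position-3-style sites where any base yields the same
# amino acid given the observed codon context (fourfold-degenerate).
fourfold_degenerate <- function(codon, pos) {
  gc <- Biostrings::GENETIC_CODE
  variants <- vapply(c("A", "C", "G", "T"), function(b) {
    v <- codon
    substr(v, pos, pos) <- b
    unname(gc[v])
  }, "")
  length(unique(variants)) == 1
}

#' Count synonymous sites available to mutation
#'
#' Counts sites usable as synonymous positions for per-locus mutation
#' targets: variable sites classified `synonymous_variable`, plus
#' monomorphic sites that are fourfold degenerate in every observed codon
#' variant (any base change there would be synonymous).
#'
#' @inheritParams classify_synonymous_sites
#' @return Integer count.
#' @export
count_synonymous_sites <- function(aln) {
  classes <- classify_synonymous_sites(aln)$class
  m <- alignment_matrix(aln, with_outgroup = TRUE)
  off <- aln$frame_offset
  n_cod <- (aln$length - off) %/% 3
  n_syn <- sum(classes == "synonymous_variable")
  for (k in seq_len(n_cod)) {
    j <- off + 3 * (k - 1) + 1:3
    codons <- unique(paste0(m[, j[1]], m[, j[2]], m[, j[3]]))
    if (any(grepl("[^ACGT]", codons)) || any(codons %in% STOP_CODONS)) next
    for (p in 1:3) {
      if (classes[j[p]] != "monomorphic") next
      if (all(vapply(codons, fourfold_degenerate, TRUE, pos = p))) {
        n_syn <- n_syn + 1L
      }
    }
  }
  n_syn
}

#' Synonymous divergence to the outgroup
#'
#' Raw p-distance between the ingroup majority consensus and the outgroup
#' restricted to synonymous sites (variable synonymous sites plus
#' monomorphic fourfold-degenerate sites).
#'
#' @inheritParams classify_synonymous_sites
#' @return Substitutions per synonymous site (proportion).
#' @export
synonymous_divergence <- function(aln) {
  if (is.na(aln$outgroup_seq)) stop("no outgroup sequence in alignment")
  classes <- classify_synonymous_sites(aln)$class
  m <- alignment_matrix(aln, with_outgroup = TRUE)
  off <- aln$frame_offset
  n_cod <- (aln$length - off) %/% 3
  use <- rep(FALSE, aln$length)
  for (k in seq_len(n_cod)) {
    j <- off + 3 * (k - 1) + 1:3
    codons <- unique(paste0(m[, j[1]], m[, j[2]], m[, j[3]]))
    if (any(grepl("[^ACGT]", codons)) || any(codons %in% STOP_CODONS)) next
    for (p in 1:3) {
      use[j[p]] <- classes[j[p]] == "synonymous_variable" ||
        (classes[j[p]] == "monomorphic" &&
           all(vapply(codons, fourfold_degenerate, TRUE, pos = p)))
    }
  }
  if (!any(use)) stop("no synonymous sites available for divergence")
  cons <- strsplit(consensus_sequence(aln), "")[[1]]
  outg <- strsplit(aln$outgroup_seq, "")[[1]]
  ok <- use & cons %in% c("A", "C", "G", "T") & outg %in% c("A", "C", "G", "T")
  sum(cons[ok] != outg[ok]) / sum(ok)
}

#' Calibrate the per-generation mutation rate
#'
#' Converts synonymous divergence to an outgroup into a per-site,
#' per-generation mutation rate, assuming divergence along both lineages:
#' `mu = d / (2 * t / g)` with split time `t` in years and generation
#' time `g` in years.
#'
#' @param syn_divergence Substitutions per synonymous site.
#' @param divergence_time_years Split time to the outgroup, years.
#' @param generation_time_years Generation time, years.
#' @return An object of class `mutation_rate` with fields `mu`,
#'   `divergence_time_years`, `generation_time_years`.
#' @export
calibrate_mu <- function(syn_divergence, divergence_time_years = 65e6,
                         generation_time_years = 1) {
  if (syn_divergence <= 0 || divergence_time_years <= 0 ||
      generation_time_years <= 0) {
    stop("all calibration inputs must be positive")
  }
  mu <- syn_divergence / (2 * divergence_time_years / generation_time_years)
  mutation_rate(mu, divergence_time_years, generation_time_years)
}

#' @rdname calibrate_mu
#' @param mu Substitutions per site per generation.
#' @export
mutation_rate <- function(mu, divergence_time_years = 65e6,
                          generation_time_years = 1) {
  if (mu <= 0) stop("mu must be positive")
  structure(list(mu = mu,
                 divergence_time_years = divergence_time_years,
                 generation_time_years = generation_time_years),
            class = "mutation_rate")
}

#' Per-locus mutation-rate scalars
#'
#' Relative rates from per-locus synonymous divergences, normalised to
#' mean 1 so the per-site theta keeps its across-locus average meaning.
#'
#' @param divergences Numeric vector of per-locus synonymous divergences,
#'   optionally named by locus.
#' @return A tibble with columns `locus_name`, `syn_divergence`, `scalar`.
#' @export
locus_scalars <- function(divergences) {
  if (any(divergences <= 0)) stop("all divergences must be positive")
  nms <- names(divergences)
  if (is.null(nms)) nms <- paste0("locus_", seq_along(divergences))
  tibble::tibble(locus_name = nms,
                 syn_divergence = unname(divergences),
                 scalar = unname(divergences) / mean(divergences))
}
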
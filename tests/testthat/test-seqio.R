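test_that("FASTA round-trip preserves sequences, labels and outgroup", {
  map <- micro_map(c("W01", "E01"), c("west", "east"))
  aln <- micro_alignment(
    c(W01_a1 = "ATGGGCAAAGGGTCATCGTCAGGGATCGAT",
      W01_a2 = "ATGGGCAAAGGGTCATCGTCAGGGATCGAC",
      E01_a1 = "ATGGGCAAAGGGTCTTCGTCAGGGATCGAT",
      E01_a2 = "ATGGGCAAAGGGTCATCGTCAGGGATCGAT"),
    outgroup = "ATGGGCAAAGGGTCATCGTCAGGTATCGAT")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_locus_fasta(aln, path)
  back <- read_locus_fasta(path, map, locus_name = "micro")
  expect_equal(back$alleles$sequence, aln$alleles$sequence)
  expect_equal(back$alleles$sample_id, aln$alleles$sample_id)
  expect_equal(as.character(back$alleles$population),
               as.character(aln$alleles$population))
  expect_identical(back$outgroup_seq, aln$outgroup_seq)
  expect_equal(back$length, 30)
  expect_equal(nrow(back$alleles), 4)
})

test_that("malformed FASTA input is rejected with the offender named", {
  map <- micro_map()
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">W01_a1", "ACGTACGTA", ">W01_a2", "ACGTACG"), path)
  expect_error(read_locus_fasta(path, map), "W01_a2")

  path2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">W01_a1", "ACGTACGTA", ">UNKNOWN_a1", "ACGTACGTA"), path2)
  expect_error(read_locus_fasta(path2, map), "UNKNOWN")
})

test_that("an OUTGROUP record populates outgroup_seq and is not an allele", {
  map <- micro_map(c("W01"), c("west"))
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">W01_a1", "ACGTAC", ">W01_a2", "ACGTAC",
               ">OUTGROUP", "ACGTAT"), path)
  aln <- read_locus_fasta(path, map)
  expect_equal(nrow(aln$alleles), 2)
  expect_identical(aln$outgroup_seq, "ACGTAT")
})

test_that("reading frame minimises stop codons with low-offset tie-break", {
  # TAATAATAA: offsets have 3, 0, 0 stops; tie between 1 and 2 -> 1
  expect_identical(infer_reading_frame("TAATAATAA"), 1L)
  expect_identical(count_stop_codons("TAATAATAA", 0), 3L)
  expect_identical(count_stop_codons("TAATAATAA", 1), 0L)
  # no stops anywhere: tie across all three -> 0
  expect_identical(infer_reading_frame("ATGGGCAAA"), 0L)
  # gaps are removed before codon reading
  expect_identical(infer_reading_frame("TA-ATAATA-A"), 1L)
  expect_error(infer_reading_frame("---"), "all gaps")
})

test_that("inferred frame is the global minimiser over all three offsets", {
  set.seed(42)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    counts <- vapply(0:2, function(off) {
      n_cod <- (nchar(s) - off) %/% 3
      starts <- off + 1 + 3 * (seq_len(n_cod) - 1)
      sum(substring(s, starts, starts + 2) %in% c("TAA", "TAG", "TGA"))
    }, 1L)
    expect_identical(infer_reading_frame(s),
                     as.integer(which.min(counts) - 1L))
  }
})

test_that("synonymous classification follows observed whole-codon variants", {
  # third codon position of Gly (GGA/GGG): synonymous
  aln <- micro_alignment(c(W01_a1 = "GGA", W01_a2 = "GGG",
                           E01_a1 = "GGA", E01_a2 = "GGA"),
                         frame_offset = 0L)
  cls <- classify_synonymous_sites(aln)
  expect_equal(cls$class, c("monomorphic", "monomorphic", "synonymous_variable"))

  # GGA (Gly) vs AGA (Arg): nonsynonymous at the variable first position
  aln2 <- micro_alignment(c(W01_a1 = "GGA", W01_a2 = "AGA",
                            E01_a1 = "GGA", E01_a2 = "GGA"),
                          frame_offset = 0L)
  expect_equal(classify_synonymous_sites(aln2)$class,
               c("nonsynonymous_variable", "monomorphic", "monomorphic"))

  # a gap in any codon variant excludes the whole codon
  aln3 <- micro_alignment(c(W01_a1 = "GGA", W01_a2 = "GG-",
                            E01_a1 = "GGA", E01_a2 = "GGA"),
                          frame_offset = 0L)
  expect_equal(classify_synonymous_sites(aln3)$class, rep("excluded", 3))

  # untrimmed alignment is a precondition error
  aln4 <- micro_alignment(c(W01_a1 = "GGAA", W01_a2 = "GGAA",
                            E01_a1 = "GGAA", E01_a2 = "GGAA"),
                          frame_offset = 0L)
  expect_error(classify_synonymous_sites(aln4), "not trimmed")
})

test_that("site classes partition the alignment and ignore allele order", {
  set.seed(7)
  ds <- generate_dataset(study_design(n_loci = 1, n_west = 6, n_east = 6,
                                      rng_seed = 7))
  aln <- ds$alns[[1]]
  cls <- classify_synonymous_sites(aln)
  expect_equal(nrow(cls), aln$length)
  expect_true(all(cls$class %in% c("synonymous_variable",
                                   "nonsynonymous_variable",
                                   "monomorphic", "excluded")))
  shuffled <- aln
  perm <- sample(nrow(aln$alleles))
  shuffled$alleles <- shuffled$alleles[perm, ]
  expect_equal(classify_synonymous_sites(shuffled)$class, cls$class)
})

test_that("trim_to_frame yields whole codons starting at position one", {
  aln <- micro_alignment(c(W01_a1 = "TGGAGGAA"), frame_offset = 1L)
  trimmed <- trim_to_frame(aln)
  expect_equal(trimmed$length, 6)
  expect_identical(trimmed$frame_offset, 0L)
  expect_equal(trimmed$alleles$sequence, "GGAGGA")
})

test_that("mutation-rate calibration matches hand arithmetic", {
  expect_equal(calibrate_mu(0.34970, 6.5e7, 1)$mu, 2.69e-9, tolerance = 1e-6)
  expect_equal(calibrate_mu(0.13, 6.5e7, 1)$mu, 1.0e-9)
  expect_error(calibrate_mu(0, 6.5e7, 1), "positive")
  expect_error(calibrate_mu(0.1, -1, 1), "positive")
})

test_that("locus scalars are divergences over their mean, normalised to 1", {
  sc <- locus_scalars(c(0.2, 0.4))
  expect_equal(sc$scalar, c(2 / 3, 4 / 3), tolerance = 1e-9)
  expect_equal(locus_scalars(c(0.3, 0.3, 0.3))$scalar, rep(1, 3))
  set.seed(11)
  d <- stats::runif(13, 0.1, 0.6)
  expect_equal(mean(locus_scalars(d)$scalar), 1, tolerance = 1e-12)
  expect_error(locus_scalars(c(0.2, 0)), "positive")
})
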
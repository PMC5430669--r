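# Shared fixture builders; all data are generated in code.

# tiny population map for hand-built alignments
micro_map <- function(samples = c("W01", "E01"),
                      population = c("west", "east")) {
  tibble::tibble(sample_id = samples, species = "gilli",
                 population = factor(population, levels = c("west", "east")),
                 year = 2013L)
}

# alignment from named sequences: names are allele ids sampleID_a1/_a2
micro_alignment <- function(seqs, outgroup = NA_character_,
                            frame_offset = NA_integer_,
                            locus_name = "micro") {
  sample_id <- sub("_a[12]$", "", names(seqs))
  population <- factor(ifelse(grepl("^W", sample_id), "west", "east"),
                       levels = c("west", "east"))
  locus_alignment(
    locus_name,
    tibble::tibble(allele_id = names(seqs), sample_id = sample_id,
                   population = population, sequence = unname(seqs)),
    outgroup_seq = outgroup, frame_offset = frame_offset)
}

mu_study <- function() mutation_rate(2.69e-9, 65e6, 1)

# small panmictic setup used by several simulator checks
panmictic_params <- function(theta = 1) model_params("isolation", theta, 0)

# number of segregating sites of one simulated locus
sim_n_sites <- function(params, spec, mu) {
  nrow(drop_mutations(simulate_genealogy(params, spec, mu), spec, params))
}

theta_axis_study <- function() {
  unique(c(seq(0.001, 0.01, by = 0.001), seq(0.01, 0.1, by = 0.01)))
}
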
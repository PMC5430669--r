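# gilliflow

Coalescent demographic inference for two diverged frog populations from
multi-locus phased exon sequences.

## The problem

The endangered Cape platanna (*Xenopus gilli*) persists in two small
populations east and west of False Bay, South Africa, that share nuclear
alleles despite deep mitochondrial divergence. Shared alleles can arise
from retained ancestral polymorphism (incomplete lineage sorting) or
from gene flow, and distinguishing the two matters for whether the
populations should be managed as one unit or two. `gilliflow`
implements the inference pipeline that makes this distinction from a
modest Sanger-style dataset: phased alleles of ~13 nuclear exons
(333–770 bp) sampled from both populations, polarised against a
*X. tropicalis* outgroup.

## The method

Three demographic models are compared, all with an ancestral population
of polymorphism parameter θ = 4Nμ (per site) splitting `T` generations
ago into west and east demes of the same size:

- **isolation** — no migration after the split (shared alleles are pure
  incomplete lineage sorting);
- **ongoing migration** — symmetric migration at `m` migrants per
  generation ever since the split;
- **secondary contact** — migration only during the most recent
  fraction τ of the time since the split.

Isolation (m = 0) and ongoing migration (τ = 1) are boundary special
cases of secondary contact.

Data enter through four Wakeley–Hey summary statistics computed at
synonymous sites and summed across loci: counts of sites with a derived
polymorphism private to the west, private to the east, shared between
the populations, and fixed between them. The likelihood of each grid
point (over the study grid of θ, T, m, τ) is approximated by rejection
sampling:

    lnL(θ, T, m, τ) ≈ ln( #{simulations within ±ε% of the observed statistics} / n_sims )

with ε = 25 and 40,000 simulations per point (defaults). Simulations
use a structured coalescent with infinite-sites mutation, per-locus
mutation-rate scalars from synonymous divergence to the outgroup, and a
mutation rate calibrated on the 65-My outgroup split
(μ = d_syn / (2 T_div / g)). When no simulation is accepted the
likelihood is bounded above by ln(1/n_sims). Profile 95% CIs are the
axis values within 1.92 lnL units of the maximum; nested models are
compared with a boundary-corrected likelihood-ratio test, where
2ΔlnL follows the mixture ½χ²₀ + ½χ²₁ because the nested parameter
sits on its boundary.

The package also provides per-population diversity statistics:
nucleotide diversity π with length-weighted bootstrap CIs, rarefied
allelic richness (hypergeometric expectation at a fixed subsample
depth), and Hudson-style pairwise F_ST with an individual-level
permutation test — plus a synthetic-data generator that produces
study-like datasets with known truth.

## Worked example

Simulate a study-like dataset at the ongoing-migration maximum-likelihood
parameters (θ = 0.002, m = 0.7, T = 8.5e6), then re-estimate θ along
the study grid:

```r
library(gilliflow)

design <- study_design(n_loci = 13, rng_seed = 7)   # truth: theta 0.002, m 0.7, T 8.5e6
td <- file.path(tempdir(), "demo")
generate_dataset(design, td)

ds   <- read_dataset(td)
alns <- lapply(ds$alns, function(a) trim_to_frame(set_reading_frame(a)))
(obs <- wakeley_hey(alns))
#> # A tibble: 1 x 4
#>   private_west private_east shared fixed
#>          <int>        <int>  <int> <int>
#> 1            7           12     24     0

div <- vapply(alns, synonymous_divergence, 1)
mu  <- calibrate_mu(mean(div))                      # 2.76e-09 subs/site/gen
specs <- locus_spec(vapply(alns, function(a) a$locus_name, ""),
                    vapply(alns, count_synonymous_sites, 1L),
                    locus_scalars(div)$scalar,
                    vapply(alns, function(a) sum(a$alleles$population == "west"), 1L),
                    vapply(alns, function(a) sum(a$alleles$population == "east"), 1L))

surf <- grid_search(obs, "ongoing_migration",
                    grid_spec("ongoing_migration", T_gen = 8.5e6, m = 0.7),
                    specs, mu,
                    rejection_config(epsilon_pct = 25, n_sims = 2000, rng_seed = 7))
glance(surf)
#> # A tibble: 1 x 8
#>   model             n_points max_lnL theta   T_gen     m   tau is_bound
#> 1 ongoing_migration       19   -2.49 0.002 8500000   0.7     1 FALSE
profile_ci(surf, "theta")
#> # A tibble: 1 x 6
#>   axis    mle   low  high censored_low censored_high
#> 1 theta 0.002 0.002 0.002 FALSE        FALSE
```

The sampler recovers the generating θ = 0.002 exactly, with a tight
profile interval. The boundary-mixture test on two maximised
log-likelihoods:

```r
boundary_lrt(-8.032, -8.987)
#>   statistic = 1.91, p_value = 0.0835   # the full model is not supported
```

Diversity statistics for the same dataset:

```r
diversity_tables(alns, n_boot = 1000, rng_seed = 7)$summary
#>   population statistic          point    ci_low  ci_high
#>   west       pi               0.00123  0.000641 0.00197
#>   west       allelic_richness 2.69     2.08     3.38
#>   east       pi               0.00125  0.000741 0.00185
#>   east       allelic_richness 2.75     2.03     3.37
pairwise_fst(alns, n_perms = 999, rng_seed = 7)
#>   pop_pair     fst    p_value
#>   west_vs_east 0.216  0.001   # the two demes are clearly differentiated
```

A thin command-line wrapper over the same pipeline lives at
`inst/scripts/demog_pipeline.R` with subcommands `simulate`, `fit`,
`diversity`.

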
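---
title: "Rejection-sampling demographic inference for two diverged populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rejection-sampling demographic inference for two diverged populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gilliflow)
```

## The model

`gilliflow` asks whether nuclear alleles shared between two diverged
populations reflect retained ancestral polymorphism (incomplete lineage
sorting) or gene flow. Three nested demographic hypotheses are
compared. In all of them an ancestral population splits `T` generations
ago into a west and an east deme; the per-site polymorphism parameter
θ = 4Nμ is assumed equal in the ancestral and both descendant
populations. Under **isolation** no migration follows the split. Under
**ongoing migration** the demes exchange `m` migrant individuals per
generation, symmetrically, ever since the split. Under **secondary
contact** migration is restricted to the most recent fraction τ of the
time since the split. Setting τ = 1 recovers ongoing migration and
additionally m = 0 recovers isolation, so the models are nested with
the nested parameter on a boundary — which drives the choice of test
below.

### Coalescent scaling

Internally, time is measured in units in which one pair of lineages
within a deme coalesces at rate 1, so `T_coal = T / (4 N_e)` with
`N_e = θ / (4μ)`, lineages migrate at rate `M/2` while migration is
active, and infinite-sites mutations fall at rate `θ_locus / 2` per
lineage per time unit with `θ_locus = θ · scalar · L_syn`. Under this
convention the expected pairwise diversity per site within a deme is θ
and the expected number of segregating sites follows Watterson's
formula — both are verified by Monte-Carlo tests, and the whole
simulator is additionally cross-validated distributionally against
msprime configured to the same scaled rates.

### The migration-rate convention

The printed units of the migration estimate ("individuals per
generation") identify `m` with Wright's `Nm`, so the scaled coalescent
rate is `M = 4m`. A verbal definition of `m` that divides by `4N`
appears in some descriptions of this class of models and is
inconsistent with those units; we follow the units. The alternative
(`M = m`) is available through `migration_convention = "direct"` in
`coalescent_scaling()` and `rejection_config()` for sensitivity
analysis.

## From sequences to summary statistics

Each locus is a phased alignment (two alleles per diploid) with an
outgroup sequence. The reading frame is inferred by minimising stop
codons over the three offsets (ties to the smallest offset; all
complete codons counted, since the exons are internal fragments), and
the alignment is trimmed to whole codons. A variable site is
*synonymous* only if every observed codon variant in its codon column —
ingroup plus outgroup — translates to the same amino acid; codons
containing `N`, a gap, or a stop exclude all three of their sites. This
whole-codon rule is deliberately conservative and independent of allele
order: a codon with mixed synonymous and nonsynonymous changes is
counted as nonsynonymous.

Polarising each synonymous variable site against the outgroup base
yields the four Wakeley–Hey counts: derived polymorphisms private to
the west, private to the east, shared, or fixed between the
populations. Sites with more than two states (given the ancestral) are
unpolarisable under infinite sites and are excluded; a site where both
populations are fixed for the same derived base carries no information
about their divergence and counts as monomorphic.

The per-locus mutation target for simulations is the number of
*available* synonymous sites: synonymous variable sites plus
monomorphic sites that are fourfold degenerate in every observed codon.
This is a conservative count (twofold-degenerate positions are not
fractionally counted); it is exactly consistent with the synthetic-data
generator, which places all variation at fourfold third positions, and
for real data it errs toward slightly underestimating θ rather than
overestimating it.

Rate heterogeneity across loci is absorbed by scalars
`d_i / mean(d)` from per-locus synonymous divergence to the outgroup
(raw p-distance between the ingroup majority consensus and the
outgroup; the consensus avoids an arbitrary choice of reference
allele). Scalars are normalised to mean 1 so θ keeps its per-site,
across-locus average meaning. The overall rate is calibrated as
`μ = mean(d) / (2 · T_div / g)` with a 65-My outgroup split and a
one-year generation time by default.

## Rejection-sampling likelihood

At each point of the parameter grid, `n_sims` multi-locus datasets are
simulated and the approximate log-likelihood is
`ln(accepted / n_sims)`, where a simulation is accepted when its four
across-locus sums all lie within ±ε% of the observed sums
(`epsilon_pct = 25` by default). The published description of the rule
is grammatically ambiguous between this per-component reading and a
single grand total; per-component retains more information and is the
default, with `acceptance_mode = "total_sum"` provided for sensitivity
analysis. An observed component of zero makes the per-component rule
degenerate (the simulated component must be zero); this is common for
the `fixed` component under migration and is reported with a warning
rather than an error.

When nothing is accepted, `ln(1/n_sims)` is an upper bound for the
likelihood and is flagged as such (`is_bound`); running a larger
`n_sims` (the study used 1,000,000 for the isolation model) tightens
the bound.

The default grid is the study grid: `T` every 1e6 generations in
[0, 2e7] (21 values, T = 0 collapsing to panmixia), θ every 0.001 in
[0.001, 0.01] and every 0.01 in [0.01, 0.1] (19 unique values after
de-duplicating 0.01), τ every 10% in [10%, 100%], and m every 0.1 in
[0, 1] plus every integer in [1, 10] (20 unique values). Each grid
point derives a child seed deterministically from the master seed and
its parameter values, so a nested model's optimum lies inside the
larger model's grid *with the same simulation stream* — making the
likelihood ordering of nested models exact rather than only expected,
and making every surface bit-reproducible.

Profile 95% confidence intervals take, along one axis, the outermost
values whose profiled log-likelihood is within 1.92 units of the
maximum; intervals touching the grid boundary are flagged censored
rather than silently truncated.

### Model comparison at a boundary

Because the nested parameter sits on its boundary (τ = 1, or m = 0),
twice the log-likelihood difference follows the mixture
½χ²₀ + ½χ²₁ rather than χ²₁: `p = ½·P(χ²₁ ≥ 2ΔlnL)` for a positive
statistic and `p = 1` otherwise. Monte-Carlo noise can make the
statistic negative; it is reported as computed with `p = 1`. When the
nested log-likelihood is itself a zero-acceptance bound, the true
statistic can only be larger, so the reported p-value is an upper bound
and is flagged. The half-half weights are exact for one boundary
parameter; other `df_diff` values are accepted with a warning.

## Diversity statistics

Per-locus nucleotide diversity is the mean pairwise difference per
comparable site (pairwise deletion of gaps/ambiguity), computed through
`ape::dist.dna`. The across-locus summary weights loci by gene length
and bootstraps loci — not sites — 5,000 times by default, matching the
level at which the values are exchangeable. Rarefied allelic richness
uses the exact hypergeometric expectation
`Σ_i [1 − C(N−N_i, g)/C(N, g)]`; the default depth `g` is the smallest
number of sampled alleles over populations and loci (8 in the study
design; 4 when the sparsest locus is retained), and the implementation
is verified against exhaustive subsample enumeration and
`vegan::rarefy`. F_ST is Hudson's `1 − H_w/H_b` from haplotype
sequences pooled across loci — chosen over an AMOVA formulation because
it has a transparent pair-enumeration oracle; published AMOVA-based
F_ST values are therefore not directly comparable and are not asserted
anywhere. Its permutation test permutes individuals (both phased
alleles together), preserving within-individual structure, with
`p = (#{F* ≥ F} + 1)/(n_perms + 1)`.

## The synthetic-data generator

`generate_dataset()` produces datasets with the study's shape: 13 loci
of 333–770 bp, 22 west and 26 east phased alleles (11/13 diploids),
lognormal rate scalars re-normalised to mean 1 (sdlog 0.3 — a moderate,
realistic spread for exon loci), true parameters defaulting to the
reported ongoing-migration MLEs. Every locus is a backbone of codons
whose third positions are fourfold degenerate; simulated derived
alleles occupy distinct third positions, and outgroup divergence
(Poisson, mean `2 μ T_div scalar` per synonymous site) occupies third
positions not carrying polymorphism. Consequently frame inference,
synonymous classification and outgroup polarisation recover the
simulated Wakeley–Hey counts *exactly*, which the tests assert over
dozens of random designs — a lossless round trip that isolates any
failure to either the simulator or the filter, never their
interaction.

What the generator does *not* emulate: sequencing or phasing error,
recombination within exons, gaps and missing data, selection, unequal
deme sizes, and the temporal (1994 vs 2013) sampling structure. Tests
passing on synthetic data therefore validate the machinery under the
stated model, not robustness to these real-data complications.

A `generate_null_pair()` variant sets `T = 0` (one panmictic deme,
arbitrary labels) and is used to verify that F_ST centres on zero and
permutation p-values are uniform under the null.

## Numerical and design choices

- Genealogy simulation and the batched Wakeley–Hey counting are
  compiled C++ (single event-driven pass per genealogy; per-branch
  Poisson mutation counts per class, which is distributionally
  identical to placing each mutation on a branch chosen by length).
  They consume R's RNG, so `set.seed()` governs everything.
- Ties in the grid argmax are broken by first-in-grid order and the
  winning row is reported as such.
- `lchoose` is used in the rarefaction formula so depths near `N`
  neither overflow nor lose precision.
- Problem sizes in the tests are desk-scale by design: Monte-Carlo
  checks use 1,500–4,000 replicates against 3-standard-error bands;
  the θ-recovery experiment uses 10 replicate datasets and 2,000
  simulations per grid point along the 19-value θ axis, which recovers
  the generating θ = 0.002 exactly in every replicate while running in
  about a minute.
- The exported surface, MLE, CI, comparison and diversity artifacts are
  plain TSV; datasets are plain FASTA/TSV/JSON. Every artifact records
  the master seed.

## Known limitations

- The rejection likelihood is a grid approximation; between-grid maxima
  (the study's own T estimate falls between grid values) are not
  searched.
- The per-component acceptance rule with a zero observed component is
  stricter than a tolerance band; with very sparse data several
  components can be zero and the surface degenerates accordingly.
- Hudson's F_ST and the conservative synonymous-site count are
  deliberate simplifications documented above; both are internally
  consistent but not numerically interchangeable with AMOVA F_ST or
  fractional degeneracy counts.
- p-distances are used for synonymous divergence without a
  multiple-hit correction; at ~35% divergence this underestimates the
  true rate for all loci roughly proportionally, which cancels in the
  scalars but biases μ slightly downward.
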
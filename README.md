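# eboxscape

Dissecting the DNA-binding specificity of E-box-binding bHLHZ dimers —
MYC:MAX and MAX:MAX — from three complementary angles:

1. **In vitro, array scale.** A custom protein-binding microarray (PBM)
   enumerating all 4096 core hexamers (`tgaNNNNNNgta`), 128 flank
   variants of the canonical E-box core, 518 core mutants and 100
   random null probes. Scores are `log2(median triplicate / array
   median)`; binding calls use empirical quantiles (95% / 80%) of the
   random-probe null; motifs are ranked by best probe score in a
   canonical orientation and summarized as position weight matrices.
2. **In vivo, genome scale.** Exact hexamer scanning on both strands,
   ChIP-seq summits (`apex ± 100 bp`), top-33% and fold-enrichment
   strata, genome-normalized motif frequency
   (`hits in regions / hits in genome`), CME/NE co-occurrence Venn
   partitions, promoter (±2 kb of TSS) / intragenic / intergenic
   annotation, and high-vs-low protein-dose fold changes.
3. **In vitro, single-site scale.** Competition EMSAs modeled with a
   full mass-balance two-ligand equilibrium,
   `p + pL/(K_L+p) + pC/(K_C+p) = P_tot`, fitted by joint least
   squares with the self-competition curve anchoring `K_L`; relative
   affinities are reported as `K_ref/K_C` with the non-E-box AACGTT
   set to 1 and classed High / Medium / Low / non-binding.

A synthetic-data layer (`gen_genome`, `plant_sites`, `gen_gene_models`,
`gen_peaks`, `gen_pbm_intensities`, `gen_competition_curves`) generates
every input with known ground truth — tiered site affinities, a
mass-action dose model `θ = c/(c+Kd)`, lognormal array noise, Gaussian
percent-scale EMSA noise — so the whole pipeline is testable end to
end. See `vignettes/eboxscape-methods.Rmd` for the models, defaults and
their rationale.

## Worked example

```r
library(eboxscape)

lib    <- build_probe_library(seed = 1)          # 4842 probes
scores <- normalize_array(gen_pbm_intensities(lib, noise_cv = 0.2, seed = 2))
thr    <- null_threshold(scores, "MYCMAX", 0.95) # empirical null, q = 0.95
ranked <- rank_motifs(bound_probes(scores, "MYCMAX", thr), lib)
head(ranked, 3)
#>    motif rank best_score n_probes                   class
#> 1 CACGTG    1   8.900557      148                   E-box
#> 2 ACGTGA    2   8.001698        2 E-box-variant/non-E-box
#> 3 CTCCAC    3   7.953278        1 E-box-variant/non-E-box
```

The canonical E-box tops the ranking; `high_confidence_motifs(scores,
lib)` returns the motifs bound by *both* dimers above the permissive
80% null, which includes the low-affinity non-E-box palindrome
`AACGTT`. A full synthetic run —

```r
res <- run_pipeline(analysis_config(seed = 1), "synthetic", "out/")
res$fold_change$count
#>    motif high low fold_change
#> 1 CACGTG   73  64    1.140625
#> 2 AACGTT   94  10    9.400000
res$coverage
#> [1] 0.8934426
```

— reproduces the qualitative in-vivo picture: raising the protein dose
multiplies the number of occupied low-affinity AACGTT summits ~9-fold
while canonical-site occupancy barely moves, and ~89% of summits carry
at least one of the top-21 in-vitro motifs.

## Command line

```sh
Rscript inst/cli/eboxscape simulate-all --out out/ --seed 1
Rscript inst/cli/eboxscape scan --genome out/genome.fa \
        --motifs CACGTG,AACGTT --out hits.tsv
```

Subcommands: `simulate-all`, `design`, `score-pbm`, `scan`, `enrich`,
`venn`, `annotate`, `compare-conditions`, `coverage`, `emsa-fit`; see
`?ebox_cli`.
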
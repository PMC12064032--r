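# tilemave

Analysis of **tiled, dual-assay deep mutational scans**: experiments that
measure, for every single amino-acid substitution in a protein domain, both
the variant's *cellular abundance* (via a DHFR protein-fragment
complementation growth selection) and its *protein–protein interaction* (via
yeast two-hybrid selection), read out by paired-end amplicon sequencing of
tiled site-saturation libraries before and after selection.

The package is written for analysts of multiplexed assays of variant effects
(MAVEs) who need a tested, reproducible path from raw paired-end reads (or
pre-tabulated counts) to normalised variant-effect scores, per-position
summaries, structural context, and clinical benchmarking. The canonical
configuration is a 270-residue C-terminal domain scanned in seven tiles
(positions 487–756; 19 × 270 + 40 = 5170 programmed variants), the design
used to dissect stability versus partner binding in the DNA mismatch-repair
protein MLH1.

## What it computes

For variant *v*, replicate *r*, with control/selection counts *c* and the
tile's pooled synonymous-wild-type reference counts *R*:

```
s_vr = ln((c_sel + ε)/(c_ctrl + ε)) − ln((R_sel + ε)/(R_ctrl + ε)),   ε = 0.5
se_vr = sqrt(1/(c_sel+ε) + 1/(c_ctrl+ε) + 1/(R_sel+ε) + 1/(R_ctrl+ε))
```

Replicates are combined by DerSimonian–Laird random-effects pooling
(method-of-moments τ²). Bimodal abundance scores are rescaled per tile by
the KDE-detected location of the low-abundance mode, mapping the
destabilised peak to −1 and wild-type to 0; unimodal interaction scores
pass through unrescaled. Downstream: per-position medians, 21 × L heatmap
matrices, Shrake–Rupley relative solvent accessibility and 6 Å interface
contacts from a structure model, and Mann–Whitney ROC/AUC against clinical
classifications and ΔΔG / ΔΔE predictor tables.

The package also contains a first-class synthetic-data generator
(`draw_effects()`, `simulate_counts()`, `emit_fastq()`) that emulates the
screen's statistical structure — bimodal abundance truths with tile-specific
low modes, a sharp interaction core with sparse loss/gain tails, growth
selection, and 151 nt paired-end reads — so every stage is testable offline.

## Worked example

```r
library(tilemave)

tiles  <- default_tiles()                 # 7 tiles over positions 487-756
lib    <- design_library(tiles)           # 5170 variants + 270 Syn markers
params <- sim_params(depth = 200, seed = 42)
truths <- draw_effects(lib, params)       # ground-truth effects
counts <- simulate_counts(truths, params) # selection-driven count tables
scores <- score_dataset(counts, library = lib)
rescaled <- rescale_scores(scores, assay = "abundance")

round(attr(rescaled, "rescale_report"), 3)
#>      1      2      3      4      5      6      7
#> -3.677 -5.166 -4.639 -5.520 -3.815 -5.195 -4.361
```

These are the per-tile raw-score locations of the low-abundance peak; each
tile's scores and standard errors are divided by the absolute value, so −1
now means "as depleted as the destabilised mode" in every tile.

```r
head(subset(rescaled, assay == "abundance" & alt_aa != "Syn",
            select = c(position, wt_aa, alt_aa, score, se, tau2)), 5)
#>   position wt_aa alt_aa      score         se      tau2
#> 1      487     V      A -1.0732971 0.10019370 0.2399306
#> 2      487     V      C -1.0412980 0.11316179 0.3197370
#> 3      487     V      D -1.0018182 0.10994353 0.2969319
#> 4      487     V      E  0.1190681 0.01291906 0.0000000
#> 5      487     V      F  0.1077995 0.01320415 0.0000000
```

V487A/C/D are destabilised (scores ≈ −1, with non-zero between-replicate
variance τ² because low counts make replicates noisy); V487E/F are
wild-type-like.

```r
replicate_qc(rescaled)$abundance$min_r
#> [1] 0.964

classify_mechanism(c(-1.1, 0.02), c(-0.9, 0.45))
#> [1] "dual-loss"           "gain-of-interaction"
```

From real data you would start instead at `count_variants()` (paired FASTQ →
counts, with the stated trimming/overlap/mismatch rules) or feed your own
count TSV to `score_dataset()`; `pathogenicity_benchmark()` joins scores
with ClinVar-style annotations and ΔΔG/ΔΔE tables (Rosetta Energy Units are
divided by 2.9 into kcal/mol on read) and reports Mann–Whitney AUCs with
VUS excluded. An end-to-end runner (`run_pipeline()` with a YAML config, or
`inst/scripts/tilemave-run.R` from a shell) wires all stages with one master
seed and writes a manifest.

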
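---
title: "Scoring tiled dual-assay deep mutational scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring tiled dual-assay deep mutational scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilemave)
```

## The experiment this package models

A site-saturation variant library of a protein domain is divided into
contiguous *tiles*, each sequenced as one paired-end amplicon. Every library
member carries a single amino-acid substitution (or a synonymous wild-type
marker codon, or — in the last tile — a stop codon), and the library is passed
through two growth selections: one coupling yeast growth to the *cellular
abundance* of the protein (a DHFR protein-fragment complementation assay) and
one coupling growth to its *interaction* with a partner protein (yeast
two-hybrid). Sequencing the library before (control) and after (selection)
growth, in three replicates, turns each variant's fitness under selection into
a change in read frequency.

The canonical use case is the C-terminal domain of the DNA mismatch-repair
protein MLH1 (positions 487–756 in full-length numbering), whose heterodimer
partner is PMS2: seven tiles of 40, 42, 28, 40, 40, 40 and 40 residues, with
nonsense mutations programmed only in the last tile. The programmed library is

\[ 19 \times 270 + 40 = 5170 \]

non-synonymous variants plus one synonymous marker per position.

## Enrichment scores

For variant $v$ in one replicate $r$, with control and selection counts
$c_{v}^{ctrl}, c_{v}^{sel}$ and the tile's pooled neutral-reference counts
$R^{ctrl}, R^{sel}$ (all synonymous markers plus exact wild-type reads), the
score is the normalised log-ratio

\[ s_{v,r} = \ln\frac{c_v^{sel}+\varepsilon}{c_v^{ctrl}+\varepsilon}
          - \ln\frac{R^{sel}+\varepsilon}{R^{ctrl}+\varepsilon},
\qquad
\mathrm{se}_{v,r} = \sqrt{\tfrac{1}{c_v^{sel}+\varepsilon}
 + \tfrac{1}{c_v^{ctrl}+\varepsilon} + \tfrac{1}{R^{sel}+\varepsilon}
 + \tfrac{1}{R^{ctrl}+\varepsilon}} \]

with pseudocount $\varepsilon = 0.5$, the convention of Enrich2-style
scorers; 0 is wild-type-like, negative is depletion under selection. Pooling
all synonymous markers (rather than only exact wild-type reads) is the
default because a per-position marker exists throughout the library and the
pooled reference is far deeper than any single tally; `scoring_config()`
exposes the exact-wild-type alternative.

Replicates are combined by DerSimonian–Laird random-effects pooling: with
fixed-effect weights $w_r = 1/\mathrm{se}_r^2$, heterogeneity
$Q = \sum_r w_r (s_r - \bar s)^2$ and

\[ \tau^2 = \max\!\left(0,\;
 \frac{Q - (k-1)}{\sum w_r - \sum w_r^2 / \sum w_r}\right), \]

the combined score reweights by $1/(\mathrm{se}_r^2 + \tau^2)$. The
between-replicate variance $\tau^2$ absorbs plate-to-plate differences in
selection strength, which a fixed-effect average would understate. The unit
tests check this estimator at $10^{-12}$ against both a from-the-definition
implementation and `metafor`.

## Per-tile rescaling of the bimodal abundance scores

Abundance scores are bimodal: a wild-type-like mode at 0 and a destabilised
("low-abundance") mode whose location varies between tiles because each tile
is its own amplicon and selection plate. To put tiles on a common scale,
`detect_low_mode()` finds each tile's low mode as the highest-density local
maximum of a Gaussian KDE (Silverman bandwidth) below a guard threshold of
−0.25, and `rescale_scores()` divides all scores and standard errors of the
tile by its absolute value. This maps the destabilised mode to −1 and leaves
wild-type at 0; values outside $[-1, 0]$ are deliberately *not* clamped
(scores above 0 mean increased abundance). The guard threshold prevents the
wild-type mode itself from being mistaken for a low mode in nearly-unimodal
tiles; tiles with no maximum below the guard fall back to the pooled global
mode, with a warning. Interaction scores are sharply unimodal and pass
through unrescaled.

Per-position summaries are medians over missense substitutions (nonsense
excluded by default — truncations report on a different mechanism than
substitutions, and their inclusion is a flag). Heatmap matrices use a fixed
physicochemical row order with the `Ter` row last, and a mask distinguishing
wild-type cells from missing variants.

## The synthetic-data generator

Every downstream stage is testable without any external download because the
generator emulates the statistical structure of the real screen:

* **Abundance truth**: a two-component mixture — wild-type-like
  $N(0, 0.2)$ with weight 0.6, and a destabilised component
  $N(m_t, 0.15)$ with weight `frac_low = 0.4`, where the per-tile mode
  $m_t$ is drawn once per run uniformly in $[-3.5, -1.5]$ to reproduce the
  tile-to-tile variation of the low-abundance peak.
* **Interaction truth**: a sharp unimodal core $N(0, 0.2)$, a
  loss-of-interaction tail at $N(-2, 0.3)$ hit with probability 0.8 by
  destabilised variants (loss of binding in the screen is usually a
  consequence of loss of abundance) and 0.02 otherwise, and a planted
  gain-of-interaction region (default positions 601–604, hydrophobic and
  aromatic substitutions) at $N(+1, 0.2)$.
* **Nonsense variants**: forced into the destabilised class before position
  745; from 745 onward they get mildly positive truths, mimicking tolerated
  C-terminal truncation.
* **Synonymous markers** are exactly neutral.
* **Selection**: control frequencies are Dirichlet around uniform library
  representation (concentration 50); selection frequencies are
  $f^{ctrl} \exp\{k \cdot \text{truth} \cdot (1+\eta)\}$ with selection
  strength $k = 2$ and multiplicative replicate noise
  $\eta \sim N(0, 0.1)$ per variant and replicate; counts are multinomial
  at 200 reads/variant/condition by default, three replicates.
* **Reads**: each counted molecule becomes one 151 nt read pair on a
  176 nt amplicon (fixed primer flanks around the tile coding sequence, so
  the entire coding region lies inside the mate overlap), with independent
  per-base substitution errors at rate 0.001 and constant Phred-37
  qualities.

Values the assay design fixes (tile boundaries, read length, three
replicates, nonsense only in tile 7) are taken as given; the remaining rates
and spreads above are this package's own realism choices, chosen once for a
screen in which every variant is represented at least ~100-fold, and are
deliberately not tuned per analysis. What the generator does **not**
emulate: PCR jackpots and index hopping, codon-usage bias (one fixed codon
per amino acid — the assay is read out at amino-acid resolution), library
synthesis dropouts, and quality-score variation along reads. Tests passing
on synthetic data therefore demonstrate the correctness of the *computation*,
not robustness to every artefact of real sequencing.

The default reference protein is a deterministic synthetic 270-residue
sequence. It contains no methionine or tryptophan because single-codon amino
acids admit no synonymous marker codon; substitutions *to* M and W remain in
the library, and no statistic downstream depends on residue identities.

## Read processing

Read pairs are filtered with the defaults of the Trimmomatic/Enrich2 tool
chain this scheme follows: mates shorter than
151 nt dropped, survivors cropped to 151 nt, minimum and mean base quality
of 1 (boundary inclusive — the tool chain leaves the boundary case
unstated), and no ambiguous bases. Mates are merged at the fixed per-tile
amplicon offset (primers are fixed per tile, so the offset is configuration,
not inference). "Maximum mismatches of 0" is interpreted as disagreements
*between the two mates inside their overlap* — the overlap-merge semantics of
Enrich2 — not as mismatches against the wild-type, which would make variant
calling impossible; pairs exceeding the tolerance are removed as
unresolvable, and tolerated disagreements resolve to the higher-quality
base. Variant calling is codon-wise against the tile's wild-type sequence:
one amino-acid-changing codon gives the variant key, a single silent change
gives the synonymous marker, and reads with multiple amino-acid changes are
rejected by default because the libraries are single-substitution by design
(a QC flag retains them as multi-keys). Phred encoding is fixed at offset 33.

## Structural features

Relative solvent accessibility is computed with a hand-rolled Shrake–Rupley
implementation (no installed R package provides SASA without an external
binary): a deterministic 960-point golden-spiral lattice per atom, probe
radius 1.4 Å, heavy atoms only, normalised by the theoretical per-residue
maxima of Tien et al. and capped at 1. The lattice makes results exactly
reproducible and translation-invariant; under rotation, agreement is bounded
by the lattice resolution (≈1–5% per atom at 960 points, tightening with
more points), which the tests document. Interface contacts use the strict
6 Å heavy-atom criterion. Model-to-full-length residue numbering is an
explicit user-supplied offset (the structural model of the canonical system
starts at residue 481), never inferred. Per-position medians are written
into PDB B-factors with a sentinel (−9.99) for unmapped residues, documented
in a REMARK header.

The burial threshold separating "buried" from "exposed" residues has no
universal definition; where a binary split is needed it is a parameter with
default rSASA = 0.25.

## Clinical evaluation

Variants join clinical annotations on (position, wild-type residue,
substituted residue), with protein-level HGVS parsed on read. ROC analysis
uses the Mann–Whitney formulation (ties counted ½), oriented so that "more
negative score ⇒ more pathogenic" gives AUC ≥ 0.5; positives are pathogenic
plus likely pathogenic, negatives benign plus likely benign, and VUS never
enter the ROC (they are carried through for scatter-style outputs).
Stability predictions supplied in Rosetta Energy Units are converted to
kcal/mol by dividing by 2.9, exactly once, on read. The detrimental/
wild-type-like dichotomy uses the −0.5 cutoff with ties going to
wild-type-like ("below −0.5" is strict). Mechanism calls combine the two
assays pointwise; the loss thresholds default to the stated −0.5 and the
gain threshold to +0.3, chosen to exceed the synthetic wild-type-mode spread,
both configurable.

## Numerical and design choices

* Pseudocount $\varepsilon = 0.5$ keeps zero-count scores finite; the
  location-invariance of scores under condition-wide depth changes holds to
  $<10^{-2}$ only for variants covered by ≥100 reads, which the tests state
  explicitly.
* KDE mode detection is deterministic; ties between equal-density negative
  maxima resolve to the densest, and the −0.25 guard is a parameter.
* Random-effects pooling degrades gracefully: a single usable replicate
  passes through with a warning; zero usable replicates yield `NA` ("missing"
  downstream, surfacing as gray heatmap cells).
* All randomness flows from one master seed; per-stage seeds are derived
  with a fixed counter so adding a stage never shifts another stage's
  stream, and equal seeds give byte-identical outputs.
* Problem sizes in the test-suite: the full 270-position library at depth
  200 with three replicates for recovery and rescaling checks, and a
  single-tile screen of ~10^5 read pairs for the FASTQ round-trip; smaller
  two-tile configurations exercise the plumbing.

## Known limitations

* The FASTQ path models exactly one amplicon geometry (176 nt, full coding
  region inside the mate overlap). Real designs with partial overlap would
  exercise the `overlap_only` exclusion more heavily than the tests do.
* The published AUC/correlation benchmarks can only be recomputed when the
  deposited supplementary score workbook is provided (see
  `tests/testthat/test-acceptance.R` for the expected layout); the package
  ships no copy of it.
* Scores are relative to the synonymous reference of each tile; comparing
  *raw* (unrescaled) scores across tiles conflates tile effects with variant
  effects — rescale first, or compare within tiles.
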
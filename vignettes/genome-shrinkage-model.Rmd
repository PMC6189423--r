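---
title: "A recombination-driven model of genome-size reduction after rearrangement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A recombination-driven model of genome-size reduction after rearrangement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synshrink)
```

## The model

Plant chromosomes are strongly zoned: recombination is high in distal
(telomeric) regions and nearly absent across the pericentromere, gene
density follows the same U-shaped gradient, and transposable elements (TEs)
accumulate where recombination is low. `synshrink` implements a forward
model in which this zoning, not any property of the sequence itself, sets
the local rates of sequence gain and loss:

* **Illegitimate recombination** deletes sequence with per-bp intensity
  `lambda_illegit * c(p)`, where `c(p)` is the relative recombination rate
  at position `p`. It requires no homology and is the dominant removal
  channel.
* **Unequal intrastrand recombination** acts on intact LTR
  retrotransposons with intensity `lambda_unequal * c(midpoint)` per
  element, deleting the internal region plus one terminal repeat and
  leaving a **solo LTR** — the diagnostic scar of this mechanism.
* **TE insertion** adds new elements with intensity
  `lambda_insert * (1 - c(p))`, i.e. preferentially in the proximal,
  low-recombination zone, and much more slowly than removal.

A chromosomal inversion (or relocation) that carries formerly proximal,
TE-rich sequence into a distal position exposes it to high `c(p)`: the
relocated material is rapidly deleted, while the formerly distal material
now parked at the pericentromere slowly gains TEs. The net effect is
shrinkage of the rearranged region in the rearranged lineage, with a
distance-dependent gradient — syntenic blocks nearest the new distal end
shrink most, producing the characteristic bowed dot-plot arc.

Deletions never remove gene bp when `gene_protection` is on (deletions
overlapping a gene are re-drawn up to 10 times, then skipped; insertions
land only in spacer/TE intervals). This encodes the assumption that
intragenic losses are purged by selection, and it gives the analysis
pipeline a complete ortholog anchor set.

## The recombination map

The paper-style Marey map (cumulative cM vs bp, flat across the
pericentromere and steep distally) is modelled as a symmetric logistic ramp
in *relative arm position* `t` (0 at the centromere, 1 at the telomere):

`c(t) = floor + (1 - floor) * (s(t) - s(0)) / (s(1) - s(0))`, with
`s(t) = logistic((t - mid)/scale)`.

Defaults `mid = 0.6`, `scale = 0.08`, `floor = 0.02` give a profile that is
within a few percent of its floor over the proximal half of each arm and
near 1 over the distal fifth. Anchoring the map to relative rather than
absolute position keeps the profile meaningful as the chromosome changes
length; the small drift this allows between the map centromere and the
physical centromere after strongly asymmetric loss is a known
approximation. `floor = 1` produces a uniform map, which is how the
estimator-calibration runs are configured.

## Event scheduling

Events of one step are drawn by thinned Poisson sampling against the state
at the start of the step and applied simultaneously in a single vectorized
rebuild of the feature tiling; colliding draws are dropped
deterministically (later-drawn loses) and never logged. This is exact in
the small-rate limit and keeps desk-scale runs fast. `generations_per_step`
collapses several generations into one sampling step; at the default rates
a 10-generation step changes per-bp event probabilities by well under one
part in a thousand. Every event is logged with enough detail that
`replay_events()` reconstructs the final chromosome byte-for-byte from the
ancestor, and `ancestry_map()` replays the same log as an interval map to
ancestral coordinates, from which truth-level pairwise alignment blocks are
derived without sequence alignment.

## Study conditions and calibration

The defaults in `sim_config()` are a deliberately scaled-down study
condition chosen once: one to two 1 Mbp chromosomes, 2,000 generations,
`lambda_illegit = 1.5e-5` per bp per unit `c` per generation, deletion
lengths from a truncated discrete power law (`alpha = 1.6`, max 10 kb, mean
about 58 bp), `lambda_unequal = 5e-5` per intact element, and
`lambda_insert = 1e-9` per bp. With these values a terminal-arm inversion
loses roughly 25–35% of its ancestral sequence over the run — the same
net-reduction regime as the published two-genome comparison the package
models (inverted regions at about 0.65 of their unrearranged counterparts)
— while non-inverted regions stay near parity. The rates are calibration
constants for the desk-scale regime, not biological estimates; the
deletion-length family is chosen so that short deletions dominate event
counts while deletions of at least 1 kb dominate removed bp, matching the
observed partition of unaligned sequence.

Two generator choices deserve note. The default inversion plan starts at
`centromere_frac + 0.02`, i.e. just distal of the centromere, so the
centromere itself is never moved (a pericentric inversion would relocate
the centromere and scramble both arms' regimes). The proximal gene-density
floor (`gene_floor = 0.25`) keeps occasional genes in the deepest
pericentromere — as real pericentromeres have — so that gene-anchored
synteny blocks can cover the strong-loss region; with a lower floor the
region becomes a gene desert that block analysis cannot see.

## What the synthetic data does and does not emulate

`write_genome_pair()` serializes a simulated pair to FASTA + GFF3 + TSV.
Gene sequences are shared between orthologs; every TE copy descends from a
per-family template (LTR templates are `LTR|internal|LTR` with identical
termini), with configurable per-copy divergence. At `divergence = 0`,
full-length exact terminus matching recovers planted and mechanism-derived
solo LTRs exactly against the event ledger; at the default 2% divergence
the inventory is approximate, as it is for real genomes. The generator does
not model nucleotide substitution between the lineages, gene birth/death,
segmental duplication, or assembly artefacts — so a passing pipeline run
shows the methods are correct on their own assumptions, not that they are
robust to annotation noise or alignment error in real data.

## Analysis-side conventions

* **Homolog pairing** keeps the top hit per query with deterministic
  tie-breaks (score, then lexicographically smallest target id). The
  default scorer is exact family-label match; a k-mer identity scorer is
  available when sequences are supplied.
* **Block chaining** is unit-score dynamic programming with a hard
  gene-index gap cap in both genomes (`max_gap = 5`) and `min_pairs = 4`,
  extracted greedily; overlapping lower-scoring blocks are dropped. These
  defaults are ours: the original analyses used a chaining program whose
  parameters are not printed and whose output was manually curated. For
  within-region ratio profiling, long chains can be segmented into
  consecutive sub-blocks (`max_pairs_per_block`, default `Inf`; the
  pipeline uses 12) — with gene protection on, pairing is complete and an
  inversion would otherwise be a single block, hiding the internal ratio
  gradient.
* **Density tracks** use 500 equal partitions by default (remainder to the
  last partition, densities computed with true partition lengths); genes
  are assigned to the partition containing their midpoint — the assignment
  rule is our choice and is applied consistently. Partitions are paired by
  index between genomes even when lengths differ.
* **Flanking classification** of an unaligned segment calls `identical`
  when repeats of at least 50 bp with the same family template sit within
  100 bp of both endpoints in the same direction, `similar` when only the
  TE class matches, `none` otherwise; identical takes precedence. In the
  synthetic data the family template plays the role of a repeat-library
  entry, so `identical` means "matches the same library repeat".
* **Solo-LTR inventory** searches each intact element's terminus at full
  length and 100% identity (95%/90% available as options) and excludes
  matches overlapping intact-element footprints — the published criterion
  is silent on that exclusion, so it is our documented choice.
* **The reduction-rate estimator** defaults to the compound reading
  `x = (1 - (b/a)^(1/n)) * 100` per 100 bp per generation, because it is
  the reading consistent with a constant per-generation loss process and
  with the published worked values; the linear reading
  `x = ((1 - b/a)/n) * 100` is retained behind `variant = "linear"` and
  all reports name the variant. `b > a` yields a negative rate with a
  growth flag, not an error.

## Numerical and degenerate-input choices

Coordinates are 0-based half-open internally; GFF3 emission converts to
1-based closed. Inversion and relocation endpoints snap to the nearest
feature boundary, so rearrangements never split features (deletions do
fragment TEs, and a fragmented or inserted-into LTR element loses its
"intact" status). The solo-LTR conversion retains the 5' terminus; the
choice is arbitrary and fixed. A constant density track has undefined
rank correlation with the U template and is reported as disruption score 1.
Zero-denominator ratios (empty blocks, regions without intact elements)
are reported as NA and flagged, never as 0. Each simulation uses one seeded
generator; lineages and chromosomes run on child streams derived from the
seed, so one lineage's draw count cannot perturb the other.

## Problem sizes used in the shipped analyses

The packaged tests and acceptance analyses run the study condition at one
1 Mbp chromosome, 2,000 generations and 30 independent seeds for the
replicate properties (aggregate inverted/non-inverted ratios, TE-vs-gene
ratio correlations, the within-inversion ratio gradient), 30 replicates of
a 0.5 Mbp uniform-map chromosome for estimator parameter recovery, and 200
random instances of up to 50 homolog pairs for the chaining oracle. These
sizes were chosen as the smallest at which the replicate statistics are
stable; all of them are configuration arguments, and larger runs only
require changing `sim_config()`.

## Known limitations

The recombination map is anchored to relative arm position of the current
length rather than to a tracked physical centromere; after extreme
asymmetric loss the map and physical centromeres drift apart.
`ancestry_map()` does not support cross-chromosome relocations (relocation
effects are studied through length dynamics instead). TE fragments are
re-synthesized from the template prefix rather than the template offset
they once occupied. Local gene duplications count each duplicated gene
once across overlapping windows — the natural de-duplicated reading of a
sliding-window definition — so counts are not comparable to a
per-window-incremented variant.
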
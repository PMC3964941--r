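---
title: "Methods: CLIP-supported miRNA targeting and ceRNA network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CLIP-supported miRNA targeting and ceRNA network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

## Overview

`cernet` chains five stages: seed-site discovery on transcript sequences,
intersection with Argonaute CLIP binding-site clusters, stringency
filtering, a hypergeometric test for shared-miRNA-family gene pairs
(ceRNA candidates), and downstream summaries (super-sponge ranking,
functional enrichment). This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic
fixtures do and do not establish.

## Coordinates, strands and overlap

All interval tables use BED conventions: 0-based, half-open `[start, end)`.
Adjacent intervals (`end == start`) share zero bases and do not overlap;
"overlaps" means an intersection of at least `min_overlap` bp (default 1,
the any-overlap convention of standard interval-intersection tools).

Overlap is strand-aware by default because Argonaute binds the transcribed
strand; strand `"."` matches either strand, so unstranded cluster sets
degrade gracefully rather than silently dropping support. Chromosome names
are compared as exact strings; a `normalize_chr` switch strips a leading
`"chr"` on both sides for mixed naming schemes.

A site's `supporting_experiments` counts *distinct experiments* with at
least one overlapping cluster — two clusters from one experiment are one
piece of independent evidence. The stringency filters downstream
("supported by at least one experiment", "predicted by at least three
programs") are phrased in exactly these units.

## Seed-site model

The scanner reports canonical seed-match classes on the transcript (DNA,
sense orientation). A locus is anchored at a match to the reverse
complement of miRNA seed positions 2–7 and classified by two flanking
properties: pairing to position 8 (one base 5' on the transcript) and an
adenosine opposite position 1 (one base 3'):

| class   | pairing      | A1  | length |
|---------|--------------|-----|--------|
| 8mer    | positions 2–8| yes | 8 nt   |
| 7mer-m8 | positions 2–8| no  | 7 nt   |
| 7mer-A1 | positions 2–7| yes | 7 nt   |
| 6mer    | positions 2–7| no  | 6 nt   |

Each anchor yields exactly one site of its highest class, so an 8mer is
never double-reported as its nested 7mers. Overlapping anchors (two core
matches fewer than 6 bp apart) are distinct loci and are all reported;
the implementation therefore searches with overlapping-match semantics.
`6mer` sites are off by default: the package's built-in predictor is meant
to mirror strict seed-pairing stringency, and 6mers are too permissive to
be useful without conservation or context scores, which are out of scope.
Full hybridization-energy models (miRanda-style alignment, PITA ΔΔG,
RNA22 patterns) are deliberately not implemented; when such evidence
exists it is ingested as external prediction files and contributes to the
per-site program count instead.

miRNAs are collapsed to seed families before scanning; a catalog entry
without a family becomes a singleton family named after the miRNA so no
input is silently dropped. Family members must agree exactly on positions
2–8 (validated, not assumed).

Transcript-space sites are projected to the genome through an exon table.
Sites spanning an exon junction are not split across exons: they keep
transcript-space coordinates and are flagged, because a split site cannot
be intersected meaningfully with genome-space clusters without
double-counting. In practice seed sites are 6–8 bp, so junction-spanning
sites are rare.

## The ceRNA statistic

For a gene pair the test asks whether the overlap of their miRNA-family
sets is larger than a random draw would produce. With `N` families in the
prediction universe, `K` and `n` families targeting the two genes and `c`
shared, the p-value is the upper tail `P(X ≥ c)` of the
hypergeometric(N, K, n) distribution. Two modelling rules matter:

* **Families, not miRNAs, not sites.** Multiple miRNAs sharing a seed are
  one unit, and a family with ten binding sites on a gene counts once.
  Anything else would inflate `c` with redundant evidence.
* **`N` is the number of families used for prediction** — the full
  collapsed catalog — not the number of families that happened to hit a
  target. Restricting `N` to observed families would shrink the universe
  and anti-conservatively inflate significance.

The tail is computed in log space with log-gamma binomial coefficients,
shifted by the modal term of the pmf before exponentiation, which keeps
the sum stable for universes far beyond the exact-arithmetic range. The
suite verifies agreement with exact rational enumeration to below 1e-12
relative error over every tuple with `N ≤ 40`, and `P(X ≥ 0)` is returned
as exactly 1.

### FDR scope

`build_cerna_network()` computes a p-value for every unordered pair
sharing at least one family and applies Benjamini–Hochberg across all of
those tests; an edge is reported when its q-value passes the threshold
(default 0.05) *and* the pair shares at least `min_common` families
(default 3; a query mimicking stringent single-gene lookups might use 10).
The reporting filter is deliberately outside the correction: restricting
BH to pairs that already pass `min_common` conditions the corrected set on
a small tail probability, and in null simulations that variant showed a
realized false-discovery proportion an order of magnitude above the
nominal level, while the implemented scope stays below it. Both FDR modes
are exposed: per-query (`find_cerna_partners()`, mirroring an interactive
lookup) and global (`build_cerna_network()`, mirroring batch database
construction); their q-values differ because the correction pools
different test sets.

## Sponges

A transcript with many sites of one family is a candidate super-sponge.
`count_family_sites()` counts deduplicated sites per (family, transcript)
and separately the CLIP-supported subset; `rank_sponges()` sorts by site
count with CLIP-supported count and transcript id as tie-breaks. Both
counts are reported because either can be the quantity of interest and
no principled single threshold exists; the default reporting cut of 5
sites is far below the dozens seen in canonical sponges but high enough
to suppress the 1–2-site background.

## Enrichment

Functional prediction takes a gene set — the stringency-filtered targets
of selected families, or the ceRNA partners of a gene — and tests each
term of a GMT category with the same hypergeometric tail, `m` being the
number of terms in the category. Both Bonferroni (`min(1, m·p)`) and BH
corrections are reported, per category: categories answer different
questions and pooling their tests would let a large category dominate a
small one's threshold. The default universe is the union of the
category's gene sets because no better background is knowable from a GMT
file alone; when the assayed transcriptome is known it should be passed
explicitly — the background choice dominates enrichment p-values. Gene
identity is by uppercased symbol for GMT interoperability.

## Synthetic fixtures

`simulate_universe()` emits every input the pipeline reads (FASTA,
transcript/exon/miRNA tables, per-experiment BED with sidecar, a toy GMT)
plus truth tables. Design choices:

* **Exact plantedness.** Family seeds are drawn so that no family's 6-mer
  core occurs inside any other family's planted 8-mer string (and its own
  core occurs there exactly once); after planting, the background is
  repair-mutated until the only seed-core occurrences are the planted
  ones. Planted loci are spaced ≥ 12 bp, so any straddling spurious match
  always has a mutable base outside the protected windows. A re-scan of
  the emitted FASTA therefore reproduces the truth table exactly — the
  scanner's false-positive check is exact, not probabilistic.
* **Per-file RNG streams.** Each emitted file draws from a stream derived
  from the master seed and a stable label, so adding an output never
  perturbs existing ones and identical configs are byte-identical.
* **Defaults are the study conditions.** 150 miRNA families, 220 genes
  with 10 families each, of which 40 form 20 planted ceRNA pairs sharing
  8 families; 3 CLIP experiments covering every planted site
  (`p_support = 1`) plus 50 intergenic decoy clusters each; one planted
  sponge transcript (circRNA biotype) with 12 sites of one family. These
  sizes keep every validation run to seconds while leaving the planted
  signal (tail probability ≈ 3.8e-10) unambiguous against the null
  background.
* **Null profiles.** `simulate_null_profiles()` draws each gene's family
  set as an independent uniform k-subset — exactly the null under which
  the hypergeometric tail is the correct p-value — and backs the FDR
  calibration runs (G=200, F=100, k=10, 200 replicates).

What the fixtures do *not* emulate: real seed-site sequence composition
(background is uniform ACGT), conservation structure, 3'-UTR biology
versus full transcripts, CLIP cluster shapes or crosslink-induced
mutations, multi-exon transcripts (fixtures are single-exon; projection
handles multi-exon input but is only unit-tested), and correlated family
assignment between genes. Passing tests therefore demonstrate that the
machinery is correct under its stated model, not that the stringency
defaults are optimal for any particular organism or CLIP corpus.

## Numerical and engineering choices

* Hypergeometric domain violations (`K > N`, `c > min(K, n)`, …) are
  errors naming the violated inequality, not silent clamps.
* BH uses a stable sort; its output is permutation-equivariant and is
  cross-checked against `stats::p.adjust` on random vectors.
* Interval intersection is delegated to `GenomicRanges::findOverlaps`
  behind the tibble interface and verified against an O(n·m) brute force.
* Evidence merging is transitive over ≥ 1 bp overlaps within
  (family, gene); program tags survive comma-joined, so re-merging merged
  tables is a no-op (idempotence is tested).
* Edge tables, reports and the manifest are plain TSV written
  deterministically; the run manifest records MD5 checksums, and reruns
  on identical inputs are byte-identical (tested).
* Validation problem sizes (full `N ≤ 40` oracle grid, 1000 transcripts ×
  20 seeds for the scanner oracle, 10,000 sites for the overlap oracle,
  200 null replicates, 100,000 Monte-Carlo draws) were chosen so the
  whole suite runs in about two minutes on one core.

## Known limitations

* The built-in predictor is seed-match only; sites lacking canonical
  seeds (3'-compensatory, G-bulge) are invisible unless supplied as
  external predictions.
* `supporting_experiments` treats experiments as exchangeable; no
  weighting by protocol, depth or read counts beyond the reported totals.
* The ceRNA test uses binary family sets, not binding-site counts or
  affinities, and assumes one fixed universe `N` for all pairs.
* Enrichment is per-category; results across categories are not jointly
  corrected by design.
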
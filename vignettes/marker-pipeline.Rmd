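---
title: "Developing SSR and intron polymorphism markers genome-wide"
author: "treemarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing SSR and intron polymorphism markers genome-wide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treemarker)
```

## The problem

Tree genetics has long been starved of cheap, transferable molecular
markers. Two marker families can be developed directly from an assembled
genome: **simple sequence repeats** (SSRs, microsatellites) — perfect tandem
repetitions of a 1–7 bp motif whose repeat number mutates quickly — and
**intron length polymorphism** (ILP) markers — primer pairs placed in the
exons flanking an intron, whose product length varies with the intron.
Where only ESTs are available, **potential intron polymorphism** (PIP)
markers can be inferred by projecting an EST onto the annotated gene of a
model species and designing primers around the projected intron positions.

`treemarker` implements that entire development pipeline as a tested
toolkit: SSR mining, intron extraction and projection, primer design,
electronic PCR (e-PCR) validation and screens, marker distribution
statistics, UPGMA diversity analysis of band matrices, and duplication-block
detection from multi-site markers. Every stage can also be exercised
against a synthetic genome with planted, recorded ground truth.

## SSR mining

A locus is reported when a primitive motif of length $k \in 1..7$ repeats
perfectly at least $t_k$ times, with the class thresholds

```{r}
setNames(default_min_repeats(), paste0(1:7, "-mer"))
```

(monomers ≥ 12 repeats through heptamers ≥ 2). Each class is scanned
independently with a lag-$k$ run-length pass, so one region may legitimately
host loci of several primitive motif lengths; within a class every maximal
run is reported exactly once, anchored at the leftmost phase, and runs never
cross an `N`.

Motifs are normalized to a **canonical form**: the lexicographically
smallest string among all cyclic rotations of the motif and of its reverse
complement, so `AC`, `CA`, `TG` and `GT` are all the marker motif `AC`.
Non-primitive units (`ATAT` as a "tetramer") are rejected — such runs belong
to the class of their primitive unit. This primitivity rule is a design
choice the package makes explicit: counting non-primitive units would
inflate the large-motif classes, and a `scan` under relaxed rules can be
emulated by lowering the class thresholds.

```{r}
g <- genome_set("demo", c(chr = paste0(
  strrep("ACGTGGTCAT", 12), strrep("CA", 8), strrep("TTGCACGGAT", 12))))
scan_ssr(g)
```

## Primer design

Each locus contributes a pair of 60-bp **precursor flanks** cut immediately
left and right of the repeat (truncated or `N`-containing flanks are
rejected). The designer enumerates every window of 18–27 nt in each flank
and applies hard constraints: melting temperature 55–63 °C (optimum 60),
GC fraction 0.35–0.65, homopolymer runs ≤ 4, self-complementary stretches
≤ 8 anywhere and ≤ 4 anchored at the 3′ end, and a pair Tm difference ≤ 3 °C.
Tm is the unified nearest-neighbour model with entropic salt correction at
50 mM Na⁺ and 250 nM total strand concentration — the conventional primer
concentration regime; concentration and salt are arguments of
`primer_tm()` for anyone who needs a different chemistry. Candidate pairs
are scored by summed |Tm − 60| plus a small length-deviation term and
cross-complementarity penalties; the lowest score wins and ties resolve to
the leftmost forward, then leftmost reverse window, making the design fully
deterministic. These constraints are the package's own defaults (exposed in
`design_constraints()`), chosen as conventional values rather than a
reproduction of any particular legacy configuration.

## Electronic PCR and the screens

`epcr()` reports a hit wherever the forward primer binds one strand and the
reverse primer binds the opposite strand downstream, with disjoint primer
sites and a 5′-to-5′ product of 40–5000 bp. Matching is exact by default
(`max_mismatches = 0`), the three 3′-terminal bases must always match
exactly, and `N` in the genome matches nothing. Hits are capped at 1000 per
marker per genome to bound pathological low-complexity primers.

On top of the engine sit four screens:

* **Validation** — a marker is `validated` when a hit overlaps its source
  locus with a product within 20 % of the designed size.
* **Deduplication** — markers sharing a forward *or* reverse primer collapse
  (transitively) to one representative, the one with the smallest
  (sequence, position).
* **Polymorphism** — a validated marker amplifying exactly one genome-wide
  site is monomorphic; two or more sites, polymorphic.
* **Universal screen** — markers retaining at least one hit in every genome
  of a panel.

## Intron markers

ILP: introns are the gaps between consecutive exons of the representative
transcript (the one with the longest summed exon length; ties broken by
transcript id). No intron length filter is applied. Flanks must be fully
exonic — that placement is what makes the product length track the intron.
Intron positions of the model species are read from its annotation rather
than re-derived by spliced alignment: the annotation is required anyway and
carries the same information; an alignment-based mode is reserved as a
future option.

PIP: each EST is aligned to model CDS sequences by local Smith–Waterman
(match +1, mismatch −2, gap open 5, extend 1, both strands), accepted at
≥ 85 % identity over ≥ 100 aligned columns — conventional cross-species EST
mapping values, exposed as arguments. Annotated intron positions falling
inside the aligned region are projected column-by-column onto the EST and
become PIP design points. On synthetic ESTs the projection is exact at 0 %
divergence and lands within ±2 bp at 5 % substitution (alignment jitter the
test suite asserts empirically).

## Diversity analysis

Dominant-marker gels are emulated by binning e-PCR product sizes into 5-bp
bands (polyacrylamide-level resolution; configurable). The band
presence/absence matrix feeds Dice (Nei–Li) distances by default — the
standard coefficient for dominant markers; simple matching and Jaccard are
selectable because the original gel-analysis software leaves its coefficient
unstated. UPGMA agglomeration uses cluster-size-weighted average linkage
with merge height $d/2$; among tied minimum-distance pairs the merge whose
leaf set is lexicographically smallest goes first, so trees are reproducible
to the byte. Bootstrap support resamples band columns with replacement,
rebuilds the tree, and counts identical leaf bipartitions, under a single
seed.

## Duplication blocks

Markers that amplify two or more sites in their own genome are duplication
**anchors**: every unordered pair of sites links two genomic positions.
Pairs closer than 10 kb on one sequence are flagged tandem and excluded from
segmental chaining. Anchors of one sequence pair are chained by a
longest-increasing (and, for inverted blocks, longest-decreasing)
subsequence dynamic programme whose gap constraint is expressed in hit-rank
ordinals (≤ 25), mirroring the gene-rank convention of collinearity tools;
blocks need ≥ 5 anchors. Chains are extracted greedily — the maximum-length
chain is removed and the search repeats — with a fixed tie-break (same
orientation first, then the lexicographically smallest anchor sequence), so
no anchor is ever in two blocks and the output is deterministic. Gene-based
blocks can be built the same way from protein BLAST tabular files read with
`read_blast_tabular()`; block overlap statistics intersect both spans under
either axis pairing.

## The synthetic fixture

`generate_fixture()` builds the test genome every stage is verified
against. The background is drawn from configurable base frequencies (default
30/20/20/30, plant-like AT richness) and **rejection-sampled to silence**:
any window that would form a reportable SSR is redrawn until a scan of the
background finds nothing, so specificity checks are exact rather than
statistical. Features are then planted at recorded coordinates: SSR loci
(200 by default over the seven classes), genes (50, with 149 introns:
forty-nine 3-intron genes and one 2-intron gene), and duplicated segments
(three 60-kb copies at 2 % per-base substitution, each seeded with 20 SSR
loci kept 150 bp clear of the segment edges so the primer flanks are copied
intact). A junction-repair pass redraws any background base whose
coincidental context would extend or create a locus, so the final scan
equals the planted truth exactly — except inside the duplicated copies,
where surviving repeats are expected and recorded as such. ESTs are spliced
transcripts with 2 % substitution by default. All randomness flows from one
seed; two runs are byte-identical.

What the fixture does *not* emulate: indels, imperfect or compound repeats,
nested gene structures, assembly gaps and real base-composition
heterogeneity. Passing tests therefore demonstrate algorithmic correctness
under the stated model, not performance on real assemblies, where repeat
density, Ns and fragmented scaffolds will reduce design and validation
rates.

Problem sizes used by the standard verification runs: a 2 Mb two-scaffold
genome for end-to-end work; 10-kb sequences (×100) for scanner/oracle
equivalence; 100-kb genomes for e-PCR/oracle equivalence; anchor sets of at
most 12 for exhaustive chaining enumeration; 1000 bootstrap replicates on an
8 × 50 band matrix.

## Numerical and degenerate-input choices

* Intervals are 0-based half-open internally; GFF3 and marker TSVs convert
  to 1-based inclusive at the I/O boundary, BED stays 0-based. One
  conversion point, no off-by-one drift.
* Tm is deterministic to well below 0.01 °C; equality of the windowed and
  scalar implementations is asserted in the tests.
* Distance matrices must be symmetric to 1e-12; UPGMA trees are ultrametric
  to 1e-9 (asserted).
* A band-distance pair is undefined (NA, with a warning) only when both
  samples are all-zero under Dice/Jaccard; bootstrap replicates hitting such
  a pair are skipped, which biases support conservatively downward.
* Empty inputs return empty, correctly-typed tables everywhere; single-exon
  genes yield no introns; a validated marker with zero e-PCR hits raises an
  internal-consistency error rather than a silent label.

## Known limitations

Imperfect/compound SSRs and SSR genotyping from reads are out of scope, as
are spliced-alignment re-derivation of model introns, thermodynamic hairpin
models beyond contiguous complementarity, Ks-based dating of duplications,
and any attempt to reproduce genome-scale counts from real assemblies,
which depend on assembly versions the package does not ship.
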
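# treemarker

Genome-wide development of molecular markers for plant (especially tree)
genomes: **SSR** (simple sequence repeat / microsatellite), **ILP** (intron
length polymorphism) and **PIP** (potential intron polymorphism) markers,
from raw FASTA/GFF3 to validated, deduplicated primer pairs — plus the
downstream analyses those markers support: polymorphism and universal-marker
screens by electronic PCR, marker density/concomitance statistics, UPGMA
diversity analysis of dominant-marker band matrices, and duplication-block
detection from multi-site markers.

The core objects and rules:

* An SSR locus is a maximal perfect tandem run of a primitive motif of
  length *k* = 1..7 with at least *t_k* repeats
  (*t* = 12, 6, 4, 3, 3, 2, 2 for monomer..heptamer). Motifs are stored in
  canonical form — the lexicographic minimum over all rotations of the motif
  and of its reverse complement, so {AC, CA, TG, GT} → AC.
* Markers are primer pairs designed deterministically from the 60-bp
  precursor flanks of a locus (or from the exonic flanks of an intron, or
  around an intron position projected from a model species onto an EST),
  under nearest-neighbour Tm, GC, homopolymer and self-complementarity
  constraints.
* A marker is *validated* when e-PCR against its source genome yields an
  on-target product within 20 % of the designed size; *monomorphic* when it
  amplifies exactly one genome-wide site, *polymorphic* at two or more;
  *universal* when it amplifies in every genome of a panel. Markers sharing
  a forward or reverse primer are duplicates (transitively) and collapse to
  one representative.
* Band matrices (samples × 5-bp product-size bins, 0/1) are clustered by
  UPGMA on Dice distance *d* = 1 − 2a/(2a + b + c), with bootstrap support
  from column resampling.
* Markers with ≥ 2 amplification sites anchor duplication detection:
  anchors are chained by a longest-increasing/decreasing-subsequence DP
  (ordinal gap ≤ 25, block length ≥ 5) into collinear blocks.

Everything is testable without any external data: `generate_fixture()`
builds a deterministic synthetic genome (SSR-free rejection-sampled
background) with planted SSR loci, genes with known introns, spliced ESTs
and duplicated segments, all with recorded ground truth.

## Worked example

Scan a sequence, design a primer pair from the precursor flanks, validate it
by e-PCR and classify its polymorphism:

```r
library(treemarker)
set.seed(7)
bg  <- function(n) paste0(sample(c("A","C","G","T"), n, TRUE, prob = c(.3,.2,.2,.3)), collapse = "")
chr <- paste0(bg(140), strrep("CA", 8), bg(140))
g   <- genome_set("demo", c(chr = chr))

(loci <- scan_ssr(g))
#>   species seq_id start end class_k motif motif_as_found repeat_count
#> 1    demo    chr   140 156       2    AC             CA            8
```

The (CA)×8 run is reported once, as canonical motif `AC` with the phase
actually found (`CA`) kept alongside. Cut flanks and design:

```r
pre <- ssr_precursors(loci, g)
d   <- design_primer_pair(pre$left_flank, pre$right_flank,
                          insert_len = loci$end - loci$start)
#> forward: CTTTAGTGAGACGGTCGCCGC  (Tm 59.98 C)
#> reverse: CGCTTGTACCGTTGGCATCACA (Tm 60.11 C)
#> expected product: 91 bp
```

Both primers sit within 0.2 °C of the 60 °C optimum. Validation finds the
single on-target product and the marker is monomorphic:

```r
#>        marker_id type motif repeat_count expected_product_bp    status
#> 1 SSR_chr_140_AC  SSR    AC            8                  91 validated
#>        marker_id species seq_id start end strand product_bp
#> 1 SSR_chr_140_AC    demo    chr   119 210      +         91
#>        marker_id site_count       label
#> 1 SSR_chr_140_AC          1 monomorphic
```

The whole pipeline (scan → precursors → design → e-PCR validation → dedup →
screens → statistics → duplication blocks) runs in one call and writes a
marker table, BED tracks, summaries and a reproducibility manifest:

```r
fx  <- generate_fixture(fixture_spec(seed = 42))
res <- run_marker_pipeline(fx$genome, genes = fx$genes, out_dir = "out", seed = 1)
```

A thin command-line front-end wraps the same functions
(`exec/treemarker`), e.g.
`treemarker scan --fasta genome.fa --out loci.tsv` or
`treemarker pipeline --fasta genome.fa --gff genes.gff3 --out out/`.

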
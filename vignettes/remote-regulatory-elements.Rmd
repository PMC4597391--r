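---
title: "Predicting remotely acting regulatory elements from Hi-C and epigenomic tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting remotely acting regulatory elements from Hi-C and epigenomic tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remreg)
```

## The problem

Disease-causing mutations are not confined to coding sequence: a variant in
an enhancer or other *cis*-regulatory element tens of kilobases away can
disrupt the transcription of its target gene by perturbing a chromatin
looping interaction between the element and the gene promoter. Screening
for such variants requires knowing *where to look*. remreg implements a
six-step in silico procedure that narrows a whole chromosome down to a
handful of candidate regulatory regions worth sequencing in patients:

1. **Fix a fragment (bin) size** for the chromatin-contact data, typically
   1 Mb for a first pass and 100 kb for refinement.
2. **Locate the gene-containing fragment(s)** — the bin(s) intersecting
   the gene of interest (`gene_bins()`).
3. **Rank fragments by Hi-C interaction count** with the gene-containing
   fragments (`rank_interacting()`, `interacting_block()`). Raw counts are
   used; the dominant signal of a raw intra-chromosomal ranking is the
   self-interaction, with genuinely interacting neighbours standing far
   above a low background.
4. **Refine to a CTCF-bounded search region**
   (`refine_search_region()`): CTCF insulator binding sites delimit the
   stretch of DNA, upstream and downstream of the gene, within the
   interacting fragments that could plausibly harbour regulatory elements
   acting on it.
5. **Intersect with epigenomic evidence** (`find_candidates()`):
   candidate regions are clusters of transcription-factor binding sites
   (TFBS) and DNaseI-hypersensitive sites (open chromatin), corroborated
   by histone marks — H3K4me1 (enhancers/promoters), H3K27ac (active
   enhancers), H3K4me3 (active promoters) — enhancer atlases and
   chromatin-state calls.
6. **Validate against chromatin-loop calls** (`validate_candidate()`):
   a candidate is supported when an in situ Hi-C or promoter Capture Hi-C
   loop joins it to the gene promoter.

Variants found by sequencing the predicted regions are then annotated
(`annotate_variants()`) with containment, feature overlap, phyloP
conservation and cohort allele frequencies.

## Design decisions

### Coordinates

Internally every interval is a `GRanges`, i.e. 1-based and inclusive — the
native convention of the Bioconductor ecosystem this package is built on.
The two file conventions are handled at the I/O boundary: BED, BEDPE and
narrowPeak files (0-based half-open) are converted on read and write by
the readers in `read_bed()` and friends, while VCF positions and all
coordinates in reports are 1-based. `from_printed()`/`format_printed()`
bridge to the 1-based inclusive notation used by genome browsers and in
the literature, so a printed coordinate pair survives a round trip through
the package unchanged. Loop anchors are the one deliberate exception: they
are stored with the BEDPE numbers they are published under, and
`loop_anchors()` converts when overlap arithmetic is needed.

### Fragment selection

`interacting_block()` hands Step 4 the *contiguous* run of fragments
around the gene whose interaction total with the gene fragments reaches
`min_count` (default 1, i.e. any observed interaction). Contiguity
matters: a distant bin with a stray background count is not evidence of a
regulatory neighbourhood, whereas a weakly interacting bin *between* the
gene and a strong interactor — or one harbouring the nearest insulator —
legitimately belongs to the search space. Bins absent from a sparse map
count zero, and an empty map yields an empty ranking.

### CTCF boundaries

CTCF sites within `cluster_gap = 5000` bp of each other merge into one
boundary cluster (two adjacent weak sites act as a single boundary); sites
inside the gene body are ignored; only clusters lying entirely within the
interacting fragments are admissible. The weak/strong cut defaults to a
score of 500 out of 1000 — browser tracks label sites below ~445 weak and
clearly strong sites score ~700+, so any cut between those values yields
the same labels; 500 is the midpoint and is configurable.

Two boundary policies are exposed. The default, `outermost`, takes the
farthest admissible cluster on each side, weak clusters allowed (and
flagged): an insulator delimits the search space even when it sits in a
weakly interacting fragment, so the region is extended out to it. The
`strict` policy instead takes the strong cluster nearest the gene —
the narrower, textbook reading of "bounded by the CTCF site". A side with
no admissible cluster falls back to the interacting-fragment edge and is
recorded as a `fragment_edge` sentinel in the provenance.

### Candidate geometry

A candidate is the span of an *anchor* cluster — TFBS and DNase features
whose mutual gaps are at most `cluster_gap = 200` bp — not the span of the
histone-mark domains that corroborate it. Mark domains from ChIP
enrichment are broad (routinely 10 kb and more) and blur element
boundaries; TFBS/DNase calls are the sharp, open-chromatin core of a
regulatory element, and the regions practitioners take to sequencing
coincide with those cluster spans. Marks, enhancer calls and active
chromatin states (`CHROMHMM` features whose state name denotes activity)
serve as evidence: a cluster must overlap at least `min_mark_classes = 1`
distinct mark classes to be emitted. "Enrichment" is presence of an
overlapping call — the inputs are already enriched-region calls from
ENCODE-style pipelines, so no further statistical test is warranted.

Classification is promoter-first: H3K4me3 or an active-promoter chromatin
state makes a candidate `promoter_like`; otherwise H3K4me1, H3K27ac or an
enhancer call makes it `enhancer_like`; anchors alone leave it
`unclassified`.

### Cell lines

Epigenomic tracks are tagged with the cell line they were assayed in. One
primary line can be configured (ideally the line the Hi-C data comes
from); tracks from other lines are used for a class only when the class is
entirely absent in the primary line. This mirrors the common situation
where a mark was never assayed in the contact-map cell line and a closely
related line substitutes.

### Loop validation

A candidate is `supported` when some loop has one anchor overlapping it
and the other overlapping the promoter; anchor order is irrelevant.
Separation is measured edge-to-edge between candidate and promoter.
Published promoter Capture Hi-C call lists omit promoter-proximal pairs —
interactions separated by less than about 20 kb are simply not reported —
so for `capture_hic` sources a candidate closer than `min_separation`
(default 20,000 bp) with no supporting loop is `not_assessable` rather
than `unsupported`. Shrinking `min_separation` can only demote
`not_assessable` to `unsupported`, never promote to `supported`. Loop
scores are carried through but never thresholded: published loop support
at this resolution is qualitative.

### Variant annotation

Variants are 1-bp intervals at their VCF position. "Novel" means absent
from a user-supplied known-variant list (a dbSNP extract, say), matched on
chromosome, position and both alleles — no online lookup, for offline
reproducibility. Conservation labels follow the phyloP convention:
positive means slower-than-neutral evolution, so `conserved` iff
`score > 0` by default (threshold configurable), with the raw score always
reported. No proximity cutoff is applied when relating variants to
open-chromatin features; exact distances are reported and interpretation
is left to the analyst. Mosaicism is carried as a zygosity label only
(set via an explicit `MOSAIC` INFO flag); allele-fraction modelling is out
of scope. `mean_methylation()` implements the bisulphite summary used for
such loci: the arithmetic mean of C-vs-T ratios across a fixed panel of
validated CpG sites (ten by default), reported as an integer percent, with
the site count enforced.

## The synthetic-locus generators

`paper_locus()` rebuilds, deterministically and entirely in code, a fully
worked example: the chr18 locus around the *SMCHD1* gene (hg18), whose
regulatory neighbourhood is unusually well documented — published contact
counts at two resolutions, CTCF sites with scores, mark/DNase/TFBS/
enhancer/chromatin-state intervals, a promoter loop, three patient
variants with phyloP scores, a 229-patient cohort tally and a methylation
profile. Where only a span or an existence claim is documented (two of the
proximal TFBS, the distal TFBS/DNase peak, off-diagonal contact counts),
the fixture fills in synthetic features placed so the documented cluster
extents and interaction totals are reproduced; such features carry
`synthetic` in their names.

`random_locus(sim_config(seed))` generates randomized loci with a planted
regulatory element for benchmarking. Defaults (a 5-Mb chromosome at
100-kb bins, planted contact counts 3371/663 over a uniform background
capped at 30, a ~1-kb planted element, three decoys) echo the contrast
the worked example exhibits, making recovered output immediately
recognizable. The planted element carries the full co-occurrence
signature — TFBS cluster tiling it exactly, a DNase peak inside it,
enhancer marks over it, flanking CTCF boundaries and a loop to the
promoter — while each decoy lacks at least one required class (anchors
without marks, or marks without anchors). Every fragment between the
planted element and the gene keeps a nonzero interaction count so the
planted fragment stays in the gene's contiguous interacting block, and
far-field background pairs never involve the gene fragments, leaving the
gene's totals untouched. The bundle records the planted interval as the
recovery oracle.

What the generator does **not** emulate: the distance-decay of real Hi-C
contact frequencies, matrix-level noise and coverage biases, fuzzy peak
boundaries from ChIP enrichment, overlapping or nested regulatory
elements, and sequence content (no FASTA). Recovery of the planted element
in 100/100 seeded runs therefore demonstrates that the pipeline logic is
correct and deterministic under the stated co-occurrence model — not that
the procedure has any particular sensitivity or specificity on real
ENCODE-scale data, where boundary noise and partial evidence are the norm.

## Problem sizes and numerical choices

The test suite runs the worked example end to end, recovers planted
elements on 100 seeded 5-Mb loci, checks the interval algebra against
brute-force oracles on 10,000 random pairs, the contact ranking against a
dense-matrix oracle on maps up to 50×50 bins, and I/O round-trips over 50
seeds — sizes chosen so the whole suite completes in a few minutes on a
single CPU while exercising every code path. Determinism is enforced
throughout: ranking ties break by ascending fragment start; candidates
and evidence are reported in ascending coordinate order regardless of
input order; the generators derive all randomness from a single integer
seed and restore the RNG state afterwards. Degenerate inputs fail loudly
(malformed records error with their line number; unknown track classes,
inverted spans, negative counts and off-grid bin starts are rejected)
rather than being silently repaired.

## Limitations

* Contact maps are consumed pre-binned from a plain 4-column TSV; binary
  matrix formats (.hic/.cool) and matrix balancing/normalization are out
  of scope, as is TAD or loop *calling* — loops are consumed as BEDPE.
* The procedure is strand-agnostic and single-assembly: coordinates are
  assumed consistent across all inputs, and lifting between assemblies is
  delegated to external tools.
* Candidate calling is rule-based presence/co-occurrence, not a trained
  model; it inherits the calls it is given and performs no peak calling
  from signal.
* CTCF is used positionally only; motif orientation (loop-extrusion
  convergence rules) is not modelled.
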
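---
title: "Methods: split-read fusion discovery, its filters, and what the simulator does and does not establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split-read fusion discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A fusion transcript joins the 3′ end of one gene's exon (G1) to the 5′
start of another gene's exon (G2). A single-end read of length $L$ that
spans this junction aligns to no normal transcript, but its first
$n_5 = \lfloor L f_5 \rfloor$ bases and last $n_3 = \lfloor L f_3 \rfloor$
bases (the *pseudo paired-end mates*, $f \le 0.5$) can each align cleanly —
one inside the G1 exon, one inside the G2 exon. The discarded middle has
length $g = L - n_5 - n_3$ (16 for a 76-mer at $n = 30$).

The decisive observation is geometric. If the fusion really joins two
canonical exon boundaries, then the $g$ hidden bases must be exactly the
bases between mate 1's alignment end and the 3′ boundary of its exon
($d_1$) plus the bases between the 5′ boundary of mate 2's exon and mate
2's alignment start ($d_2$):

$$d_1 + d_2 = g, \qquad d_1, d_2 \ge 0.$$

Library-preparation chimeras, mismapped repeats and most coincidental
co-alignments fail this identity, which is why it is applied with zero
tolerance. Distances are measured in transcript coordinates on the exon
abutting the putative junction (an alignment may internally span one of
its own transcript's exon junctions; only the junction-side exon matters).

## Assumptions

* Fusions occur at canonical exon boundaries. Intra-exon breakpoints
  violate the identity above and are a documented blind spot.
* Reads are at least 50 nt, so that both mates are long enough (≥ 20 nt at
  $f = 0.4$) to align specifically; shorter reads are rejected at intake,
  not trimmed.
* Alignment is ungapped and end-to-end with at most 2 mismatches (28-base
  seed), mirroring the short-read aligner the procedure was designed
  around. One consequence is deliberate: a junction read cannot be
  "explained away" at step 1, because its tail mismatches the transcript
  at far more than 2 positions.
* RNA-level evidence cannot distinguish genomic fusion, read-through
  transcription and trans-splicing; the categoriser labels, it does not
  adjudicate.

## Read orientation

Either strand of a cDNA fragment may be sequenced. When both mates align
as reverse complements, the parent read is the reverse complement of the
fused transcript, and mate 1 physically covers the *3′* partner. The
evidence model therefore canonicalises such pairs by swapping the mate
roles before the geometry test, so all evidence for one fusion accumulates
in a single directed G1:G2 candidate. Strand-inconsistent pairs (one mate
forward, one reverse) cannot arise from a single fused molecule under this
model and are removed at the geometry stage. Directionality is preserved
throughout: G1:G2 and G2:G1 remain distinct candidates.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fraction5`, `fraction3` | 0.4 | fraction of read length | mates long enough to be specific, short enough to clear the junction; 0.5 is the hard ceiling (mates would overlap). A smaller 3′ fraction recovers junctions very close to an exon end. |
| `max_mismatch` | 2 | bases | aligner validity threshold, over the whole read and within the seed |
| `seed_length` | 28 | bases | seed region of the mismatch rule; whole read when shorter |
| `min_reads` | 1 | read pairs | evidence threshold (Step 5D); raise to trade sensitivity for precision |
| `readthrough_max` | 20 000 | bp | span-edge gap for the read-through label; a literature convention, hence configurable |
| `min_read_length` | 50 | nt | intake floor for full-length reads |

The read-through distance is measured between the nearest gene *span
boundaries* (0 when spans overlap); the source material does not say
whether the 20 kb convention is TSS-to-TSS or edge-to-edge, and
edge-to-edge is the conservative reading for adjacency.

## Numerical and tie-break choices

* Geometry tolerance is exactly 0 bp — the identity is integer arithmetic
  on error-free coordinates, and the worked per-read examples it comes
  from are exact.
* When several alignment placements are valid, the reported hit is the one
  with fewest mismatches, then lexicographically smallest
  (transcript id, position, strand). This makes every run byte-identical
  and keeps reads from family paralogs on their true gene whenever an
  exact placement exists. The all-hits pass at the multi-mapping filter
  re-examines the ambiguity this choice hides.
* Blocks merge on ≥ 1 shared genomic base, transitively; no gap-merging.
  A read whose own alignment spans an intron links the flanking pieces
  into one block.
* Nearest-exon assignment compares a block's junction-side extremity
  (3′ edge for G1 — genomic right on + genes, genomic left on − genes;
  5′ edge for G2, mirrored) against the matching boundary of every exon of
  the gene; ties break to the smallest exon id (the data give no rule).
* Degenerate inputs: empty candidate lists produce header-only files;
  an all-aligned step 1 short-circuits to empty outputs; zero predictions
  give sensitivity 0 and an undefined (NA) PPV.

## The built-in aligner

The default backend needs no external binary and is exact for its
criterion: any placement with ≤ 2 mismatches must contain an exact third
of the read (pigeonhole), so three trusted-band multi-pattern passes over
the concatenated reference enumerate every candidate placement, each then
verified base by base (total and seed mismatch counts). A property test
checks it against a brute-force all-offsets, both-strands comparator on
randomised references. An external Bowtie-compatible aligner can be used
instead by importing its SAM (`read_sam()`); its hits are consumed
verbatim.

## What the simulator emulates — and what a green test does not establish

The generator reproduces the benchmark world at desk scale: ~300
multi-exon genes on synthetic chromosomes (a handful of families at 95%
identity, built as mutated founder copies), an expressed subset (70%) with
log-normal per-transcript read counts, 55 planted single-exon fusions
with junction-read counts uniform on 1–295 and a ≥ 30-base overhang of
each exon in every junction read, 10,000 uniform-random junk reads, and
~50% of reads reverse-complemented. The background depth distribution is
a parametric stand-in (meanlog 4, sdlog 1.2) for the unpublished empirical
distribution the original benchmark sampled; reads are error-free by
default because junk reads, not base errors, are the intended noise model
(an optional per-base substitution rate exists).

It does **not** model: sequencing error profiles or quality decay,
intron-retaining or multi-exon fusion junctions (single exon per partner,
per the stated procedure; a config extension allows more), expression-
linked fragment biases, library-prep chimera formation (exercised
indirectly through shared-exon and family planting), or genome-scale
reference size. A passing end-to-end test therefore establishes the
*logic* of the cascade — conservation, geometry, block/isoform
reconstruction, scoring — on clean, in-model data; it does not certify
recall on real libraries, where reference incompleteness and base errors
dominate.

Synonymous fusions — a family member substituted for the true partner —
are the simulator's designed failure mode and are scored as false
positives (and as misses for sensitivity), the most stringent accounting.

## Known limitations

* Intra-exon breakpoints are invisible by design (zero-tolerance
  geometry).
* With ~5% divergent paralogs, a 30-mer mate is identical in both family
  members roughly a fifth of the time; single-read fusions involving
  family genes can then surface as synonymous predictions. More evidence
  reads resolve this, which is precisely the ranking rationale.
* The antisense filter is operationalised as "gene spans overlap on
  opposite strands" — the narrowest definition consistent with its
  purpose; it does not catch antisense transcription outside annotated
  spans.
* Single-threaded; the per-read stages are vectorised but genome-scale
  references belong to an external aligner backend.
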
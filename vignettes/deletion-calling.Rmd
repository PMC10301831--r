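---
title: "Calling and genotyping deletions with deepdel: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and genotyping deletions with deepdel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Deletions of 50 bp and above leave two kinds of traces in a read
alignment: *intra-read* evidence — a long `D` run inside one CIGAR — and
*inter-read* evidence — a read split into two reference-adjacent segments
whose gap on the reference exceeds the gap on the read. Around the
breakpoints, coverage drops (fully for homozygous, by about half for
heterozygous events) and clipped read ends pile up. deepdel turns these
traces into per-position counts, classifies fixed-width reference tiles
with a neural network, and only then reconstructs exact breakpoints from
the raw signatures of the flagged tiles. The classifier therefore decides
*where to look*; coordinates always come from the deterministic heuristic,
never from the network.

## Signature tracks and normalization

Nine per-position tracks are computed once per chromosome (coverage with
`D`-consumed bases counted as covered; `D` depth; left-/right-clip
boundaries; split-segment boundaries; 10 Mbp block mean coverage; and the
short-read coverage and clip counts). Two conventions matter:

* Counting `D`-consumed positions as covered makes the deletion fraction
  `read_ld / read_lc` live in `[0, 1]` by construction — an invariant the
  tests assert on every fixture.
* Clip and split boundaries are counted at the *last aligned base* (for a
  clip on the right of the alignment) or the first aligned base (left
  clip), so every boundary count sits inside the span of the read that
  produced it. This keeps the per-position counts mutually consistent and
  shifts left-breakpoint boundaries by a single base relative to the
  half-open end — immaterial to a classifier reading 200 bp tiles.

Each tile becomes a 9 × L matrix (L = 200 bp default), z-scored per
position within the six long-read rows and, separately, the three
short-read rows. The standard deviation is the population form (divide by
group size), and a zero-variance group maps to zeros — the same encoding
as padding, so "no information" is one consistent value. Normalizing per
position rather than per matrix or genome-wide is a deliberate reading of
a per-tuple operation; it makes every column a self-contained relative
pattern (e.g. "D depth ≈ coverage") independent of absolute depth, which
is what lets one model generalise across coverages. HiFi-only mode simply
leaves the three short-read rows zero.

## Network design

The published structure of the classifier is: four convolutions, a
convolutional block attention module (CBAM), a bidirectional GRU over
consecutive tiles, and a three-layer fully connected head with a sigmoid.
Within that structure several details are open, and we fixed them as
follows:

* **Convolution layout.** The nine signature rows are heterogeneous count
  features in an arbitrary order, not a spatial axis, so we convolve
  1-dimensionally along the tile length with the rows as input channels
  (kernels 1 × 3; channels 32→32→64→64; max-pool 2 along the length after
  blocks 2 and 4; CBAM after block 4). Convolving *across* feature rows
  would make the model depend on a meaningless row ordering; the
  channel reading is the standard design for genomics sequence CNNs and
  is ~25× cheaper, which keeps single-CPU training honest. With this
  layout the CBAM spatial attention is a 1-D map over tile positions.
* **CBAM.** Channel gate: average- and max-pooled channel descriptors
  through a shared bottleneck MLP (reduction 8), summed, sigmoid. Spatial
  gate: channel-wise mean and max maps, a width-7 convolution, sigmoid.
  Both gates are strictly inside (0, 1); composition order (channel, then
  spatial) is asserted against a literal two-step evaluation in the tests.
* **Recurrence.** "Two 64 pairs" of GRUs is read as one bidirectional
  layer with 64 hidden units per direction (depth is configurable via
  `gru_layers`). The GRU consumes the flattened trunk features of
  `seq_len = 25` consecutive tiles (5 kb of genome) — long enough that a
  multi-tile deletion and its flanks fit in one sequence, small enough for
  CPU training. Forward and backward passes are written directly on BLAS
  matrix products; gradients of every block are checked against central
  finite differences in the test suite.
* **Head and loss.** 128 → 64 → 1 with dropout 0.4 after the first two
  layers; binary cross-entropy; Adam at 1e-3, batches of 8 sequences,
  all randomness under one seed (bitwise-reproducible training on CPU).
* **Class balance.** Deletion tiles are a small minority of the genome.
  Training keeps every sequence containing a positive tile and samples
  negative-only sequences at a 1:1 ratio; all tiles are scored at
  inference.

The genotype network reuses the trunk and attention (no recurrence) with
the same head, trained on tiles overlapping known deletions with labels
1 = homozygous, 0 = heterozygous.

## Two-pass prediction

A deletion centred on a tile boundary splits its evidence between two
tiles and can fall below threshold in both. The second pass re-tiles the
chromosome shifted by `L/2` (100 bp); any shifted positive flags both
main-grid tiles it overlaps, and the flag set is the union — monotone in
both passes and a superset of the first pass. Probabilities are not
averaged across passes; a flagged tile carries the maximum probability
that flagged it. Both passes use the same 0.5 threshold.

## Breakpoint refinement and its tie-breaks

* CIGAR signatures: `D` ops strictly longer than 30 bp whose start is
  strictly within 200 bp of the flagged tile's start. A `D` op starting
  shortly *before* the tile also satisfies the inequality and is
  admitted — the filter is a distance, not a containment test. Same-read
  signatures separated by less than 20 bp merge into one.
* Split signatures: segments are taken per record with query coordinates
  recovered from the clip lengths (hard clips count like soft clips),
  expressed in the reference orientation of the read, i.e. the leading
  SAM clips for either strand — equivalent to flipping as-sequenced
  coordinates, and exactly the frame in which split segments are
  collinear with the reference. `Distance > 40` (strict) emits a
  signature at `(ref1_end, ref1_end + Distance)`.
* Clustering: signatures sorted by (chrom, start); a signature joins the
  open cluster iff both |Δstart| ≤ 1500 and |Δend| ≤ 1500 against the
  *most recent* member. On realistically separated clusters this equals
  all-pairs transitive closure (asserted on randomized sets); chaining is
  kept because it is single-pass and deterministic.
* Summary: lower median of starts (for even counts the smaller central
  value — deterministic), lower median of lengths, end = start + length.
  Calls need ≥ `min_support` distinct reads (a read contributing both a
  CIGAR and a split signature counts once) and length ≥ 50 bp.
* All printed inequalities are strict; exactly 40 bp distance, exactly
  30 bp `D`, or exactly 0.5 probability do not fire. A genotype vote tie
  (including an exact 0.5) resolves to 0/1, the conservative call.
* Argmax ties inside the attention poolings take the first index, so
  eval-mode forward passes are bit-reproducible.

`min_support` defaults to 3, appropriate for ~30× long-read coverage;
for very deep (≈ 70×) data raise it to ~10, for ≤ 5× lower it to 2 —
support scales with how many reads span a true event.

# What the simulator emulates — and what it does not

`simulate_genome()` plants non-overlapping deletions (one per equal slot
of the reference, ≥ 50 bp apart by construction), homozygous on both
haplotypes or heterozygous on a random one. Long reads (clipped normal
lengths, mean 8 kb like a typical error-prone long-read library; default
30×) are drawn uniformly per haplotype; a read spanning a deletion
≤ `d_op_max` (1 kb) carries an interior `D` op of exactly that size,
larger deletions become a soft-clipped primary plus hard-clipped
supplementary whose split distance equals the deletion length, and
sub-30 bp terminal anchors become breakpoint clips. Short 250 bp pairs
(default 40×, echoing a 2 × 250 bp sequencing-by-synthesis library) clip
exactly at junctions. Substitution errors (default 2%) are injected into
the sequences.

Deliberately absent: alignment ambiguity (alignments are synthesised, not
produced by an aligner), indel sequencing errors inside CIGARs, D-op
fragmentation and placement jitter around true breakpoints, SNPs,
repeats, mapping-quality variation, and coverage biases. Consequently the
simulator's signatures are geometrically *exact*, and passing the
round-trip at high precision/recall demonstrates that the pipeline's
logic is correct and self-consistent — not that the trained weights
transfer to real libraries, where breakpoint scatter and spurious
signatures in repeats are the dominant error sources. On real data the
network must be retrained on a matched truth set, and precision hinges on
the support filter far more than it does here.

# Problem sizes and numerical choices

The package's standard validation study (also run by
`scripts/acceptance.R`) uses a 2 Mbp reference with 40 deletions of
50–5,000 bp (half heterozygous), 30× long plus 40× short reads at 2%
base error; networks train for up to 15 epochs on the first half of the
chromosome and call the whole chromosome. These sizes give every size
class several events and each event tens of supporting reads while a
complete study (simulation, featurization, training, two-pass prediction,
refinement, genotyping, evaluation) runs in minutes on one CPU.
Noise-free exactness uses 20 homozygous deletions of
{60, 100, 300, 800, 2000, 5000} bp on 800 kb at 30×, where recovery must
be exact to the base — sizes straddling `d_op_max` so both signature
paths are exercised.

Other numerics: convolution padding is zero ("same" output length);
max-pool on an odd length drops the trailing column; BCE uses an 1e-12
clamp inside the logs; weight init is He (convolutions, dense) and
uniform ±1/√h (GRU); the im2col gather indices are cached per tensor
shape, which is why prediction runs in fixed-size chunks.

# Known limitations

* Deletions only — no insertions, inversions, duplications,
  translocations, and no inter-chromosomal or inverted split handling.
* Single-sample, single-chromosome-at-a-time processing; whole-chromosome
  signature tracks are held densely in memory (about 150 MB per 2 Mbp ×
  9 tracks of doubles; a human chromosome would need a windowed variant).
* No genotype class for reference-homozygous (a call is 0/1 or 1/1).
* The two trained networks are desk-scale (≈ 1.2 M parameters); no GPU
  path is provided or needed at these sizes.
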
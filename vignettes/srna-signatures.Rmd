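---
title: "Detecting small-RNA biogenesis signatures: methods and design notes"
author: "srnasig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting small-RNA biogenesis signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnasig)
```

## The problem

Animal small-RNA silencing runs through three pathways that leave distinct
fingerprints in genome-aligned sRNA-seq reads.  miRNAs and siRNAs are Dicer
products, 18–24 nt; because Dicer is an RNase III enzyme, an siRNA duplex
carries 2-nt 3′ overhangs at *both* ends, so the two strands of a duplex
align as an opposite-strand read pair with a characteristic offset.  piRNAs
are Dicer-independent, 26–30 nt, and arise either through the Ping-Pong
amplification loop — which pairs reads on opposite strands with exactly
10 nt of 5′–5′ overlap and biases responders toward adenine at position 10 —
or through Zucchini phasing, which chops a transcript head to tail into 1U
reads, so that a phased read's 5′ end sits at distance 1 from the 3′ end of
the alignment upstream of it.  Scoring these geometries tells you which
pathways a species actually runs, which in turn decides what kind of RNAi
trigger can silence genes in it.  `srnasig` implements those scores, the
locus annotation built on them, and a simulator that plants each geometry
with known truth.

All coordinates in the package are 0-based half-open; a read's 5′ end is
`start` on the plus strand and `end − 1` on the minus strand.  Read
nucleotides are reported in the RNA alphabet (T as U), taken from the
read-oriented sequence; on the minus strand that is the reverse complement
of the aligner-stored field.

## The three statistics

**Dicer-pair percent.**  A qualifying pair is a plus read $p$ and minus read
$m$, same chromosome, both within the Dicer window (default 20–24 nt), with
$p_{start} - m_{start} = 2$ and $p_{end} - m_{end} = 2$.  Requiring the
offset at both ends forces equal-length partners and is the strict reading
of RNase III geometry; `both_ends = FALSE` relaxes to either end for
sensitivity analyses.  The reported value is
$100 \cdot \#\{\text{alignments in} \ge 1 \text{ qualifying pair}\} /
\text{total alignments}$.  Counting alignment membership rather than pairs
keeps the statistic a true percentage (a pair count can exceed the number of
alignments on deep stacks); this choice matters only in degenerate corners
and is fixed here once.  Identical-coordinate duplicates each count — the
denominator is total alignments, and collapsing the numerator but not the
denominator would bias the percent down.

**Ping-Pong overlap histogram.**  For every opposite-strand pair the 5′–5′
overlap is $o = m_5 - p_5 + 1$, accumulated for $1 \le o \le 30$, once per
pair.  The Ping-Pong loop enriches $o = 10$.

**Phasing distance histogram.**  For each 1U read $w$ the nearest upstream
alignment $u$ on the same strand (largest 3′ end not passing $w$'s 5′ end;
on the minus strand "upstream" is rightward and everything mirrors) gives
$d = w_{start} - u_{end} + 1$, accumulated for $1 \le d \le 9$.
Head-to-tail adjacency is $d = 1$.  Pairing each downstream read with its
nearest upstream only — rather than all upstream alignments in range —
prevents deep stacks from contributing quadratically many pairs; the range
1–9 keeps the histogram within one read length of the cut site.

**Focal-bin z-score.**  For either histogram,
$z = (c_{focal} - \bar c_{bg}) / \sigma_{bg}$, where the background is every
non-focal bin in range and $\sigma$ uses the population ($n$) denominator.
If $\sigma_{bg} = 0$ (common for clean planted loci whose non-focal bins are
all zero) the score is 0 when the focal bin equals the background mean and
$\pm$`cap` (default 10) otherwise; fewer than 3 background bins is an error.
The definition is symmetric, cheap and self-contained; it is deliberately
not a model-based test (see Limitations).

A size histogram over 15–30 nt complements the pair statistics, with bands
degradation (< 18), Dicer products (18–24) and piRNA (26–30); length 25
belongs to no band and counts only toward the total — keeping a deliberate
gap between the Dicer and piRNA bands avoids contaminating either with the
boundary length.

## Locus annotation and the threshold sweep

Regions are maximal intervals of strand-pooled coverage ≥ 1 (loci are
strand-agnostic features; both piRNA pathways produce reads on both
strands), merged when separated by at most the merge distance, annotated
with read counts by 5′-end containment (a boundary-straddling read belongs
to exactly one locus, the one holding its 5′ end), and filtered at
`rpm >= min_rpm` inclusive, with RPM = count / total alignments × 10⁶.  The
operating-point defaults are a 500 bp merge and ≥ 1000 RPM.  Because the
right operating point depends on sequencing depth and genome contiguity,
`threshold_sweep()` evaluates the full grid
{0, 5, 50, 500, 5000, 50000} bp × {0, 1, 10, 100, 10³, 10⁴, 10⁵, 10⁶} RPM
from a single region-calling pass, reporting locus count and genome
fraction per cell; the depth axis is interpreted in RPM units so the grid
transfers across libraries of different depth.  Three monotonicity
properties hold by construction and are enforced in the tests: locus count
is non-increasing in the RPM threshold, genome fraction is non-decreasing in
merge distance and non-increasing in the RPM threshold.

RPM thresholds assume realistic totals: at a desk-scale total of a few
hundred alignments a single read already clears 1000 RPM, so toy analyses
should either raise the threshold or read it as "reads per million, had
there been a million".

## Locus classification

Each locus gets its 16-column read-length profile (rows sum to the locus
read count), row-Z-normalised for display with population sd and
constant-row → zeros, ordered by average-linkage Euclidean hierarchical
clustering (deterministic; ties break toward lower row index), and two
per-locus signature z-scores computed on its own reads.  Loci with fewer
than 10 reads get `NA` z-scores — a 30-bin histogram over a handful of reads
is noise.  Labels, in precedence order:

1. **piRNA-like**: piRNA-band fraction ≥ 0.5 *and* (Ping-Pong z ≥ 2 or
   phasing z ≥ 2) — size alone is not enough, a biogenesis signature is
   required, mirroring how candidate piRNA loci are selected by size plus a
   high Ping-Pong z;
2. **dicer-product-like**: Dicer-band fraction ≥ 0.5 (miRNA-like loci land
   here too: genomically, both arms of a hairpin align to one strand, so no
   duplex geometry and no signature is expected);
3. **degradation-like**: < 18 nt fraction ≥ 0.5;
4. **ambiguous** otherwise.

The z cut-off of 2 and the 0.5 band fractions are configurable; 2 is the
usual "two sigmas" screen and 0.5 makes the bands mutually exclusive at the
default precedence.

## Quantification

`count_matrix()` counts per-locus reads across libraries (optionally only
the 26–30 nt band, the right view when comparing piRNA expression
specifically), `normalize_counts()` adds RPM and `log2(rpm + 1)` views
(pseudocount 1 maps zero counts to exactly 0), and `pca_coords()` returns
column-centred principal components of the libraries with each component's
sign fixed by its largest-magnitude loading, so coordinates are reproducible
to the byte.  Differential expression is deliberately delegated: the package
exports lossless TSV counts and a naive RPM fold change, and leaves
model-based inference to dedicated negative-binomial tools.

## The simulator

`simulate_library()` builds a uniform-random A/C/G/T genome, plants each
requested locus, edits the genome bases that the planted composition implies
(a read's first nt is U exactly when the genomic base at its 5′ position is
T on plus / A on minus), adds uniformly placed background reads with
Bernoulli(0.5) strands, and extracts every read's sequence from the final
genome.  Planted classes and their defaults:

* `dicer_duplex` — equal-length plus/minus pairs, 20–24 nt, minus mate
  shifted 2 nt at both boundaries; pair anchors drawn *without replacement*
  within the locus width, so no two planted duplexes can accidentally form
  an extra qualifying pair and the manifest's pair count is exact by
  construction.
* `pingpong_pirna` — opposite-strand pairs, 26–30 nt, 5′ overlap exactly 10.
  The 10-nt overlap makes the initiator's 1U base and the responder's 10A
  base the *same* genomic position (and symmetrically for the other strand),
  so `u1_prob` and `a10_prob` cannot be satisfied independently; the shared
  base is set to the U-equivalent with probability `max(u1_prob, a10_prob)`
  (defaults 0.9/0.8).  At high pair density within one locus, base edits of
  neighbouring pairs can overwrite one another, mildly diluting the realised
  composition bias — the geometry, which is what the scans score, is never
  affected.
* `phased_pirna` — one head-to-tail trail of 26–30 nt reads on one strand;
  each read's first base drawn U with `u1_prob` (default 0.9); the manifest
  records exactly how many adjacent 1U joints were realised.
* `mirna_like` — reads stacked at two 5′ positions (mature and star arms,
  70/30 split, 15 bp loop gap) on a single strand, 21–23 nt.
* `degradation` — 15–17 nt reads scattered uniformly in a 300 bp span.

Planted loci may not overlap unless `allow_overlap = TRUE`, keeping manifest
truth unambiguous.  Everything is drawn from one seeded RNG stream, so
(config, seed) → byte-identical libraries, manifests and files.  The
simulator writes genome FASTA, unsorted SAM, a BED6 dialect carrying the 5′
nucleotide in the name column, a JSON manifest and the YAML config.

What the simulator emulates is the *geometry and composition* of biogenesis
signatures over a uniform background.  It does not model sequencing error,
adapter remnants, quality scores, multimapping ambiguity, transposon
structure, expression-level distributions across loci, or inter-individual
locus usage (a null model for the last of these is not well constrained and
is left as an explicit non-goal).  Passing tests therefore demonstrate that
the statistics recover planted geometry correctly — not that real libraries
are this clean.

## Study conditions used by the tests and acceptance script

Chosen once as realistic desk-scale analogues and then fixed: null and
contrast libraries are 2,000 alignments with lengths uniform on 15–30 nt on
a 50 kb chromosome (a null library for signature calibration must contain
piRNA- and siRNA-sized reads; the 15–17 nt default range emulates
degradation, not a null library).  Signal conditions plant 200 pairs (or 200
phased reads) over a background of 10× the signal read count.  The
five-percent contrast library plants 100 duplex alignments among 2,000.
Classification runs use 100 loci, 60 reads each, in 8 kb slots across four
220 kb chromosomes with 600 background reads — slot spacing keeps planted
loci from merging at the 500 bp operating point, and bridging chains of
background reads are rare at that density.  Oracle-equivalence checks run 50
libraries of 200–500 reads on deliberately small (3 kb) chromosomes so that
coordinate collisions, duplicate reads and deep stacks actually occur.

## Numerical choices and degenerate inputs

* Population (n-denominator) sd in both the z-score and row normalisation;
  constant rows normalise to zeros rather than NaN.
* sd = 0 z-scores cap at ±10; the cap is configurable and is reported
  as-is, not as infinity, so JSON output stays finite.
* An empty library is a valid input everywhere except where the statistic
  is undefined (Dicer percent, nucleotide bias), which error explicitly.
* Reads shorter than a requested bias position leave the denominator.
* `merge_regions` is idempotent; merge distance 0 unites touching regions.
* All outputs are deterministic; pipeline reruns are byte-identical
  (artifact files carry no timestamps).

## Known limitations

* The focal-bin z-score is computed against an *empirical* background sd
  estimated from 8 (phasing) or 29 (Ping-Pong) bins, so under a pure null
  its tails are heavier than standard normal (a $t$-like inflation of
  roughly $\sqrt{(k+1)/(k-1)}$ for $k$ background bins); |z| slightly above
  2 on a null library is therefore more common than the normal 5%, and the
  phasing statistic is additionally biased upward at high read density
  because nearest-upstream distances decay geometrically even for uniform
  reads.  The acceptance script reports the measured null calibration rates;
  treat z ≥ 3 as a detection screen, not a calibrated p-value.
* Multimapped reads count once per reported primary alignment, unweighted;
  no 1/n-hits weighting is applied (upstream mappers differ in what they
  report, and no weighting scheme is canonical).  Secondary and
  supplementary alignments are dropped on load.
* Clipped, gapped and spliced alignments are excluded rather than
  interpreted.
* No hairpin-folding validation of miRNA-like loci and no transposon
  annotation of piRNA loci; classification is by read geometry alone.
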
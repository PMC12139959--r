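# srnasig

Small-RNA biogenesis signatures, locus annotation and library simulation.

`srnasig` is for researchers surveying which small-RNA silencing pathways
(miRNA/siRNA vs piRNA) are active in a species from genome-aligned sRNA-seq
data — the typical situation in non-model animals such as mollusks, where the
presence or absence of an endogenous siRNA pathway decides whether long-dsRNA
RNAi is even worth attempting.  It takes ungapped genomic alignments of
15–30 nt reads (SAM/BAM) and answers, with tested statistics rather than
eyeballing:

* **Are Dicer duplex products present?**  RNase III cleavage leaves 2-nt 3′
  overhangs on both ends of an siRNA duplex.  For a plus-strand read *p* and
  minus-strand read *m* on the same chromosome, both 20–24 nt, the package
  scores the pair when

  `p.start − m.start = 2  and  p.end − m.end = 2`

  and reports `100 · #{alignments in ≥ 1 qualifying pair} / total alignments`
  — an siRNA-bearing library scores percent-scale values, a library without
  an siRNA pathway scores near zero.
* **Is there piRNA Ping-Pong amplification?**  Histogram of 5′–5′ overlaps
  `o = m₅ − p₅ + 1` of opposite-strand pairs; the amplification loop enriches
  `o = 10`.  The focal-bin z-score is
  `z = (c₁₀ − mean(c_bg)) / sd_pop(c_bg)` over the non-focal bins.
* **Is there Zucchini phasing?**  Histogram of distances
  `d = w.start − u.end + 1` from each 1U read *w* to its nearest upstream
  alignment *u* (strand-aware); head-to-tail trails enrich `d = 1`, scored
  with the same z.
* **Where are the sRNA-producing loci, and what do they make?**  Coverage →
  merge adjacent features (operating point 500 bp) → keep loci ≥ 1000 RPM,
  with the full merge-distance × depth threshold sweep over
  {0, 5, 50, 500, 5000, 50000} bp × {0 … 10⁶} RPM; per-locus read-size
  profiles (Z-normalised, hierarchically ordered) and per-locus signature
  z-scores classify each locus as piRNA-like, dicer-product-like,
  degradation-like or ambiguous.
* **How do libraries compare?**  Per-locus count matrices across libraries
  (optionally 26–30 nt reads only), RPM/log2 views, deterministic PCA
  coordinates, and TSV export for model-based differential expression done
  elsewhere.

Because real surveys need multi-gigabyte downloads, the package ships a
simulator that plants loci of each biogenesis class — Dicer duplexes,
Ping-Pong pairs, phased 1U trails, miRNA-like stacks, degradation noise — in
toy genomes, with a ground-truth manifest, so the whole pipeline is testable
offline.

## Worked example

Simulate a 50 kb chromosome carrying a Ping-Pong locus, a phased-piRNA
trail and a miRNA-like stack over sparse degradation background, then run
the stages:

```r
library(srnasig)

cfg <- sim_config(
  n_chroms = 1, chrom_length = 50000, seed = 7,
  loci_specs = list(
    planted_locus("pingpong_pirna", chrom = "chr1", anchor = 8000,  n_reads = 100),
    planted_locus("phased_pirna",   chrom = "chr1", anchor = 20000, n_reads = 50),
    planted_locus("mirna_like",     chrom = "chr1", anchor = 30000, n_reads = 40)),
  background_reads = 60)
sim <- simulate_library(cfg)

size_distribution(sim$library)
#> <size_histogram> 250 reads: 60 degradation (<18), 40 Dicer-sized (18-24), 150 piRNA-sized (26-30)
#> 15 16 17 18 19 20 21 22 23 24 25 26 27 28 29 30
#> 22 21 17  0  0  0 16 14 10  0  0 30 29 23 31 37

dicer_pair_fraction(sim$library)
#> [1] 0
overlap_histogram(sim$library)
#> <ping-pong signature histogram> focal bin 10, z = 41.81
phasing_histogram(sim$library)
#> <phasing signature histogram> focal bin 1, z = 28.15
```

No Dicer duplexes were planted, so the duplex percent is exactly 0 while
both piRNA signatures light up (counts concentrate at overlap 10 and
distance 1; z-scores of 41.8 and 28.2 against the non-focal bins).  Annotate
and classify loci at the standard operating point:

```r
lib  <- sim$library
loci <- rpm_filter(annotate_loci(merge_regions(call_regions(lib), 500), lib),
                   min_rpm = 1000)
cl   <- classify_loci(locus_size_matrix(loci, lib),
                      per_locus_signatures(loci, lib))
subset(as.data.frame(cl), !is.na(pingpong_z))[,
  c("locus_id", "pirna_frac", "dicer_frac", "pingpong_z", "phasing_z", "label")]
#>       locus_id pirna_frac dicer_frac pingpong_z phasing_z              label
#> 6  locus_00006  0.9803922  0.0000000 42.4506777  0.940647         piRNA-like
#> 16 locus_00016  0.9090909  0.0000000 -0.1889822 10.000000         piRNA-like
#> 22 locus_00022  0.0000000  0.9302326  0.0000000  0.000000 dicer-product-like
```

All three planted loci are recovered with the right label: the Ping-Pong
locus by its overlap z, the phased trail by its distance-1 z (here the
degenerate-background cap of 10, since all other distance bins are empty),
and the miRNA-like stack by its 18–24 nt size profile with flat signatures.
The remaining called loci are single background reads — at a 250-alignment
desk-scale total, one read is already 4000 RPM, a reminder that RPM
thresholds are meaningful only relative to library depth.

`run_pipeline(pipeline_config(...))` chains the same stages from files to
files (stats JSON, loci BED, classes TSV, counts TSV, optional sweep TSV),
writes the resolved configuration next to the outputs, and is byte-identical
on reruns; `inst/scripts/run-pipeline.R` wraps it for the shell.

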
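# Independent brute-force oracles: O(n^2) enumerations over all read pairs,
# deliberately sharing no code with the package's keyed/sorted scans.

oracle_dicer_percent <- function(lib, min_len = 20, max_len = 24,
                                 overhang = 2) {
  r <- lib$reads
  p <- which(r$strand == "+" & r$length >= min_len & r$length <= max_len)
  m <- which(r$strand == "-" & r$length >= min_len & r$length <= max_len)
  member <- logical(nrow(r))
  if (length(p) && length(m)) {
    hit <- outer(r$chrom[p], r$chrom[m], "==") &
      (outer(r$start[p], r$start[m], "-") == overhang) &
      (outer(r$end[p], r$end[m], "-") == overhang)
    member[p] <- rowSums(hit) > 0
    member[m] <- colSums(hit) > 0
  }
  100 * sum(member) / lib$total_alignments
}

oracle_overlap_hist <- function(lib, max_overlap = 30) {
  r <- lib$reads
  counts <- integer(max_overlap)
  p <- which(r$strand == "+")
  m <- which(r$strand == "-")
  for (i in p) for (j in m) {
    if (r$chrom[i] != r$chrom[j]) next
    o <- r$five_prime[j] - r$five_prime[i] + 1L
    if (o >= 1L && o <= max_overlap) counts[o] <- counts[o] + 1L
  }
  counts
}

oracle_phasing_hist <- function(lib, max_dist = 9) {
  r <- lib$reads
  counts <- integer(max_dist)
  for (i in which(r$first_nt == "U")) {
    same <- which(r$chrom == r$chrom[i] & r$strand == r$strand[i])
    if (r$strand[i] == "+") {
      ups <- same[r$end[same] <= r$start[i]]
      if (!length(ups)) next
      d <- r$start[i] - max(r$end[ups]) + 1L
    } else {
      ups <- same[r$start[same] >= r$end[i]]
      if (!length(ups)) next
      d <- min(r$start[ups]) - r$end[i] + 1L
    }
    if (d >= 1L && d <= max_dist) counts[d] <- counts[d] + 1L
  }
  counts
}

oracle_zscore <- function(counts, focal, cap = 10) {
  bg <- counts[-focal]
  m <- mean(bg)
  s <- sqrt(sum((bg - m)^2) / length(bg))
  if (s == 0) {
    if (counts[focal] == m) 0 else sign(counts[focal] - m) * cap
  } else (counts[focal] - m) / s
}

# Per-base coverage array scan for region calling.
oracle_regions <- function(lib, min_cov = 1) {
  r <- lib$reads
  out <- list()
  for (chrom in sort(unique(r$chrom))) {
    g <- r[r$chrom == chrom, , drop = FALSE]
    cov <- integer(max(g$end))
    for (i in seq_len(nrow(g)))
      cov[(g$start[i] + 1L):g$end[i]] <- cov[(g$start[i] + 1L):g$end[i]] + 1L
    runs <- rle(cov >= min_cov)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    sel <- which(runs$values)
    if (length(sel))
      out[[chrom]] <- data.frame(chrom = chrom, start = starts[sel] - 1L,
                                 end = ends[sel])
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Random read set builder for oracle comparisons (built directly, not via the
# simulator, so oracle tests do not depend on simulator correctness).
random_library <- function(n, seed, chrom_len = 4000, n_chroms = 2,
                           len_range = c(15, 30), u_frac = 0.25) {
  set.seed(seed)
  len <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  start <- floor(runif(n) * (chrom_len - len))
  srna_library(data.frame(
    chrom = paste0("chr", sample.int(n_chroms, n, replace = TRUE)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    start = as.integer(start), end = as.integer(start + len),
    first_nt = sample(c("U", "A", "C", "G"), n, replace = TRUE,
                      prob = c(u_frac, rep((1 - u_frac) / 3, 3)))))
}

# Mixed-class 100-locus simulation used by the classification checks.
mixed_class_sim <- function(seed, n_loci = 100, n_reads = 60) {
  cls <- rep(c("dicer_duplex", "pingpong_pirna", "phased_pirna",
               "mirna_like", "degradation"), length.out = n_loci)
  base <- sim_config(n_chroms = 4, chrom_length = 220000, seed = seed)
  simulate_library(sim_config(
    n_chroms = 4, chrom_length = 220000, seed = seed,
    loci_specs = layout_locus_specs(cls, base, n_reads = n_reads,
                                    slot = 8000),
    background_reads = 600))
}

classify_sim <- function(sim, merge_distance = 500, min_rpm = 1000) {
  lib <- sim$library
  loci <- rpm_filter(annotate_loci(merge_regions(call_regions(lib),
                                                 merge_distance), lib),
                     min_rpm = min_rpm)
  cl <- classify_loci(locus_size_matrix(loci, lib),
                      per_locus_signatures(loci, lib))
  list(loci = loci, classes = cl,
       accuracy = classification_accuracy(sim$manifest, loci, cl))
}
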
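#' Per-locus read-size matrix
#'
#' Cell `(l, s)` is the number of reads of length `s` whose 5' end lies in
#' locus `l`; row sums equal the loci's read counts.  Rows are loci
#' (rownames = locus ids), columns read lengths 15-30.
#'
#' @param loci sorted `srna_loci`; loci must be pairwise disjoint.
#' @param library the [srna_library].
#' @param lengths length columns (default 15:30).
#' @return Integer matrix.
#' @export
locus_size_matrix <- function(loci, library, lengths = 15:30) {
  stopifnot(inherits(library, "srna_library"))
  m <- matrix(0L, nrow = nrow(loci), ncol = length(lengths),
              dimnames = list(loci$locus_id, lengths))
  if (!nrow(loci)) return(m)
  for (chrom in unique(loci$chrom)) {
    l <- loci[loci$chrom == chrom, , drop = FALSE]
    l <- l[order(l$start), , drop = FALSE]
    if (nrow(l) > 1L && any(l$start[-1L] < l$end[-nrow(l)]))
      stopf("loci overlap on %s; size matrix requires disjoint loci", chrom)
  }
  r <- library$reads
  r <- r[r$length %in% lengths, , drop = FALSE]
  if (!nrow(r)) return(m)
  for (chrom in unique(loci$chrom)) {
    li <- which(loci$chrom == chrom)
    g <- r[r$chrom == chrom, , drop = FALSE]
    if (!nrow(g)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(g$five_prime + 1L, width = 1L),
      IRanges::IRanges(loci$start[li] + 1L, loci$end[li]))
    if (!length(hits)) next
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    tab <- table(factor(loci$locus_id[li][s], levels = rownames(m)),
                 factor(g$length[q], levels = lengths))
    m <- m + as.matrix(unclass(tab))
  }
  m
}

#' Z-normalise matrix rows
#'
#' Each row is centred and scaled to population (n-denominator) unit sd;
#' constant rows map to all zeros.
#'
#' @param m numeric matrix.
#' @return Matrix of the same shape.
#' @export
z_normalize_rows <- function(m) {
  if (!nrow(m)) return(m)
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  out <- (m - mu) / ifelse(sd_pop == 0, 1, sd_pop)
  out[sd_pop == 0, ] <- 0
  out
}

#' Hierarchical-clustering row order
#'
#' Agglomerative clustering leaf order for heatmap display.  Deterministic
#' given the input row order ([stats::hclust()] breaks ties by lower index).
#'
#' @param m numeric matrix (typically Z-normalised).
#' @param metric distance metric for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @return Integer permutation of `seq_len(nrow(m))`.
#' @export
cluster_order <- function(m, metric = "euclidean", linkage = "average") {
  if (nrow(m) < 2L) return(seq_len(nrow(m)))
  hclust(dist(m, method = metric), method = linkage)$order
}

#' Per-locus Ping-Pong and phasing z-scores
#'
#' Runs [overlap_histogram()] and [phasing_histogram()] restricted to the
#' reads of each locus (5'-end containment).  Loci with fewer than
#' `min_reads` reads get `NA` z-scores (insufficient data sentinel).
#'
#' @param loci `srna_loci`.
#' @param library the [srna_library].
#' @param min_reads minimum reads for a defined z (default 10).
#' @param max_overlap,max_dist histogram ranges.
#' @return data.frame: `locus_id`, `n_reads`, `pingpong_z`, `phasing_z`.
#' @export
per_locus_signatures <- function(loci, library, min_reads = 10,
                                 max_overlap = 30, max_dist = 9) {
  stopifnot(inherits(library, "srna_library"))
  res <- data.frame(locus_id = loci$locus_id,
                    n_reads = integer(nrow(loci)),
                    pingpong_z = NA_real_, phasing_z = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(loci))) {
    r <- subset_reads_5p(library, loci$chrom[i], loci$start[i], loci$end[i])
    res$n_reads[i] <- nrow(r)
    if (nrow(r) < min_reads) next
    sub <- srna_library(r, total_alignments = library$total_alignments)
    res$pingpong_z[i] <- overlap_histogram(sub, max_overlap = max_overlap)$z
    res$phasing_z[i] <- phasing_histogram(sub, max_dist = max_dist)$z
  }
  res
}

#' Classify loci by size profile and signature z-scores
#'
#' A locus is piRNA-like iff its piRNA-band (26-30 nt) read fraction is at
#' least `pirna_frac` and either signature z-score reaches `z_min`;
#' otherwise dicer-product-like iff the 18-24 nt fraction reaches
#' `dicer_frac`; otherwise degradation-like iff the <18 nt fraction is at
#' least 0.5; otherwise ambiguous.  `NA` z-scores never satisfy the z
#' condition.
#'
#' @param size_matrix raw per-locus size matrix ([locus_size_matrix()]).
#' @param signature_zs data.frame from [per_locus_signatures()].
#' @param pirna_frac,dicer_frac band-fraction thresholds in `[0, 1]`.
#' @param z_min signature z threshold (>= 0).
#' @return data.frame of class `locus_classification`: band fractions, both
#'   z-scores and `label`.
#' @export
classify_loci <- function(size_matrix, signature_zs, pirna_frac = 0.5,
                          dicer_frac = 0.5, z_min = 2.0) {
  if (pirna_frac < 0 || pirna_frac > 1 || dicer_frac < 0 || dicer_frac > 1)
    stopf("band-fraction thresholds must lie in [0, 1]")
  if (z_min < 0) stopf("'z_min' must be >= 0")
  lens <- as.integer(colnames(size_matrix))
  tot <- rowSums(size_matrix)
  safe_tot <- ifelse(tot == 0, 1, tot)
  frac <- function(sel) rowSums(size_matrix[, lens %in% sel, drop = FALSE]) /
    safe_tot
  out <- data.frame(
    locus_id = rownames(size_matrix),
    degradation_frac = frac(15:17),
    dicer_frac = frac(18:24),
    pirna_frac = frac(26:30),
    stringsAsFactors = FALSE)
  zi <- match(out$locus_id, signature_zs$locus_id)
  out$pingpong_z <- signature_zs$pingpong_z[zi]
  out$phasing_z <- signature_zs$phasing_z[zi]
  z_ok <- (!is.na(out$pingpong_z) & out$pingpong_z >= z_min) |
          (!is.na(out$phasing_z) & out$phasing_z >= z_min)
  label <- rep("ambiguous", nrow(out))
  label[tot > 0 & out$degradation_frac >= 0.5] <- "degradation-like"
  label[tot > 0 & out$dicer_frac >= dicer_frac] <- "dicer-product-like"
  label[tot > 0 & out$pirna_frac >= pirna_frac & z_ok] <- "piRNA-like"
  out$label <- label
  rownames(out) <- NULL
  class(out) <- c("locus_classification", "data.frame")
  out
}

#' @export
print.locus_classification <- function(x, ...) {
  cat(sprintf("<locus_classification> %d loci:\n", nrow(x)))
  print(table(x$label))
  invisible(x)
}

#' Expected classification label for a planted biogenesis class
#'
#' Both Dicer-duplex and miRNA-like loci are Dicer products by size, so both
#' map to `dicer-product-like`; the two piRNA pathways map to `piRNA-like`.
#'
#' @param class_label planted class label(s).
#' @return Character vector of expected labels.
#' @export
expected_label <- function(class_label) {
  map <- c(dicer_duplex = "dicer-product-like",
           mirna_like = "dicer-product-like",
           pingpong_pirna = "piRNA-like",
           phased_pirna = "piRNA-like",
           degradation = "degradation-like")
  unname(map[class_label])
}

#' Planted-truth classification accuracy
#'
#' Matches every planted locus of a simulation manifest to the called locus
#' containing its midpoint and compares the assigned label with
#' [expected_label()].  Unrecovered planted loci count as misclassified.
#'
#' @param manifest a `sim_manifest`.
#' @param loci called `srna_loci`.
#' @param classes [classify_loci()] result for `loci`.
#' @return List with `accuracy` (fraction correct), `n` planted loci, and the
#'   per-locus `detail` data.frame.
#' @export
classification_accuracy <- function(manifest, loci, classes) {
  pl <- manifest$loci
  if (!nrow(pl)) stopf("manifest has no planted loci")
  mid <- (pl$start + pl$end) %/% 2
  assigned <- rep(NA_character_, nrow(pl))
  for (i in seq_len(nrow(pl))) {
    hit <- which(loci$chrom == pl$chrom[i] & loci$start <= mid[i] &
                 loci$end > mid[i])
    if (length(hit) == 1L)
      assigned[i] <- classes$label[match(loci$locus_id[hit],
                                         classes$locus_id)]
  }
  expected <- expected_label(pl$class_label)
  correct <- !is.na(assigned) & assigned == expected
  list(accuracy = mean(correct), n = nrow(pl),
       detail = data.frame(locus = pl$locus, class_label = pl$class_label,
                           expected = expected, assigned = assigned,
                           correct = correct))
}
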
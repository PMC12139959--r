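#' Percent of alignments in Dicer-product duplex pairs
#'
#' RNase III enzymes leave 2-nt 3' overhangs on both ends of a small-RNA
#' duplex.  A qualifying pair is a plus-strand read `p` and a minus-strand
#' read `m` on the same chromosome, both within the Dicer size window, with
#' `p$start - m$start == overhang` and `p$end - m$end == overhang` (which
#' forces equal lengths).  The returned percent is
#' `100 * (alignments that belong to at least one qualifying pair) /
#' total_alignments`: counting alignment membership rather than pairs keeps
#' the ratio bounded by 100.  Identical-coordinate duplicates each count.
#'
#' @param library an [srna_library] (length-screened, non-empty).
#' @param pair_min_len,pair_max_len Dicer size window, default 20-24 nt.
#' @param overhang 3' overhang in nt (default 2).
#' @param both_ends require the overhang at both duplex ends (default).
#'   `FALSE` accepts a match at either end alone.
#' @return Percent in `[0, 100]`.
#' @export
dicer_pair_fraction <- function(library, pair_min_len = 20, pair_max_len = 24,
                                overhang = 2, both_ends = TRUE) {
  stopifnot(inherits(library, "srna_library"))
  if (library$total_alignments == 0L || nrow(library$reads) == 0L)
    stopf("Dicer-pair percent is undefined for an empty library")
  r <- library$reads
  inwin <- r$length >= pair_min_len & r$length <= pair_max_len
  p <- r[inwin & r$strand == "+", , drop = FALSE]
  m <- r[inwin & r$strand == "-", , drop = FALSE]
  if (nrow(p) == 0L || nrow(m) == 0L) return(0)
  if (both_ends) {
    pk <- paste(p$chrom, p$start, p$end)
    mk <- paste(m$chrom, m$start + overhang, m$end + overhang)
    n_member <- sum(pk %in% mk) + sum(mk %in% pk)
  } else {
    ps <- paste(p$chrom, p$start); pe <- paste(p$chrom, p$end)
    ms <- paste(m$chrom, m$start + overhang); me <- paste(m$chrom, m$end + overhang)
    n_member <- sum(ps %in% ms | pe %in% me) + sum(ms %in% ps | me %in% pe)
  }
  100 * n_member / library$total_alignments
}

.new_signature_histogram <- function(counts, bins, focal, type, cap = 10) {
  names(counts) <- bins
  z <- if (length(bins) >= 4L && focal %in% bins)
    signature_zscore(counts, focal = focal, cap = cap) else NA_real_
  structure(list(counts = counts, focal = focal, z = z, type = type),
            class = "signature_histogram")
}

#' 5'-5' overlap histogram of opposite-strand read pairs (Ping-Pong)
#'
#' For every opposite-strand pair on the same chromosome the overlap is
#' `o = minus$five_prime - plus$five_prime + 1`; `counts[o]` is incremented
#' once per pair for `1 <= o <= max_overlap`.  piRNA Ping-Pong amplification
#' enriches `o = 10`.
#'
#' @param library an [srna_library].
#' @param max_overlap largest overlap tracked (default 30).
#' @param focal focal bin for the z-score (default 10).
#' @return A `signature_histogram` with elements `counts`, `focal`, `z`.
#' @export
overlap_histogram <- function(library, max_overlap = 30, focal = 10) {
  stopifnot(inherits(library, "srna_library"))
  r <- library$reads
  counts <- integer(max_overlap)
  for (chrom in unique(r$chrom)) {
    p5 <- r$five_prime[r$chrom == chrom & r$strand == "+"]
    m5 <- r$five_prime[r$chrom == chrom & r$strand == "-"]
    if (!length(p5) || !length(m5)) next
    tp <- table(p5); tm <- table(m5)
    pp <- as.integer(names(tp)); pm <- as.integer(names(tm))
    np <- as.integer(tp); nm <- as.integer(tm)
    for (o in seq_len(max_overlap)) {
      j <- match(pp + o - 1L, pm)
      hit <- !is.na(j)
      if (any(hit)) counts[o] <- counts[o] + sum(np[hit] * nm[j[hit]])
    }
  }
  .new_signature_histogram(counts, seq_len(max_overlap), focal, "ping-pong")
}

#' Distance histogram from upstream alignments to downstream 1U reads
#' (phasing)
#'
#' Zucchini-phased piRNAs are arranged head to tail: the 5' end of a 1U read
#' sits immediately after the 3' end of the upstream alignment.  For each
#' same-strand, same-chromosome 1U read `w`, the nearest upstream alignment
#' `u` (largest 3' end not passing `w`'s 5' end, strand-aware) contributes
#' `d = w$start - u$end + 1` on the plus strand (mirrored on minus), counted
#' for `1 <= d <= max_dist`; head-to-tail adjacency gives `d = 1`.  Each
#' downstream read pairs with its nearest upstream alignment only, which
#' avoids quadratic inflation over deep stacks.
#'
#' @param library an [srna_library].
#' @param max_dist largest distance tracked (default 9).
#' @param focal focal bin for the z-score (default 1).
#' @return A `signature_histogram`.
#' @export
phasing_histogram <- function(library, max_dist = 9, focal = 1) {
  stopifnot(inherits(library, "srna_library"))
  r <- library$reads
  counts <- integer(max_dist)
  if (nrow(r)) for (chrom in unique(r$chrom)) {
    for (str in c("+", "-")) {
      g <- r[r$chrom == chrom & r$strand == str, , drop = FALSE]
      if (nrow(g) < 2L) next
      if (str == "+") {
        u_end <- g$end
        w_pos <- g$start[g$first_nt == "U"]
      } else {
        # mirror: transcript runs right to left
        u_end <- -g$start
        w_pos <- -g$end[g$first_nt == "U"]
      }
      if (!length(w_pos)) next
      se <- sort(unique(u_end))
      idx <- findInterval(w_pos, se)
      has_up <- idx >= 1L
      d <- w_pos[has_up] - se[idx[has_up]] + 1L
      d <- d[d >= 1L & d <= max_dist]
      if (length(d)) counts <- counts + tabulate(d, nbins = max_dist)
    }
  }
  .new_signature_histogram(counts, seq_len(max_dist), focal, "phasing")
}

#' Focal-bin z-score of a signature histogram
#'
#' `z = (counts[focal] - mean(background)) / sd(background)` where the
#' background is every non-focal bin in the histogram's range and the sd uses
#' the population (n) denominator.  Degenerate backgrounds (sd 0) yield 0
#' when the focal bin equals the background mean and `+/-cap` otherwise.
#'
#' @param hist a `signature_histogram` or a named/plain numeric vector of bin
#'   counts (names taken as bin labels, else `1:length`).
#' @param focal focal bin label (defaults to the histogram's own).
#' @param cap magnitude assigned when the background sd is zero but the focal
#'   bin differs from the background mean (default 10).
#' @return The z-score (scalar).
#' @export
signature_zscore <- function(hist, focal = NULL, cap = 10) {
  if (inherits(hist, "signature_histogram")) {
    counts <- hist$counts
    focal <- focal %||% hist$focal
  } else counts <- hist
  if (is.null(names(counts))) names(counts) <- seq_along(counts)
  if (is.null(focal)) stopf("'focal' bin must be given")
  fi <- match(as.character(focal), names(counts))
  if (is.na(fi)) stopf("focal bin '%s' not present in histogram", focal)
  bg <- counts[-fi]
  if (length(bg) < 3L)
    stopf("z-score needs at least 3 background bins (got %d)", length(bg))
  m <- mean(bg)
  s <- sqrt(mean((bg - m)^2))
  d <- counts[[fi]] - m
  if (s == 0) {
    if (d == 0) 0 else sign(d) * cap
  } else unname(d / s)
}

#' @export
print.signature_histogram <- function(x, ...) {
  cat(sprintf("<%s signature histogram> focal bin %d, z = %s\n", x$type,
              x$focal, format(x$z, digits = 4)))
  print(x$counts)
  invisible(x)
}

#' @export
plot.signature_histogram <- function(x, ...) {
  cols <- ifelse(names(x$counts) == as.character(x$focal), "firebrick",
                 "grey55")
  barplot(x$counts, col = cols, border = NA,
          xlab = if (x$type == "ping-pong") "5'-5' overlap (nt)"
                 else "distance to upstream alignment (nt)",
          ylab = "pairs",
          main = sprintf("%s signature (z = %.2f)", x$type, x$z), ...)
  invisible(x)
}

#' Nucleotide bias at a read position
#'
#' Fraction of reads whose nucleotide at 1-based position `position` (from
#' the 5' end) equals `nt`: position 1 against U measures the 1U bias of
#' primary/phased piRNAs, position 10 against A the 10A bias of Ping-Pong
#' responders.  Reads shorter than `position` are excluded from the
#' denominator.
#'
#' @param reads an [srna_library] or its reads data.frame (sequences
#'   required for positions beyond 1).
#' @param position 1-based position from the 5' end.
#' @param nt nucleotide to test; defaults to `"U"` at position 1 and `"A"`
#'   elsewhere.
#' @return Fraction in `[0, 1]`.
#' @export
first_nt_bias <- function(reads, position = 1,
                          nt = if (position == 1) "U" else "A") {
  if (inherits(reads, "srna_library")) reads <- reads$reads
  if (nrow(reads) == 0L) stopf("nucleotide bias is undefined for no reads")
  reads <- reads[reads$length >= position, , drop = FALSE]
  if (nrow(reads) == 0L)
    stopf("no reads reach position %d", position)
  obs <- if (position == 1) reads$first_nt else {
    if (all(is.na(reads$seq)))
      stopf("read sequences required for position %d", position)
    reads <- reads[!is.na(reads$seq), , drop = FALSE]
    chartr("T", "U", toupper(substr(reads$seq, position, position)))
  }
  mean(obs == nt)
}

#' Read-size distribution with biogenesis bands
#'
#' Counts per read length 15-30 nt, summarised into the named bands
#' `degradation` (< 18 nt), `dicer_products` (18-24 nt, miRNA/siRNA sized)
#' and `pirna` (26-30 nt).  Length 25 belongs to no band and is counted in
#' the total only.
#'
#' @param reads an [srna_library] or reads data.frame.
#' @return A list of class `size_histogram` with `counts` (lengths 15-30),
#'   `bands` and `total`.
#' @export
size_distribution <- function(reads) {
  if (inherits(reads, "srna_library")) reads <- reads$reads
  lens <- 15:30
  counts <- setNames(integer(length(lens)), lens)
  if (nrow(reads)) {
    tab <- table(factor(reads$length, levels = lens))
    counts[] <- as.integer(tab)
  }
  bands <- c(degradation = sum(counts[as.character(15:17)]),
             dicer_products = sum(counts[as.character(18:24)]),
             pirna = sum(counts[as.character(26:30)]))
  structure(list(counts = counts, bands = bands, total = sum(counts)),
            class = "size_histogram")
}

#' @export
print.size_histogram <- function(x, ...) {
  cat(sprintf("<size_histogram> %d reads: %d degradation (<18), %d Dicer-sized (18-24), %d piRNA-sized (26-30)\n",
              x$total, x$bands["degradation"], x$bands["dicer_products"],
              x$bands["pirna"]))
  print(x$counts)
  invisible(x)
}

#' @export
plot.size_histogram <- function(x, ...) {
  len <- as.integer(names(x$counts))
  cols <- ifelse(len < 18, "grey70",
                 ifelse(len <= 24, "steelblue",
                        ifelse(len >= 26, "darkorange", "grey40")))
  barplot(x$counts, col = cols, border = NA, xlab = "read length (nt)",
          ylab = "alignments", ...)
  invisible(x)
}
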
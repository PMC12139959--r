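.empty_regions <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

.sort_regions <- function(regions) {
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  regions
}

#' Call covered regions
#'
#' Maximal intervals where strand-pooled per-base alignment coverage is at
#' least `min_cov`.  An sRNA locus is a strand-agnostic feature, so
#' coverage is pooled across strands by default; pass `per_strand = TRUE` to
#' call each strand separately (regions are then still returned pooled into
#' one sorted set and may touch).
#'
#' @param library an [srna_library].
#' @param min_cov minimum per-base alignment depth (default 1).
#' @param per_strand call strands separately.
#' @return data.frame (`chrom`, `start`, `end`), 0-based half-open, sorted
#'   and disjoint (per strand when `per_strand = TRUE`).
#' @export
call_regions <- function(library, min_cov = 1, per_strand = FALSE) {
  stopifnot(inherits(library, "srna_library"))
  r <- library$reads
  if (!nrow(r)) return(.empty_regions())
  groups <- if (per_strand) split(r, list(r$chrom, r$strand), drop = TRUE)
            else split(r, r$chrom)
  out <- lapply(names(groups), function(g) {
    gr <- groups[[g]]
    ir <- IRanges::IRanges(start = gr$start + 1L, end = gr$end)
    sl <- IRanges::slice(IRanges::coverage(ir), lower = min_cov)
    data.frame(chrom = gr$chrom[1L],
               start = IRanges::start(sl) - 1L,
               end = IRanges::end(sl))
  })
  .sort_regions(do.call(rbind, out))
}

#' Merge regions within a distance
#'
#' Unites any two regions whose gap (`next$start - prev$end`) is at most
#' `merge_distance`; `merge_distance = 0` unites only touching or overlapping
#' regions.  Idempotent; output sorted and disjoint.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param merge_distance non-negative gap threshold in bp.
#' @return Merged regions data.frame.
#' @export
merge_regions <- function(regions, merge_distance) {
  if (length(merge_distance) != 1L || is.na(merge_distance) ||
      merge_distance < 0)
    stopf("'merge_distance' must be a single non-negative number")
  if (!nrow(regions)) return(.empty_regions())
  out <- lapply(split(regions, regions$chrom), function(g) {
    ir <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end),
                          min.gapwidth = merge_distance + 1)
    data.frame(chrom = g$chrom[1L], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir))
  })
  .sort_regions(do.call(rbind, out))
}

#' Annotate regions with read counts and RPM
#'
#' A read belongs to the locus containing its 5' coordinate, which assigns
#' boundary-straddling reads unambiguously.  RPM uses the library's
#' `total_alignments` as the only denominator.
#'
#' @param regions sorted, disjoint regions ([call_regions()] /
#'   [merge_regions()]).
#' @param library the [srna_library] the regions came from.
#' @return data.frame of class `srna_loci`: `chrom`, `start`, `end`,
#'   `locus_id`, `read_count`, `rpm`.
#' @export
annotate_loci <- function(regions, library) {
  stopifnot(inherits(library, "srna_library"))
  n <- nrow(regions)
  loci <- data.frame(chrom = regions$chrom,
                     start = as.integer(regions$start),
                     end = as.integer(regions$end),
                     locus_id = sprintf("locus_%05d", seq_len(n)),
                     read_count = integer(n),
                     stringsAsFactors = FALSE)
  if (n && nrow(library$reads)) {
    r <- library$reads
    for (chrom in unique(loci$chrom)) {
      li <- which(loci$chrom == chrom)
      fp <- r$five_prime[r$chrom == chrom]
      if (!length(fp)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(fp + 1L, width = 1L),
        IRanges::IRanges(loci$start[li] + 1L, loci$end[li]))
      tab <- tabulate(S4Vectors::subjectHits(hits), nbins = length(li))
      loci$read_count[li] <- tab
    }
  }
  loci$rpm <- if (library$total_alignments > 0)
    loci$read_count / library$total_alignments * 1e6 else 0
  class(loci) <- c("srna_loci", "data.frame")
  loci
}

#' Filter loci by RPM
#'
#' Retains loci with `rpm >= min_rpm` (inclusive boundary, matching a
#' ">= 1,000 RPM" style operating point).  If `total_alignments` is
#' supplied, RPM is recomputed from `read_count` first.
#'
#' @param loci an `srna_loci` data.frame.
#' @param total_alignments optional denominator for recomputing RPM; must be
#'   positive when given.
#' @param min_rpm RPM threshold (default 1000).
#' @return Filtered loci.
#' @export
rpm_filter <- function(loci, total_alignments = NULL, min_rpm = 1000) {
  if (!is.null(total_alignments)) {
    if (total_alignments == 0) stopf("'total_alignments' must be positive")
    loci$rpm <- loci$read_count / total_alignments * 1e6
  }
  out <- loci[loci$rpm >= min_rpm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of the genome covered by loci
#'
#' @param loci loci or regions data.frame.
#' @param genome_seqlengths named vector of chromosome lengths.
#' @return Percent of the genome covered (sum of locus lengths over sum of
#'   chromosome lengths, times 100).
#' @export
genome_fraction <- function(loci, genome_seqlengths) {
  if (!length(genome_seqlengths) || sum(genome_seqlengths) <= 0)
    stopf("'genome_seqlengths' must be a non-empty positive length table")
  if (!nrow(loci)) return(0)
  100 * sum(loci$end - loci$start) / sum(genome_seqlengths)
}

#' Merge-distance by read-depth threshold sweep
#'
#' Evaluates the full grid of merge distances crossed with minimum RPM
#' thresholds used to pick a locus-annotation operating point.  A single
#' [call_regions()] pass is reused for every cell.  The depth grid is in RPM
#' units (the operating point the method states is an RPM).
#'
#' @param library an [srna_library].
#' @param genome_seqlengths named chromosome length vector.
#' @param merge_grid merge distances in bp; default
#'   `c(0, 5, 50, 500, 5000, 50000)`.
#' @param rpm_grid minimum-RPM thresholds; default
#'   `c(0, 1, 10, 100, 1e3, 1e4, 1e5, 1e6)` (0 to one million).
#' @param min_cov coverage threshold for the initial region call.
#' @return data.frame of class `sweep_result` with one row per grid cell:
#'   `merge_distance`, `min_rpm`, `n_loci`, `genome_fraction` (percent).
#' @export
threshold_sweep <- function(library, genome_seqlengths,
                            merge_grid = c(0, 5, 50, 500, 5000, 50000),
                            rpm_grid = c(0, 1, 10, 100, 1e3, 1e4, 1e5, 1e6),
                            min_cov = 1) {
  if (!length(merge_grid) || !length(rpm_grid))
    stopf("'merge_grid' and 'rpm_grid' must be non-empty")
  base <- call_regions(library, min_cov = min_cov)
  cells <- lapply(merge_grid, function(md) {
    loci <- annotate_loci(merge_regions(base, md), library)
    do.call(rbind, lapply(rpm_grid, function(thr) {
      kept <- loci[loci$rpm >= thr, , drop = FALSE]
      data.frame(merge_distance = md, min_rpm = thr, n_loci = nrow(kept),
                 genome_fraction = genome_fraction(kept, genome_seqlengths))
    }))
  })
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> n_loci by merge distance (rows) x min RPM (columns):\n")
  m <- stats::xtabs(n_loci ~ merge_distance + min_rpm, data = x)
  print(m)
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, what = c("n_loci", "genome_fraction"), ...) {
  what <- match.arg(what)
  m <- stats::xtabs(stats::as.formula(paste(what, "~ min_rpm + merge_distance")),
                    data = x)
  matplot(log10(as.numeric(rownames(m)) + 1), unclass(m), type = "b",
          pch = 19, lty = 1, xlab = "log10(min RPM + 1)", ylab = what, ...)
  legend("topright", legend = paste(colnames(m), "bp"), col = seq_len(ncol(m)),
         lty = 1, pch = 19, title = "merge", bty = "n", cex = 0.8)
  invisible(x)
}
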
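#' Construct a small-RNA alignment library
#'
#' The central container of the package: a multiset of ungapped genomic
#' alignments of small RNAs plus the total number of mapped alignments, which
#' is the sole denominator for RPM and percent calculations downstream.
#'
#' Coordinates are 0-based half-open throughout the package.  The 5' end of a
#' read is `start` on the plus strand and `end - 1` on the minus strand.
#'
#' @param reads data.frame with at least `chrom`, `strand` (`"+"`/`"-"`),
#'   `start`, `end` (0-based half-open).  Optional columns: `seq`
#'   (read-oriented 5'->3' DNA sequence), `first_nt`, `id`.  Missing
#'   `first_nt` is derived from `seq` (T reported as U) or set to `"N"`.
#' @param total_alignments number of mapped alignments the library represents;
#'   defaults to `nrow(reads)`.
#' @param metadata named list of sample annotations (species, tissue,
#'   individual, `genome_lengths`, ...).
#'
#' @return An object of class `srna_library`.
#' @seealso [load_alignments()], [simulate_library()], [library_stats()]
#' @export
srna_library <- function(reads, total_alignments = nrow(reads),
                         metadata = list()) {
  stopifnot(is.data.frame(reads))
  n <- nrow(reads)
  if (n > 0L) {
    miss <- setdiff(c("chrom", "strand", "start", "end"), names(reads))
    if (length(miss))
      stopf("reads lack required column(s): %s", paste(miss, collapse = ", "))
    if (!all(reads$strand %in% c("+", "-")))
      stopf("strand must be '+' or '-'")
    if (any(reads$end <= reads$start))
      stopf("all reads must satisfy start < end")
  } else {
    reads <- data.frame(chrom = character(), strand = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
  }
  reads$chrom <- as.character(reads$chrom)
  reads$start <- as.integer(reads$start)
  reads$end <- as.integer(reads$end)
  reads$length <- reads$end - reads$start
  if (is.null(reads$seq)) reads$seq <- rep(NA_character_, n)
  if (is.null(reads$first_nt)) reads$first_nt <- first_nt_of(reads$seq)
  if (is.null(reads$id)) reads$id <- sprintf("r%06d", seq_len(n))
  reads$five_prime <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  rownames(reads) <- NULL
  structure(list(reads = reads,
                 total_alignments = as.integer(total_alignments),
                 metadata = metadata),
            class = "srna_library")
}

#' @export
print.srna_library <- function(x, ...) {
  cat(sprintf("<srna_library> %d alignments (%d rows) on %d sequence(s)\n",
              x$total_alignments, nrow(x$reads),
              length(unique(x$reads$chrom))))
  if (nrow(x$reads)) {
    rng <- range(x$reads$length)
    cat(sprintf("  read lengths %d-%d nt; %d plus / %d minus strand\n",
                rng[1], rng[2],
                sum(x$reads$strand == "+"), sum(x$reads$strand == "-")))
  }
  meta <- x$metadata[setdiff(names(x$metadata), "genome_lengths")]
  if (length(meta))
    cat("  metadata:", paste(names(meta), unlist(lapply(meta, paste,
        collapse = ",")), sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' Summary statistics of an alignment library
#'
#' Totals, per-length, per-strand and per-chromosome alignment counts.  The
#' per-length counts always sum to the number of alignment rows.
#'
#' @param library an [srna_library].
#' @return A list of class `library_stats` with elements `total_alignments`,
#'   `n_reads`, `per_length` (named vector over observed lengths),
#'   `per_strand`, `per_chrom` and `first_nt`.
#' @export
library_stats <- function(library) {
  stopifnot(inherits(library, "srna_library"))
  r <- library$reads
  lens <- if (nrow(r)) seq(min(15L, min(r$length)), max(30L, max(r$length)))
          else 15:30
  per_length <- setNames(integer(length(lens)), lens)
  if (nrow(r)) {
    tab <- table(factor(r$length, levels = lens))
    per_length[] <- as.integer(tab)
  }
  structure(list(
    total_alignments = library$total_alignments,
    n_reads = nrow(r),
    per_length = per_length,
    per_strand = c(`+` = sum(r$strand == "+"), `-` = sum(r$strand == "-")),
    per_chrom = if (nrow(r)) table(r$chrom) else table(character()),
    first_nt = table(factor(r$first_nt, levels = c("A", "C", "G", "U", "N")))
  ), class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf("Library of %d alignments\n", x$total_alignments))
  cat("Per-length counts:\n")
  print(x$per_length)
  cat("Per-strand:\n")
  print(x$per_strand)
  invisible(x)
}

#' @export
summary.srna_library <- function(object, ...) library_stats(object)

#' @export
plot.srna_library <- function(x, ...) {
  plot(size_distribution(x), ...)
}

# Subset a library's reads to those whose 5' end falls in [start, end) of
# `chrom`.  Total alignments kept from the parent (RPM denominators must not
# change when restricting to a locus).
subset_reads_5p <- function(library, chrom, start, end) {
  r <- library$reads
  r[r$chrom == chrom & r$five_prime >= start & r$five_prime < end, ,
    drop = FALSE]
}
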
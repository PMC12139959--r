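#' Load genome-aligned small-RNA reads
#'
#' Reads SAM, BAM or the package's BED6 dialect into an [srna_library],
#' applying the standard 15-30 nt length screen.  Unmapped records, secondary
#' and supplementary alignments, and gapped/clipped alignments (any CIGAR
#' other than a single `M` run) are excluded and counted, not fatal.  SAM's
#' 1-based closed coordinates are converted to 0-based half-open at this
#' boundary; internally everything is 0-based half-open.
#'
#' The stored SAM sequence is on the forward genomic strand (aligners
#' reverse-complement minus-strand reads), so the read-oriented sequence of a
#' minus-strand record is the reverse complement of the stored field; the
#' first nucleotide is reported in the RNA alphabet (T as U).
#'
#' @param path SAM (`.sam`), BAM (`.bam`) or BED6 (`.bed`) file.  The BED6
#'   dialect written by [write_alignments_bed()] is
#'   `chrom start end read-id_firstnt length strand`; sequences are not
#'   recoverable from BED.
#' @param min_len,max_len inclusive read-length screen (default 15-30 nt).
#' @param include_secondary keep secondary/supplementary alignments
#'   (default `FALSE`: primary alignments only, so multimapped reads count
#'   once per reported primary alignment, unweighted).
#' @return An [srna_library]; `attr(, "load_log")` records input, retained
#'   and excluded-by-reason counts (`input = retained + sum(excluded)`).
#' @export
load_alignments <- function(path, min_len = 15, max_len = 30,
                            include_secondary = FALSE) {
  if (!file.exists(path)) stopf("cannot read alignment file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed")
    return(.load_bed6(path, min_len, max_len))
  if (!ext %in% c("sam", "bam"))
    stopf("unsupported alignment format '.%s' (use .sam, .bam or .bed)", ext)

  bam <- if (ext == "sam")
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  else path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]

  n_in <- length(x$flag)
  unmapped <- bitwAnd(x$flag, 4L) > 0L | is.na(x$pos)
  secondary <- bitwAnd(x$flag, 0x900L) > 0L & !include_secondary
  m_only <- grepl("^[0-9]+M$", x$cigar)
  gapped <- !unmapped & !m_only
  len <- suppressWarnings(as.integer(sub("M$", "", x$cigar)))
  len[!m_only] <- NA_integer_
  out_of_range <- !unmapped & !gapped & !secondary &
    (len < min_len | len > max_len)
  keep <- !unmapped & !secondary & !gapped & !out_of_range
  # precedence for the log: unmapped > secondary > gapped > length
  excl <- c(unmapped = sum(unmapped),
            secondary = sum(secondary & !unmapped),
            gapped = sum(gapped & !secondary & !unmapped),
            out_of_range = sum(out_of_range, na.rm = TRUE))

  seqs <- as.character(x$seq)[keep]
  strand <- as.character(x$strand)[keep]
  seqs[seqs == ""] <- NA_character_
  reads <- data.frame(
    chrom = as.character(x$rname)[keep],
    strand = strand,
    start = x$pos[keep] - 1L,
    end = x$pos[keep] - 1L + len[keep],
    seq = ifelse(strand == "-", revcomp(seqs), seqs),
    id = x$qname[keep],
    stringsAsFactors = FALSE)
  lib <- srna_library(reads, metadata = list(source = path))
  attr(lib, "load_log") <- list(input = n_in, retained = sum(keep),
                                excluded = as.list(excl))
  lib
}

.load_bed6 <- function(path, min_len, max_len) {
  b <- tryCatch(
    read.table(path, sep = "\t", comment.char = "#",
               col.names = c("chrom", "start", "end", "name", "score",
                             "strand"),
               colClasses = c("character", "integer", "integer", "character",
                              "integer", "character")),
    error = function(e) data.frame(chrom = character(), start = integer(),
                                   end = integer(), name = character(),
                                   score = integer(), strand = character()))
  n_in <- nrow(b)
  len <- b$end - b$start
  keep <- len >= min_len & len <= max_len
  nm <- b$name[keep]
  has_nt <- grepl("_[ACGUN]$", nm)
  reads <- data.frame(
    chrom = b$chrom[keep], strand = b$strand[keep],
    start = b$start[keep], end = b$end[keep],
    first_nt = ifelse(has_nt, sub(".*_", "", nm), "N"),
    id = sub("_[ACGUN]$", "", nm),
    stringsAsFactors = FALSE)
  lib <- srna_library(reads, metadata = list(source = path))
  attr(lib, "load_log") <- list(input = n_in, retained = sum(keep),
                                excluded = list(out_of_range = sum(!keep)))
  lib
}

#' Write a library as unsorted SAM
#'
#' Stored sequences follow the SAM convention (forward genomic strand;
#' minus-strand reads are reverse-complemented on output).
#'
#' @param library an [srna_library].
#' @param path output `.sam` path.
#' @param genome_seqlengths named vector of chromosome lengths for the `@SQ`
#'   header; defaults to `metadata$genome_lengths` or, failing that, the
#'   maximum end coordinate per chromosome.
#' @return `path`, invisibly.
#' @export
write_sam <- function(library, path, genome_seqlengths = NULL) {
  stopifnot(inherits(library, "srna_library"))
  r <- library$reads
  gl <- genome_seqlengths %||% library$metadata$genome_lengths
  if (is.null(gl)) {
    gl <- tapply(r$end, r$chrom, max)
    gl <- setNames(as.integer(gl), names(gl))
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(gl), as.integer(gl)))
  if (nrow(r)) {
    seq_out <- ifelse(is.na(r$seq), "*",
                      ifelse(r$strand == "-", revcomp(r$seq), r$seq))
    rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                   r$id, ifelse(r$strand == "-", 16L, 0L), r$chrom,
                   r$start + 1L, r$length, seq_out)
  } else rec <- character()
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write a library as BED6
#'
#' `chrom start end read-id_firstnt length strand`; the 5' nucleotide rides
#' in the name column so that [load_alignments()] can recover it (sequences
#' themselves are not representable in BED).
#'
#' @param library an [srna_library].
#' @param path output `.bed` path.
#' @return `path`, invisibly.
#' @export
write_alignments_bed <- function(library, path) {
  stopifnot(inherits(library, "srna_library"))
  r <- library$reads
  lines <- if (nrow(r))
    sprintf("%s\t%d\t%d\t%s_%s\t%d\t%s", r$chrom, r$start, r$end,
            r$id, r$first_nt, r$length, r$strand)
  else character()
  writeLines(lines, path)
  invisible(path)
}

#' Write annotated loci as BED
#'
#' 0-based half-open BED with locus id, read count, RPM and (when present)
#' class label in the extra columns.  An empty locus set yields a file with
#' the header comment only.  [read_loci_bed()] reproduces the intervals
#' exactly.
#'
#' @param loci data.frame from [annotate_loci()] / [classify_loci()] merges.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  has_label <- "label" %in% names(loci)
  header <- paste0("#chrom\tstart\tend\tlocus_id\tread_count\trpm",
                   if (has_label) "\tlabel")
  lines <- if (nrow(loci)) {
    base <- sprintf("%s\t%d\t%d\t%s\t%d\t%.10g", loci$chrom,
                    as.integer(loci$start), as.integer(loci$end),
                    loci$locus_id, as.integer(loci$read_count), loci$rpm)
    if (has_label) paste(base, loci$label, sep = "\t") else base
  } else character()
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read loci back from BED
#' @param path a file written by [write_loci_bed()].
#' @return data.frame with `chrom`, `start`, `end`, `locus_id`, `read_count`,
#'   `rpm` and optional `label`.
#' @export
read_loci_bed <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  b <- tryCatch(read.table(path, sep = "\t", comment.char = "#",
                           col.names = cols, stringsAsFactors = FALSE),
                error = function(e) NULL)
  if (is.null(b)) {
    b <- data.frame(chrom = character(), start = integer(), end = integer(),
                    locus_id = character(), read_count = integer(),
                    rpm = numeric())
    if ("label" %in% cols) b$label <- character()
  }
  b
}
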
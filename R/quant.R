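#' Per-locus count matrix across libraries
#'
#' Cell `(l, j)` counts the alignments of library `j` whose 5' end lies in
#' locus `l`, optionally restricted to the piRNA size band (26-30 nt).
#' Libraries carrying a `genome_lengths` metadata entry are checked for
#' chromosome-name compatibility with the loci.
#'
#' @param loci shared `srna_loci` annotation.
#' @param libraries named list of [srna_library] objects.
#' @param size_band `"none"` (all 15-30 nt reads) or `"pirna"` (26-30 nt).
#' @return Integer matrix, rows = loci, columns = libraries.
#' @export
count_matrix <- function(loci, libraries, size_band = c("none", "pirna")) {
  size_band <- match.arg(size_band)
  stopifnot(is.list(libraries), length(libraries) >= 1L)
  if (is.null(names(libraries)))
    names(libraries) <- sprintf("lib%02d", seq_along(libraries))
  m <- matrix(0L, nrow = nrow(loci), ncol = length(libraries),
              dimnames = list(loci$locus_id, names(libraries)))
  for (j in seq_along(libraries)) {
    lib <- libraries[[j]]
    stopifnot(inherits(lib, "srna_library"))
    gl <- lib$metadata$genome_lengths
    if (!is.null(gl) && nrow(loci) && !all(loci$chrom %in% names(gl)))
      stopf("library '%s' was aligned to a genome lacking loci chromosome(s) %s",
            names(libraries)[j],
            paste(setdiff(loci$chrom, names(gl)), collapse = ", "))
    r <- lib$reads
    if (size_band == "pirna")
      r <- r[r$length >= 26L & r$length <= 30L, , drop = FALSE]
    if (!nrow(r) || !nrow(loci)) next
    for (chrom in unique(loci$chrom)) {
      li <- which(loci$chrom == chrom)
      fp <- r$five_prime[r$chrom == chrom]
      if (!length(fp)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(fp + 1L, width = 1L),
        IRanges::IRanges(loci$start[li] + 1L, loci$end[li]))
      m[li, j] <- m[li, j] + tabulate(S4Vectors::subjectHits(hits),
                                      nbins = length(li))
    }
  }
  m
}

#' RPM and log2 views of a count matrix
#'
#' `rpm = count / column_total * 1e6`; the log view is
#' `log2(rpm + pseudocount)`.  Column totals are the libraries'
#' `total_alignments`, never the matrix column sums.
#'
#' @param counts matrix from [count_matrix()].
#' @param totals per-library total alignment counts (recycled against
#'   columns); alternatively a list of [srna_library] objects.
#' @param pseudocount added inside the log (default 1, so zero counts map to
#'   0).
#' @return List with `rpm`, `log2`, `totals`, `pseudocount`.
#' @export
normalize_counts <- function(counts, totals, pseudocount = 1) {
  if (is.list(totals))
    totals <- vapply(totals, function(l) l$total_alignments, 0L)
  totals <- rep_len(as.numeric(totals), ncol(counts))
  if (any(totals == 0)) stopf("zero column total: RPM undefined")
  rpm <- sweep(counts, 2L, totals, "/") * 1e6
  list(rpm = rpm, log2 = log2(rpm + pseudocount), totals = totals,
       pseudocount = pseudocount)
}

#' PCA coordinates of libraries
#'
#' Column-centred principal components of the libraries (observations =
#' libraries, variables = loci).  Signs are fixed by making each component's
#' largest-magnitude loading positive, so coordinates are fully
#' deterministic.
#'
#' @param log_matrix loci x libraries matrix (typically the `log2` view of
#'   [normalize_counts()]).
#' @param n_components number of components to return (default 2).
#' @return List with `coords` (libraries x components), `var_frac`
#'   (non-increasing variance fractions), and `rotation`.
#' @export
pca_coords <- function(log_matrix, n_components = 2) {
  if (ncol(log_matrix) < 2L) stopf("PCA needs at least 2 libraries")
  pc <- prcomp(t(log_matrix), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  tot_var <- sum(pc$sdev^2)
  var_frac <- if (tot_var > 0) pc$sdev^2 / tot_var else rep(0, length(pc$sdev))
  list(coords = coords, var_frac = var_frac[seq_len(k)], rotation = rot)
}

#' Naive log2 fold change between two libraries
#'
#' `log2((rpm_a + pseudocount) / (rpm_b + pseudocount))` per locus.  This is
#' descriptive plumbing, not a differential-expression test; export the raw
#' counts for model-based inference.
#'
#' @param rpm RPM matrix (the `rpm` view of [normalize_counts()]).
#' @param a,b column names or indices.
#' @param pseudocount stabilising offset (default 1 RPM).
#' @return Named numeric vector of per-locus log2 fold changes.
#' @export
log2_fold_change <- function(rpm, a, b, pseudocount = 1) {
  log2((rpm[, a] + pseudocount) / (rpm[, b] + pseudocount))
}

#' Export / import a count table as TSV
#'
#' Integer counts with a leading `locus_id` column; the round trip is
#' lossless.
#'
#' @param counts matrix from [count_matrix()].
#' @param path TSV path.
#' @return `path` invisibly ([export_counts()]); the matrix
#'   ([read_counts()]).
#' @export
export_counts <- function(counts, path) {
  df <- data.frame(locus_id = rownames(counts) %||% character(),
                   counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_counts
#' @export
read_counts <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$locus_id
  m
}
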
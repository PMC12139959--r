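#' Simulation configuration
#'
#' Describes a toy genome and the small-RNA library to plant on it.  Given the
#' same configuration (which includes the seed), [simulate_library()] is
#' byte-identical across runs.
#'
#' @param n_chroms number of chromosomes (>= 1).
#' @param chrom_length length of every chromosome in bases (>= 1000).
#' @param seed integer RNG seed.
#' @param loci_specs list of [planted_locus()] specifications.
#' @param background_reads number of uniformly placed background reads.
#' @param background_length_range length-2 integer vector; read lengths are
#'   drawn uniformly from this range.  The default 15-17 nt emulates a
#'   degradation background; pass `c(15, 30)` for a full-width null library.
#' @param allow_overlap permit planted loci to overlap (default `FALSE`;
#'   overlapping loci make the manifest truth ambiguous).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 1, chrom_length = 50000, seed = 1,
                       loci_specs = list(), background_reads = 0,
                       background_length_range = c(15, 17),
                       allow_overlap = FALSE) {
  if (length(n_chroms) != 1L || is.na(n_chroms) || n_chroms < 1)
    stopf("'n_chroms' must be a single integer >= 1")
  if (length(chrom_length) != 1L || is.na(chrom_length) || chrom_length < 1000)
    stopf("'chrom_length' must be >= 1000")
  if (background_reads < 0)
    stopf("'background_reads' must be >= 0")
  blr <- as.integer(background_length_range)
  if (length(blr) != 2L || any(is.na(blr)) || blr[1] > blr[2] || blr[1] < 1)
    stopf("'background_length_range' must be an increasing length-2 range")
  if (!all(vapply(loci_specs, inherits, TRUE, "planted_locus")))
    stopf("'loci_specs' must be a list of planted_locus() objects")
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 seed = as.integer(seed),
                 loci_specs = loci_specs,
                 background_reads = as.integer(background_reads),
                 background_length_range = blr,
                 allow_overlap = isTRUE(allow_overlap)),
            class = "sim_config")
}

.locus_classes <- c("dicer_duplex", "pingpong_pirna", "phased_pirna",
                    "mirna_like", "degradation")

.class_defaults <- list(
  dicer_duplex   = list(length_range = c(20L, 24L), u1_prob = 0.25,
                        a10_prob = 0,   width = 1000L),
  pingpong_pirna = list(length_range = c(26L, 30L), u1_prob = 0.9,
                        a10_prob = 0.8, width = 1000L),
  phased_pirna   = list(length_range = c(26L, 30L), u1_prob = 0.9,
                        a10_prob = 0,   width = NA_integer_),
  mirna_like     = list(length_range = c(21L, 23L), u1_prob = 0.25,
                        a10_prob = 0,   width = 60L),
  degradation    = list(length_range = c(15L, 17L), u1_prob = 0.25,
                        a10_prob = 0,   width = 300L)
)

#' Specification of one planted small-RNA locus
#'
#' Each class plants reads with the geometry of a biogenesis pathway:
#' `dicer_duplex` emits plus/minus pairs with 2-nt 3' overhangs at both duplex
#' ends; `pingpong_pirna` emits opposite-strand pairs whose 5' ends overlap by
#' exactly 10 nt; `phased_pirna` emits a same-strand head-to-tail trail of 1U
#' reads; `mirna_like` stacks reads at two 5' positions on one genomic strand
#' (mature and star arms of a hairpin both align to the same strand);
#' `degradation` scatters short reads uniformly.
#'
#' @param class_label one of `"dicer_duplex"`, `"pingpong_pirna"`,
#'   `"phased_pirna"`, `"mirna_like"`, `"degradation"`.
#' @param chrom chromosome name (or index into the simulated genome).
#' @param anchor 0-based base position anchoring the locus.
#' @param n_reads number of alignments to emit (pair-based classes emit
#'   `2 * floor(n_reads / 2)`).
#' @param length_range read-length range; class defaults are 20-24
#'   (dicer), 26-30 (piRNA classes), 21-23 (miRNA), 15-17 (degradation).
#' @param u1_prob probability that a read's first nucleotide is U
#'   (default 0.9 for the piRNA classes, 0.25 otherwise).
#' @param a10_prob probability that position 10 of a responder read is A
#'   (ping-pong only, default 0.8).  Because the 10-nt overlap places the
#'   responder's position 10 on the initiator's first base, the generator sets
#'   that base to the U-equivalent with probability `max(u1_prob, a10_prob)`.
#' @param strand `"+"`, `"-"`, or `NULL` to draw at random at planting time.
#' @param width span in bp over which pair anchors are scattered (ignored for
#'   `phased_pirna`, whose span is the trail itself).
#' @return A list of class `planted_locus`.
#' @export
planted_locus <- function(class_label, chrom = "chr1", anchor, n_reads,
                          length_range = NULL, u1_prob = NULL,
                          a10_prob = NULL, strand = NULL, width = NULL) {
  class_label <- match.arg(class_label, .locus_classes)
  d <- .class_defaults[[class_label]]
  length_range <- as.integer(length_range %||% d$length_range)
  u1_prob <- u1_prob %||% d$u1_prob
  a10_prob <- a10_prob %||% d$a10_prob
  width <- as.integer(width %||% d$width)
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 15L || length_range[2] > 30L)
    stopf("'length_range' must be within 15-30 nt")
  if (u1_prob < 0 || u1_prob > 1 || a10_prob < 0 || a10_prob > 1)
    stopf("probabilities must lie in [0, 1]")
  if (n_reads < 1) stopf("'n_reads' must be >= 1")
  if (anchor < 0) stopf("'anchor' must be >= 0")
  if (!is.null(strand)) strand <- match.arg(strand, c("+", "-"))
  structure(list(class_label = class_label, chrom = chrom,
                 anchor = as.integer(anchor), n_reads = as.integer(n_reads),
                 length_range = length_range, u1_prob = u1_prob,
                 a10_prob = a10_prob, strand = strand, width = width),
            class = "planted_locus")
}

.draw_genome <- function(config) {
  seqs <- vapply(seq_len(config$n_chroms), function(i)
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
          collapse = ""), character(1))
  names(seqs) <- paste0("chr", seq_len(config$n_chroms))
  structure(seqs,
            lengths = setNames(rep(config$chrom_length, config$n_chroms),
                               names(seqs)),
            class = "sim_genome")
}

#' Generate a random toy genome
#'
#' @param config a [sim_config()].
#' @return A named character vector of class `sim_genome` (one DNA sequence
#'   per chromosome) with a `lengths` attribute.  Deterministic under
#'   `config$seed`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .draw_genome(config))
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d chromosome(s), %s bp total\n", length(x),
              format(sum(attr(x, "lengths")), big.mark = ",")))
  invisible(x)
}

#' Chromosome length table of a simulated genome
#' @param genome a `sim_genome`.
#' @return Named integer vector of chromosome lengths.
#' @export
genome_lengths <- function(genome) {
  if (inherits(genome, "sim_genome")) return(attr(genome, "lengths"))
  setNames(nchar(genome), names(genome))
}

# Draw the 5' genomic base for a read: the U-equivalent (`u_base`, "T" on plus
# strand, "A" on minus) with probability p, otherwise uniformly one of the
# other three letters, so P(first nt = U) is exactly p.
.draw_5p_base <- function(p, u_base) {
  if (runif(1) < p) u_base else sample(setdiff(c("A", "C", "G", "T"), u_base), 1)
}

.rlen <- function(range, n) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

# Plant one locus.  Uses the ambient RNG stream.  Returns coordinates, genome
# base edits implied by the 1U/10A composition, the locus span, and the
# construction-truth signature counts.
.plant_locus <- function(glens, spec) {
  chrom <- spec$chrom
  if (is.numeric(chrom)) chrom <- paste0("chr", chrom)
  if (!chrom %in% names(glens))
    stopf("planted locus names unknown chromosome '%s'", chrom)
  clen <- glens[[chrom]]
  a0 <- spec$anchor
  lr <- spec$length_range
  strand <- spec$strand %||% sample(c("+", "-"), 1)
  truth <- list(dicer_pairs = 0L, dicer_pair_alignments = 0L,
                pairs_overlap10 = 0L, d1_count = 0L)
  edits <- data.frame(pos = integer(), base = character())
  add_edit <- function(pos, base)
    edits <<- rbind(edits, data.frame(pos = pos, base = base))

  if (spec$class_label == "dicer_duplex") {
    n_pairs <- spec$n_reads %/% 2L
    if (n_pairs < 1L) stopf("dicer_duplex locus needs n_reads >= 2")
    w <- max(spec$width, n_pairs)
    # distinct anchors: no two planted duplexes can form an accidental pair
    anc <- a0 + sample.int(w, n_pairs) - 1L
    L <- .rlen(lr, n_pairs)
    reads <- data.frame(
      chrom = chrom,
      strand = rep(c("+", "-"), each = n_pairs),
      start = c(anc, anc - 2L),
      end = c(anc + L, anc + L - 2L))
    for (i in seq_len(n_pairs)) {
      add_edit(anc[i], .draw_5p_base(spec$u1_prob, "T"))
      add_edit(anc[i] + L[i] - 3L, .draw_5p_base(spec$u1_prob, "A"))
    }
    truth$dicer_pairs <- n_pairs
    truth$dicer_pair_alignments <- 2L * n_pairs
  } else if (spec$class_label == "pingpong_pirna") {
    n_pairs <- spec$n_reads %/% 2L
    if (n_pairs < 1L) stopf("pingpong_pirna locus needs n_reads >= 2")
    w <- max(spec$width, n_pairs)
    anc <- a0 + sample.int(w, n_pairs) - 1L
    Lp <- .rlen(lr, n_pairs)
    Lm <- .rlen(lr, n_pairs)
    if (strand == "+") {
      # initiator on plus with 5' at anc; responder minus 5' at anc + 9
      reads <- data.frame(
        chrom = chrom,
        strand = rep(c("+", "-"), each = n_pairs),
        start = c(anc, anc + 10L - Lm),
        end = c(anc + Lp, anc + 10L))
      for (i in seq_len(n_pairs)) {
        add_edit(anc[i], .draw_5p_base(max(spec$u1_prob, spec$a10_prob), "T"))
        add_edit(anc[i] + 9L, .draw_5p_base(spec$u1_prob, "A"))
      }
    } else {
      # initiator on minus with 5' at anc; responder plus 5' at anc - 9
      reads <- data.frame(
        chrom = chrom,
        strand = rep(c("-", "+"), each = n_pairs),
        start = c(anc - Lp + 1L, anc - 9L),
        end = c(anc + 1L, anc - 9L + Lm))
      for (i in seq_len(n_pairs)) {
        add_edit(anc[i], .draw_5p_base(max(spec$u1_prob, spec$a10_prob), "A"))
        add_edit(anc[i] - 9L, .draw_5p_base(spec$u1_prob, "T"))
      }
    }
    truth$pairs_overlap10 <- n_pairs
  } else if (spec$class_label == "phased_pirna") {
    n <- spec$n_reads
    L <- .rlen(lr, n)
    u_hit <- runif(n) < spec$u1_prob
    if (strand == "+") {
      s <- a0 + c(0L, cumsum(L))[seq_len(n)]
      reads <- data.frame(chrom = chrom, strand = "+", start = s, end = s + L)
      for (i in seq_len(n))
        add_edit(s[i], if (u_hit[i]) "T" else sample(c("A", "C", "G"), 1))
    } else {
      e <- a0 - c(0L, cumsum(L))[seq_len(n)]
      reads <- data.frame(chrom = chrom, strand = "-", start = e - L, end = e)
      for (i in seq_len(n))
        add_edit(e[i] - 1L, if (u_hit[i]) "A" else sample(c("C", "G", "T"), 1))
    }
    truth$d1_count <- sum(u_hit[-1L])
  } else if (spec$class_label == "mirna_like") {
    n <- spec$n_reads
    n1 <- ceiling(0.7 * n)
    n2 <- n - n1
    gap <- 15L  # hairpin loop between the two arms
    L1 <- .rlen(lr, n1)
    L2 <- .rlen(lr, max(n2, 0L))
    if (strand == "+") {
      p2 <- a0 + lr[2] + gap
      reads <- data.frame(
        chrom = chrom, strand = "+",
        start = c(rep(a0, n1), rep(p2, n2)),
        end = c(a0 + L1, p2 + L2))
      add_edit(a0, .draw_5p_base(spec$u1_prob, "T"))
      if (n2 > 0) add_edit(p2, .draw_5p_base(spec$u1_prob, "T"))
    } else {
      p2 <- a0 - lr[2] - gap
      # stack1 5' at a0, stack2 5' at p2 (leftward of stack1)
      reads <- data.frame(
        chrom = chrom, strand = "-",
        start = c(a0 + 1L - L1, p2 + 1L - L2),
        end = c(rep(a0 + 1L, n1), rep(p2 + 1L, n2)))
      add_edit(a0, .draw_5p_base(spec$u1_prob, "A"))
      if (n2 > 0) add_edit(p2, .draw_5p_base(spec$u1_prob, "A"))
    }
  } else { # degradation
    n <- spec$n_reads
    L <- .rlen(lr, n)
    w <- max(spec$width, lr[2] + 1L)
    s <- a0 + floor(runif(n) * (w - L))
    reads <- data.frame(chrom = chrom,
                        strand = ifelse(runif(n) < 0.5, "+", "-"),
                        start = as.integer(s), end = as.integer(s + L))
  }

  reads$start <- as.integer(reads$start)
  reads$end <- as.integer(reads$end)
  if (any(reads$start < 0L) || any(reads$end > clen))
    stopf("planted locus '%s' at anchor %d extends outside chromosome %s",
          spec$class_label, a0, chrom)
  if (nrow(edits)) edits$chrom <- chrom
  list(reads = reads, edits = edits,
       span = c(min(reads$start), max(reads$end)),
       chrom = chrom, strand = strand, truth = truth)
}

#' Plant a single locus on a genome
#'
#' Lower-level entry point used by [simulate_library()]; exposed for
#' geometry-level testing.  Draws from the ambient RNG stream (seed it with
#' [set.seed()] for reproducibility).
#'
#' @param genome a `sim_genome` from [generate_genome()].
#' @param spec a [planted_locus()].
#' @return data.frame of planted reads (`chrom`, `strand`, `start`, `end`,
#'   `seq`, `first_nt`) with attributes `truth` (construction-truth signature
#'   counts), `span`, and `genome` (the genome with the locus's 1U/10A base
#'   edits applied).
#' @export
plant_locus <- function(genome, spec) {
  stopifnot(inherits(genome, "sim_genome"), inherits(spec, "planted_locus"))
  pl <- .plant_locus(genome_lengths(genome), spec)
  genome <- .apply_edits(genome, pl$edits)
  reads <- .extract_seqs(pl$reads, genome)
  attr(reads, "truth") <- pl$truth
  attr(reads, "span") <- pl$span
  attr(reads, "genome") <- genome
  reads
}

.apply_edits <- function(genome, edits) {
  if (!nrow(edits)) return(genome)
  for (chrom in unique(edits$chrom)) {
    e <- edits[edits$chrom == chrom, ]
    ch <- strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
    ch[e$pos + 1L] <- e$base  # 0-based -> 1-based
    g <- unclass(genome)
    g[[chrom]] <- paste(ch, collapse = "")
    attributes(g) <- attributes(genome)
    genome <- g
  }
  genome
}

.extract_seqs <- function(reads, genome) {
  if (!nrow(reads)) { reads$seq <- character(); reads$first_nt <- character()
                      return(reads) }
  fwd <- substring(unclass(genome)[reads$chrom], reads$start + 1L, reads$end)
  reads$seq <- ifelse(reads$strand == "+", fwd, revcomp(fwd))
  reads$first_nt <- first_nt_of(reads$seq)
  reads
}

#' Simulate a small-RNA alignment library with ground truth
#'
#' Generates the genome, plants every locus in `config$loci_specs`, applies
#' the 1U/10A base edits the planted composition implies, adds uniformly
#' placed background reads (strand Bernoulli(0.5)), and extracts each read's
#' sequence from the final genome.  The manifest records, per locus, the
#' construction-truth signature counts: qualifying Dicer pairs, pairs at 5'
#' overlap 10, and adjacent 1U distances at d = 1.
#'
#' @param config a [sim_config()].
#' @return A list with elements `library` (an [srna_library]), `manifest`
#'   (class `sim_manifest`), `genome` (`sim_genome`), and `config`.
#'   Byte-identical for identical configurations.
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    genome <- .draw_genome(config)
    glens <- genome_lengths(genome)
    planted <- lapply(config$loci_specs, function(s) .plant_locus(glens, s))

    if (!config$allow_overlap && length(planted) > 1L) {
      spans <- data.frame(
        chrom = vapply(planted, `[[`, "", "chrom"),
        start = vapply(planted, function(p) p$span[1], 0),
        end = vapply(planted, function(p) p$span[2], 0))
      for (chrom in unique(spans$chrom)) {
        s <- spans[spans$chrom == chrom, ]
        s <- s[order(s$start), ]
        if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
          stopf("planted loci overlap on %s; set allow_overlap = TRUE", chrom)
      }
    }

    edits <- do.call(rbind, c(list(data.frame(pos = integer(),
                                              base = character(),
                                              chrom = character())),
                              lapply(planted, `[[`, "edits")))
    genome <- .apply_edits(genome, edits)

    locus_reads <- lapply(planted, `[[`, "reads")
    n_bg <- config$background_reads
    bg <- if (n_bg > 0L) {
      blr <- config$background_length_range
      chrom <- sample(names(glens), n_bg, replace = TRUE)
      L <- .rlen(blr, n_bg)
      start <- as.integer(floor(runif(n_bg) * (glens[chrom] - L)))
      data.frame(chrom = chrom, strand = ifelse(runif(n_bg) < 0.5, "+", "-"),
                 start = start, end = start + L)
    } else data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer())
    reads <- do.call(rbind, c(locus_reads, list(bg)))
    rownames(reads) <- NULL
    reads <- .extract_seqs(reads, genome)

    lib <- srna_library(reads,
                        metadata = list(genome_lengths = glens,
                                        seed = config$seed,
                                        simulated = TRUE))

    loci_df <- if (length(planted)) data.frame(
      locus = sprintf("planted_%03d", seq_along(planted)),
      class_label = vapply(config$loci_specs, `[[`, "", "class_label"),
      chrom = vapply(planted, `[[`, "", "chrom"),
      start = vapply(planted, function(p) p$span[1], 0),
      end = vapply(planted, function(p) p$span[2], 0),
      strand = vapply(planted, `[[`, "", "strand"),
      n_reads = vapply(planted, function(p) nrow(p$reads), 0),
      dicer_pairs = vapply(planted, function(p) p$truth$dicer_pairs, 0L),
      dicer_pair_alignments =
        vapply(planted, function(p) p$truth$dicer_pair_alignments, 0L),
      pairs_overlap10 =
        vapply(planted, function(p) p$truth$pairs_overlap10, 0L),
      d1_count = vapply(planted, function(p) p$truth$d1_count, 0L)
    ) else data.frame()
    total <- nrow(reads)
    manifest <- structure(list(
      seed = config$seed,
      loci = loci_df,
      totals = list(planted = total - n_bg, background = n_bg, total = total),
      dicer_percent = if (total > 0)
        100 * sum(loci_df$dicer_pair_alignments) / total else NA_real_
    ), class = "sim_manifest")

    list(library = lib, manifest = manifest, genome = genome, config = config)
  })
}

#' @export
print.sim_manifest <- function(x, ...) {
  cat(sprintf("<sim_manifest> seed %d: %d planted loci, %d planted + %d background reads\n",
              x$seed, nrow(x$loci), x$totals$planted, x$totals$background))
  if (nrow(x$loci))
    print(x$loci[, c("locus", "class_label", "chrom", "start", "end",
                     "n_reads")])
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits the genome as FASTA, the alignments as unsorted SAM and BED6, the
#' manifest as JSON and the configuration as YAML.  SAM and BED carry the same
#' alignment information, enabling I/O round-trip tests.
#'
#' @param sim result of [simulate_library()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named vector of the file paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             sam = file.path(dir, "reads.sam"),
             bed = file.path(dir, "reads.bed"),
             manifest = file.path(dir, "manifest.json"),
             config = file.path(dir, "config.yaml"))
  dna <- Biostrings::DNAStringSet(unclass(sim$genome))
  Biostrings::writeXStringSet(dna, paths["genome"])
  write_sam(sim$library, paths["sam"])
  write_alignments_bed(sim$library, paths["bed"])
  jsonlite::write_json(unclass(sim$manifest), paths["manifest"],
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  cfg <- unclass(sim$config)
  cfg$loci_specs <- lapply(cfg$loci_specs, unclass)
  yaml::write_yaml(cfg, paths["config"])
  invisible(paths)
}

#' Lay out non-overlapping planted locus specs on a slot grid
#'
#' Convenience generator for mixed-class simulations: assigns each locus a
#' 4 kb slot (3 kb usable span, >= 1 kb inter-locus gap, so loci never touch
#' and are not merged at the 500 bp operating point).
#'
#' @param classes character vector of class labels, one locus each.
#' @param config a [sim_config()]; slots are tiled across its chromosomes.
#' @param n_reads reads per locus (recycled).
#' @param slot slot size in bp.
#' @return List of [planted_locus()] specs, suitable for `loci_specs`.
#' @export
layout_locus_specs <- function(classes, config, n_reads = 60, slot = 4000) {
  per_chrom <- (config$chrom_length - 2000) %/% slot
  if (per_chrom * config$n_chroms < length(classes))
    stopf("genome too small for %d loci (capacity %d)", length(classes),
          per_chrom * config$n_chroms)
  n_reads <- rep_len(n_reads, length(classes))
  usable <- slot - 1000L
  lapply(seq_along(classes), function(i) {
    slot_i <- i - 1L
    chrom <- slot_i %/% per_chrom + 1L
    at <- 1000L + (slot_i %% per_chrom) * slot
    # pair geometries reach at most ~30 bp upstream of the anchor, so a
    # 500 bp inset suffices; a phased trail grows a full trail length in its
    # strand direction, so it is anchored mid-slot
    if (classes[i] == "phased_pirna") {
      anchor <- at + usable %/% 2L
      if (n_reads[i] * 30L + 100L > usable %/% 2L)
        stopf("slot %d bp too small for a phased trail of %d reads", slot,
              n_reads[i])
    } else anchor <- at + 500L
    width <- if (classes[i] %in% c("dicer_duplex", "pingpong_pirna")) 1000L
             else NULL
    planted_locus(classes[i], chrom = paste0("chr", chrom), anchor = anchor,
                  n_reads = n_reads[i], width = width)
  })
}
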
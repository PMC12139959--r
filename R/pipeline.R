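#' Pipeline configuration
#'
#' Bundles every tunable of the analysis flow with the defaults of the
#' standard operating point: 15-30 nt length screen, 20-24 nt Dicer window
#' with 2-nt overhangs, Ping-Pong focal overlap 10, phasing focal distance 1,
#' merge distance 500 bp and a >= 1000 RPM locus filter.
#'
#' @param alignments path to SAM/BAM/BED alignments.
#' @param genome path to the genome FASTA or a two-column
#'   `chrom<TAB>length` text file.
#' @param out_dir output directory.
#' @param min_len,max_len read-length screen.
#' @param dicer_min_len,dicer_max_len,overhang Dicer-pair parameters.
#' @param max_overlap,pingpong_focal Ping-Pong histogram range and focal bin.
#' @param max_dist,phasing_focal phasing histogram range and focal bin.
#' @param min_cov coverage for region calling.
#' @param merge_distance,min_rpm locus operating point.
#' @param pirna_frac,dicer_frac,z_min,min_reads_sig classification
#'   thresholds.
#' @param run_sweep also evaluate the full merge x RPM threshold sweep.
#' @param merge_grid,rpm_grid sweep grids.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alignments, genome, out_dir,
                            min_len = 15, max_len = 30,
                            dicer_min_len = 20, dicer_max_len = 24,
                            overhang = 2,
                            max_overlap = 30, pingpong_focal = 10,
                            max_dist = 9, phasing_focal = 1,
                            min_cov = 1, merge_distance = 500,
                            min_rpm = 1000,
                            pirna_frac = 0.5, dicer_frac = 0.5, z_min = 2,
                            min_reads_sig = 10,
                            run_sweep = FALSE,
                            merge_grid = c(0, 5, 50, 500, 5000, 50000),
                            rpm_grid = c(0, 1, 10, 100, 1e3, 1e4, 1e5, 1e6)) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

.load_genome_lengths <- function(path) {
  if (!file.exists(path)) stopf("cannot read genome file '%s'", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    dna <- Biostrings::readDNAStringSet(path)
    setNames(Biostrings::width(dna), sub("\\s.*", "", names(dna)))
  } else {
    tab <- read.table(path, col.names = c("chrom", "length"),
                      colClasses = c("character", "integer"))
    setNames(tab$length, tab$chrom)
  }
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage %s: %s", name, conditionMessage(e)))
}

#' Run the full small-RNA analysis pipeline
#'
#' load -> library stats and global signatures -> region calling, merging and
#' RPM filtering -> per-locus size profiles, signatures and classification ->
#' per-locus counts, with an optional threshold sweep.  All artifacts are
#' deterministic: rerunning with the same configuration and inputs writes
#' byte-identical files.  The resolved configuration is always written next
#' to the outputs as provenance, and a stage log (`pipeline.log`, no
#' timestamps) records read-count conservation.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress the stage log on stderr.
#' @return Invisibly, a list with the in-memory results (`library`, `stats`,
#'   `signatures`, `loci`, `classes`, `sweep`) and `paths` of the artifacts:
#'   `stats.json`, `loci.bed`, `classes.tsv`, `counts.tsv`, optional
#'   `sweep.tsv`, `config_used.yaml`, `pipeline.log`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(c("stats.json", "loci.bed", "classes.tsv", "counts.tsv",
                    "sweep.tsv", "config_used.yaml", "pipeline.log"),
                  function(f) file.path(config$out_dir, f), "")

  glens <- .stage("load", .load_genome_lengths(config$genome))
  lib <- .stage("load", {
    if (!file.exists(config$alignments))
      stopf("missing input '%s'", config$alignments)
    load_alignments(config$alignments, min_len = config$min_len,
                    max_len = config$max_len)
  })
  lib$metadata$genome_lengths <- glens
  log_ <- attr(lib, "load_log")
  say("stage load: %d records in, %d retained (%s excluded)",
      log_$input, log_$retained,
      paste(names(log_$excluded), unlist(log_$excluded), sep = "=",
            collapse = ", "))

  sig <- .stage("signatures", {
    list(dicer_percent = dicer_pair_fraction(
           lib, config$dicer_min_len, config$dicer_max_len, config$overhang),
         pingpong = overlap_histogram(lib, config$max_overlap,
                                      config$pingpong_focal),
         phasing = phasing_histogram(lib, config$max_dist,
                                     config$phasing_focal))
  })
  say("stage signatures: dicer %.3f%%, ping-pong z %.2f, phasing z %.2f",
      sig$dicer_percent, sig$pingpong$z, sig$phasing$z)

  loci <- .stage("loci", {
    regions <- call_regions(lib, min_cov = config$min_cov)
    merged <- merge_regions(regions, config$merge_distance)
    rpm_filter(annotate_loci(merged, lib), min_rpm = config$min_rpm)
  })
  say("stage loci: %d loci (merge %d bp, >= %g RPM), %d/%d reads assigned",
      nrow(loci), config$merge_distance, config$min_rpm,
      sum(loci$read_count), lib$total_alignments)

  sweep <- NULL
  if (isTRUE(config$run_sweep)) {
    sweep <- .stage("sweep",
      threshold_sweep(lib, glens, config$merge_grid, config$rpm_grid,
                      config$min_cov))
    say("stage sweep: %d grid cells", nrow(sweep))
  }

  classes <- .stage("profile", {
    sm <- locus_size_matrix(loci, lib)
    zs <- per_locus_signatures(loci, lib, min_reads = config$min_reads_sig,
                               max_overlap = config$max_overlap,
                               max_dist = config$max_dist)
    cl <- classify_loci(sm, zs, config$pirna_frac, config$dicer_frac,
                        config$z_min)
    ord <- cluster_order(z_normalize_rows(sm))
    cl$heatmap_order <- match(seq_len(nrow(cl)), ord)
    cl
  })
  say("stage profile: %s",
      paste(names(table(classes$label)), table(classes$label), sep = "=",
            collapse = ", "))

  counts <- .stage("quant", count_matrix(loci, list(sample = lib)))

  .stage("write", {
    stats <- library_stats(lib)
    jsonlite::write_json(list(
      load = log_,
      total_alignments = stats$total_alignments,
      per_length = as.list(stats$per_length),
      per_strand = as.list(stats$per_strand),
      dicer_percent = sig$dicer_percent,
      pingpong = list(counts = as.list(sig$pingpong$counts),
                      focal = sig$pingpong$focal, z = sig$pingpong$z),
      phasing = list(counts = as.list(sig$phasing$counts),
                     focal = sig$phasing$focal, z = sig$phasing$z)),
      paths[["stats.json"]], auto_unbox = TRUE, digits = NA)
    loci_out <- loci
    loci_out$label <- classes$label[match(loci_out$locus_id,
                                          classes$locus_id)]
    write_loci_bed(loci_out, paths[["loci.bed"]])
    write.table(classes, paths[["classes.tsv"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    export_counts(counts, paths[["counts.tsv"]])
    if (!is.null(sweep))
      write.table(sweep, paths[["sweep.tsv"]], sep = "\t", quote = FALSE,
                  row.names = FALSE)
    write_pipeline_config(config, paths[["config_used.yaml"]])
    writeLines(log_lines, paths[["pipeline.log"]])
  })

  if (is.null(sweep)) paths <- paths[names(paths) != "sweep.tsv"]
  invisible(list(library = lib, signatures = sig, loci = loci,
                 classes = classes, counts = counts, sweep = sweep,
                 paths = paths))
}
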
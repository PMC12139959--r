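test_that("genome generation is deterministic under the seed and validated", {
  cfg <- sim_config(n_chroms = 2, chrom_length = 10000, seed = 7)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(unname(genome_lengths(g1)), c(10000, 10000))
  expect_true(all(strsplit(g1[[1]], "")[[1]] %in% c("A", "C", "G", "T")))

  g3 <- generate_genome(sim_config(n_chroms = 2, chrom_length = 10000,
                                   seed = 8))
  expect_false(identical(unclass(g1), unclass(g3)))

  expect_error(sim_config(n_chroms = 0), "n_chroms")
  expect_error(sim_config(chrom_length = 500), "chrom_length")
})

test_that("planted geometries are forced by the class definitions", {
  g <- generate_genome(sim_config(seed = 1, chrom_length = 10000))

  set.seed(1)
  dd <- plant_locus(g, planted_locus("dicer_duplex", anchor = 100,
                                     n_reads = 2, length_range = c(21, 21),
                                     width = 1))
  expect_equal(dd[dd$strand == "+", c("start", "end")],
               data.frame(start = 100, end = 121),
               ignore_attr = TRUE)
  expect_equal(dd[dd$strand == "-", c("start", "end")],
               data.frame(start = 98, end = 119),
               ignore_attr = TRUE)

  set.seed(1)
  pp <- plant_locus(g, planted_locus("pingpong_pirna", anchor = 100,
                                     n_reads = 2, length_range = c(28, 28),
                                     width = 1, strand = "+"))
  expect_equal(pp[pp$strand == "+", c("start", "end")],
               data.frame(start = 100, end = 128),
               ignore_attr = TRUE)
  expect_equal(pp[pp$strand == "-", c("start", "end")],
               data.frame(start = 82, end = 110),
               ignore_attr = TRUE)

  set.seed(1)
  ph <- plant_locus(g, planted_locus("phased_pirna", anchor = 100,
                                     n_reads = 3, length_range = c(28, 28),
                                     u1_prob = 1, strand = "+"))
  expect_equal(ph$start, c(100, 128, 156))
  expect_equal(ph$end, c(128, 156, 184))
  expect_equal(ph$first_nt, c("U", "U", "U"))

  set.seed(1)
  mi <- plant_locus(g, planted_locus("mirna_like", anchor = 500,
                                     n_reads = 10))
  expect_lte(length(unique(ifelse(mi$strand == "+", mi$start,
                                  mi$end - 1L))), 2L)
  expect_equal(length(unique(mi$strand)), 1L)

  expect_error(
    plant_locus(g, planted_locus("phased_pirna", anchor = 9990,
                                 n_reads = 10, strand = "+")),
    "outside")
})

test_that("planted geometry satisfies the signature predicates it encodes", {
  # background off: the scans must recover exactly the manifest counts
  sim <- simulate_library(sim_config(seed = 11, loci_specs = list(
    planted_locus("dicer_duplex", chrom = "chr1", anchor = 5000,
                  n_reads = 100))))
  expect_equal(dicer_pair_fraction(sim$library), sim$manifest$dicer_percent)
  expect_equal(sum(sim$manifest$loci$dicer_pair_alignments), 100)

  for (s in c("+", "-")) {
    simp <- simulate_library(sim_config(seed = 12, loci_specs = list(
      planted_locus("pingpong_pirna", anchor = 8000, n_reads = 100,
                    strand = s))))
    oh <- overlap_histogram(simp$library)
    expect_equal(oh$counts[["10"]],
                 sum(simp$manifest$loci$pairs_overlap10))

    simz <- simulate_library(sim_config(seed = 13, loci_specs = list(
      planted_locus("phased_pirna", anchor = 20000, n_reads = 20,
                    u1_prob = 1, strand = s))))
    ph <- phasing_histogram(simz$library)
    expect_equal(ph$counts[["1"]], 19)  # k head-to-tail reads, k-1 joints
    expect_equal(sum(simz$manifest$loci$d1_count), 19)
  }
})

test_that("simulated libraries conserve counts and reproduce exactly", {
  cfg <- sim_config(seed = 5, loci_specs = list(
    planted_locus("pingpong_pirna", anchor = 5000, n_reads = 40),
    planted_locus("degradation", anchor = 12000, n_reads = 25)),
    background_reads = 111)
  sim <- simulate_library(cfg)
  expect_equal(sim$manifest$totals$total,
               sum(sim$manifest$loci$n_reads) + 111)
  expect_equal(sim$library$total_alignments, sim$manifest$totals$total)
  expect_equal(nrow(sim$library$reads), sim$library$total_alignments)

  sim2 <- simulate_library(cfg)
  expect_identical(sim$library, sim2$library)
  expect_identical(sim$manifest, sim2$manifest)

  empty <- simulate_library(sim_config(seed = 2))
  expect_equal(nrow(empty$library$reads), 0)
  expect_equal(nrow(empty$manifest$loci), 0)
})

test_that("overlapping planted loci are rejected unless permitted", {
  specs <- list(
    planted_locus("degradation", anchor = 5000, n_reads = 10),
    planted_locus("degradation", anchor = 5100, n_reads = 10))
  expect_error(simulate_library(sim_config(seed = 1, loci_specs = specs)),
               "overlap")
  sim <- simulate_library(sim_config(seed = 1, loci_specs = specs,
                                     allow_overlap = TRUE))
  expect_equal(sim$library$total_alignments, 20)
})

test_that("background reads honour the configured length range and strands", {
  sim <- simulate_library(sim_config(seed = 3, background_reads = 500,
                                     background_length_range = c(15, 17)))
  expect_true(all(sim$library$reads$length %in% 15:17))
  expect_true(all(c("+", "-") %in% sim$library$reads$strand))
  expect_true(all(sim$library$reads$end <= 50000))
})
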
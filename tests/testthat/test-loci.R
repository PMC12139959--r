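stack_reads <- function(start, end, n, chrom = "chr1") {
  data.frame(chrom = chrom, strand = "+", start = rep(start, n),
             end = rep(end, n))
}

test_that("region calling equals the per-base coverage oracle", {
  one <- srna_library(data.frame(chrom = "chr1", strand = "+", start = 100,
                                 end = 128))
  expect_equal(call_regions(one),
               data.frame(chrom = "chr1", start = 100, end = 128))

  two <- srna_library(data.frame(chrom = "chr1", strand = c("+", "-"),
                                 start = c(100, 200), end = c(128, 228)))
  expect_equal(nrow(call_regions(two)), 2)

  expect_equal(nrow(call_regions(srna_library(data.frame()))), 0)

  for (seed in 1:10) {
    lib <- random_library(n = 200, seed = seed, chrom_len = 3000)
    for (mc in c(1, 3)) {
      got <- call_regions(lib, min_cov = mc)
      expect_equal(got, oracle_regions(lib, min_cov = mc))
    }
  }
})

test_that("region merging unites gaps up to the distance and is idempotent", {
  regs <- data.frame(chrom = "chr1", start = c(0, 550), end = c(100, 600))
  expect_equal(merge_regions(regs, 500),
               data.frame(chrom = "chr1", start = 0, end = 600))
  expect_equal(nrow(merge_regions(regs, 449)), 2)

  touching <- data.frame(chrom = "chr1", start = c(0, 100, 300),
                         end = c(100, 200, 400))
  m0 <- merge_regions(touching, 0)
  expect_equal(m0$start, c(0, 300))
  expect_equal(m0$end, c(200, 400))

  expect_error(merge_regions(regs, -1), "non-negative")

  for (seed in 1:10) {
    set.seed(seed)
    s <- sort(sample.int(50000, 40))
    r <- data.frame(chrom = sample(c("chr1", "chr2"), 40, TRUE),
                    start = s, end = s + sample(20:400, 40, TRUE))
    for (md in c(0, 5, 50, 500)) {
      m1 <- merge_regions(r, md)
      expect_identical(merge_regions(m1, md), m1)
      # sorted, disjoint
      for (chrom in unique(m1$chrom)) {
        g <- m1[m1$chrom == chrom, ]
        if (nrow(g) > 1)
          expect_true(all(g$start[-1] > g$end[-nrow(g)]))
      }
    }
  }
})

test_that("RPM filtering keeps the inclusive boundary", {
  lib <- srna_library(stack_reads(0, 28, 10), total_alignments = 1e6)
  loci <- annotate_loci(call_regions(lib), lib)
  expect_equal(nrow(rpm_filter(loci, min_rpm = 1000)), 0)  # 10 RPM

  lib2 <- srna_library(stack_reads(0, 28, 1000), total_alignments = 1e6)
  loci2 <- annotate_loci(call_regions(lib2), lib2)
  expect_equal(loci2$rpm, 1000)
  expect_equal(nrow(rpm_filter(loci2, min_rpm = 1000)), 1)  # exactly 1000

  expect_error(rpm_filter(loci2, total_alignments = 0), "positive")

  # direct-filter oracle on random loci
  set.seed(9)
  fake <- data.frame(chrom = "chr1", start = 1:50 * 1000L,
                     end = 1:50 * 1000L + 500L,
                     locus_id = sprintf("l%02d", 1:50),
                     read_count = sample.int(5000, 50))
  fake$rpm <- fake$read_count / 1e6 * 1e6
  got <- rpm_filter(fake, min_rpm = 2000)
  expect_equal(got$locus_id, fake$locus_id[fake$rpm >= 2000])
})

test_that("genome fraction is locus length over genome length, in percent", {
  loci <- data.frame(chrom = "chr1", start = 100, end = 460)
  expect_equal(genome_fraction(loci, c(chr1 = 100000)), 0.36)
  expect_equal(genome_fraction(loci[0, ], c(chr1 = 100000)), 0)
  expect_error(genome_fraction(loci, numeric()), "length table")

  set.seed(4)
  s <- sort(sample.int(90000, 30)); e <- s + sample(100:900, 30, TRUE)
  r <- data.frame(chrom = "chr1", start = s, end = e)
  expect_equal(genome_fraction(r, c(chr1 = 2e5)), 100 * sum(e - s) / 2e5)
})

test_that("threshold sweep resolves the 450 bp gap at the expected merges", {
  lib <- srna_library(rbind(stack_reads(1000, 1360, 40),
                            stack_reads(1810, 2170, 40)))
  sw <- threshold_sweep(lib, c(chr1 = 50000),
                        merge_grid = c(0, 5, 50, 500, 5000, 50000),
                        rpm_grid = 0)
  expect_equal(sw$n_loci[sw$merge_distance %in% c(0, 5, 50)], c(2, 2, 2))
  expect_equal(sw$n_loci[sw$merge_distance >= 500], c(1, 1, 1))

  expect_error(threshold_sweep(lib, c(chr1 = 50000), merge_grid = numeric()),
               "non-empty")
})

test_that("sweep cells are monotone along both grid axes", {
  for (seed in 1:5) {
    sim <- simulate_library(sim_config(seed = seed, chrom_length = 50000,
      loci_specs = list(
        planted_locus("pingpong_pirna", anchor = 5000, n_reads = 60),
        planted_locus("degradation", anchor = 20000, n_reads = 40)),
      background_reads = 400, background_length_range = c(15, 30)))
    sw <- threshold_sweep(sim$library, genome_lengths(sim$genome))
    for (md in unique(sw$merge_distance)) {
      row <- sw[sw$merge_distance == md, ]
      row <- row[order(row$min_rpm), ]
      expect_true(all(diff(row$n_loci) <= 0))
      expect_true(all(diff(row$genome_fraction) <= 1e-12))
    }
    for (thr in unique(sw$min_rpm)) {
      col <- sw[sw$min_rpm == thr, ]
      col <- col[order(col$merge_distance), ]
      expect_true(all(diff(col$genome_fraction) >= -1e-12))
    }
  }
})

test_that("widely separated loci never merge; close ones always do", {
  far <- srna_library(rbind(stack_reads(1000, 1300, 20),
                            stack_reads(52400, 52700, 20)))  # gap 51,100
  for (md in c(0, 5, 50, 500, 5000, 50000))
    expect_equal(nrow(merge_regions(call_regions(far), md)), 2)

  near <- srna_library(rbind(stack_reads(1000, 1300, 20),
                             stack_reads(1340, 1640, 20)))   # gap 40
  for (md in c(50, 500, 5000, 50000))
    expect_equal(nrow(merge_regions(call_regions(near), md)), 1)
})
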
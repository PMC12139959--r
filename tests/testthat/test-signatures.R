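lib_of <- function(...) {
  srna_library(do.call(rbind, lapply(list(...), as.data.frame)))
}
read_row <- function(chrom = "chr1", strand = "+", start, end,
                     first_nt = "N") {
  data.frame(chrom = chrom, strand = strand, start = start, end = end,
             first_nt = first_nt)
}

test_that("Dicer-pair percent follows the 2-nt both-end overhang geometry", {
  pair <- lib_of(read_row(strand = "+", start = 100, end = 121),
                 read_row(strand = "-", start = 98, end = 119))
  expect_equal(dicer_pair_fraction(pair), 100)

  plus_only <- lib_of(read_row(start = 100, end = 121),
                      read_row(start = 300, end = 321))
  expect_equal(dicer_pair_fraction(plus_only), 0)

  # out of the 20-24 window: no qualification
  long_pair <- lib_of(read_row(strand = "+", start = 100, end = 126),
                      read_row(strand = "-", start = 98, end = 124))
  expect_equal(dicer_pair_fraction(long_pair), 0)

  expect_error(dicer_pair_fraction(srna_library(data.frame())), "empty")
})

test_that("one-end overhang matching is a deliberate relaxation", {
  # start offset 2 but end offset 1: fails both-end, passes one-end
  lop <- lib_of(read_row(strand = "+", start = 100, end = 121),
                read_row(strand = "-", start = 98, end = 120))
  expect_equal(dicer_pair_fraction(lop), 0)
  expect_equal(dicer_pair_fraction(lop, both_ends = FALSE), 100)
})

test_that("overlap histogram counts opposite-strand 5'-5' overlaps per pair", {
  pp <- lib_of(read_row(strand = "+", start = 100, end = 128),
               read_row(strand = "-", start = 82, end = 110))
  oh <- overlap_histogram(pp)
  expect_equal(unname(oh$counts[["10"]]), 1)
  expect_equal(sum(oh$counts), 1)

  single <- lib_of(read_row(start = 100, end = 128),
                   read_row(start = 200, end = 228))
  expect_true(all(overlap_histogram(single)$counts == 0))

  # duplicates each count: 2 plus x 3 minus identical reads = 6 pairs
  dup <- srna_library(rbind(
    do.call(rbind, rep(list(read_row(strand = "+", start = 100, end = 128)),
                       2)),
    do.call(rbind, rep(list(read_row(strand = "-", start = 82, end = 110)),
                       3))))
  expect_equal(unname(overlap_histogram(dup)$counts[["10"]]), 6)
})

test_that("phasing histogram pairs 1U reads with their nearest upstream", {
  adj <- lib_of(read_row(start = 100, end = 128, first_nt = "G"),
                read_row(start = 128, end = 156, first_nt = "U"))
  expect_equal(unname(phasing_histogram(adj)$counts[["1"]]), 1)

  non_u <- lib_of(read_row(start = 100, end = 128, first_nt = "G"),
                  read_row(start = 128, end = 156, first_nt = "A"))
  expect_true(all(phasing_histogram(non_u)$counts == 0))

  # nearest upstream only: the closer of two upstream candidates wins
  near <- lib_of(read_row(start = 50, end = 78, first_nt = "G"),
                 read_row(start = 72, end = 96, first_nt = "G"),
                 read_row(start = 100, end = 128, first_nt = "U"))
  ph <- phasing_histogram(near)
  expect_equal(unname(ph$counts[["5"]]), 1)  # 100 - 96 + 1
  expect_equal(sum(ph$counts), 1)

  # minus strand mirror: upstream lies to the right
  minus <- lib_of(read_row(strand = "-", start = 100, end = 128,
                           first_nt = "G"),
                  read_row(strand = "-", start = 72, end = 100,
                           first_nt = "U"))
  expect_equal(unname(phasing_histogram(minus)$counts[["1"]]), 1)
})

test_that("signature z-score matches its formula, cap and error contract", {
  expect_equal(signature_zscore(rep(5, 20), focal = 10), 0)

  h <- rep(10, 20); h[10] <- 40
  expect_equal(signature_zscore(h, focal = 10), 10)  # sd 0 -> +cap
  expect_equal(signature_zscore(h, focal = 10, cap = 99), 99)
  h2 <- rep(10, 20); h2[10] <- 0
  expect_equal(signature_zscore(h2, focal = 10), -10)

  expect_error(signature_zscore(c(3, 1, 9), focal = 1), "background bins")

  for (seed in 1:20) {
    set.seed(seed)
    counts <- rpois(30, lambda = 20)
    expect_equal(signature_zscore(counts, focal = 10),
                 oracle_zscore(counts, 10))
  }
})

test_that("scans agree exactly with brute-force enumeration", {
  for (seed in 1:10) {
    lib <- random_library(n = 150 + seed * 20, seed = seed)
    expect_identical(dicer_pair_fraction(lib), oracle_dicer_percent(lib))
    expect_identical(unname(overlap_histogram(lib)$counts),
                     oracle_overlap_hist(lib))
    expect_identical(unname(phasing_histogram(lib)$counts),
                     oracle_phasing_hist(lib))
  }
})

test_that("nucleotide bias honours position, alphabet and exclusions", {
  all_u <- lib_of(read_row(start = 0, end = 20, first_nt = "U"),
                  read_row(start = 50, end = 70, first_nt = "U"))
  expect_equal(first_nt_bias(all_u), 1.0)

  # reads shorter than the requested position leave the denominator
  mixed <- srna_library(data.frame(
    chrom = "chr1", strand = "+", start = c(0, 100), end = c(16, 128),
    seq = c(paste(rep("A", 16), collapse = ""),
            paste(c(rep("C", 19), rep("G", 9)), collapse = ""))))
  expect_equal(first_nt_bias(mixed, position = 20, nt = "G"), 1.0)

  expect_error(first_nt_bias(srna_library(data.frame())), "no reads")

  sim <- simulate_library(sim_config(seed = 3, chrom_length = 50000,
    loci_specs = list(planted_locus("phased_pirna", anchor = 10000,
                                    n_reads = 1000, u1_prob = 0.8))))
  se3 <- 3 * sqrt(0.8 * 0.2 / 1000)
  expect_lt(abs(first_nt_bias(sim$library) - 0.8), se3)
})

test_that("size distribution assigns the biogenesis bands", {
  ten22 <- srna_library(data.frame(chrom = "chr1", strand = "+",
                                   start = 0:9 * 50L, end = 0:9 * 50L + 22L))
  sd22 <- size_distribution(ten22)
  expect_equal(unname(sd22$bands["dicer_products"]), 10)

  s0 <- size_distribution(srna_library(data.frame()))
  expect_true(all(s0$counts == 0) && s0$total == 0)

  # length 25 belongs to no band but counts in the total
  one25 <- srna_library(data.frame(chrom = "chr1", strand = "+", start = 0,
                                   end = 25))
  s25 <- size_distribution(one25)
  expect_equal(sum(s25$bands), 0)
  expect_equal(s25$total, 1)

  sim <- simulate_library(sim_config(seed = 6, loci_specs = list(
    planted_locus("pingpong_pirna", anchor = 5000, n_reads = 60),
    planted_locus("degradation", anchor = 15000, n_reads = 40))))
  sb <- size_distribution(sim$library)
  expect_equal(unname(sb$bands["pirna"]), 60)
  expect_equal(unname(sb$bands["degradation"]), 40)
})
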
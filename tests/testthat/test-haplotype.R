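test_that("read_haplotype_table groups, sorts and validates blocks", {
  f <- write_hap_table(c(
    "S1\tliver\tB2\tchr2\t500\tC\tT",
    "S1\tliver\tB1\tchr1\t300\tA\tG",
    "S1\tliver\tB1\tchr1\t100\tT\tC",
    "S1\tliver\tB2\tchr2\t100\tA\tG"
  ))
  h <- read_haplotype_table(f)
  expect_s3_class(h, "equase_haplotypes")
  expect_equal(nrow(h), 4)
  # two interleaved blocks regrouped, loci sorted ascending within block
  expect_equal(h$haplotype_block_id, c("B1", "B1", "B2", "B2"))
  expect_equal(h$pos, c(100L, 300L, 100L, 500L))
})

test_that("read_haplotype_table rejects invalid blocks", {
  expect_error(read_haplotype_table(write_hap_table(
    "S1\tliver\tB1\tchr1\t100\tA\tA")), "not heterozygous")
  expect_error(read_haplotype_table(write_hap_table(c(
    "S1\tliver\tB1\tchr1\t100\tA\tG",
    "S1\tliver\tB1\tchr2\t200\tA\tG"))), "multiple chromosomes")
  expect_error(read_haplotype_table(write_hap_table(c(
    "S1\tliver\tB1\tchr1\t100\tA\tG",
    "S1\tliver\tB1\tchr1\t100\tC\tG"))), "duplicate position")
})

test_that("sex-chromosome blocks are dropped by default, kept on request", {
  f <- write_hap_table(c(
    "S1\tliver\tB1\tchr1\t100\tA\tG",
    "S1\tliver\tBX\tchrX\t100\tA\tG"
  ))
  expect_message(h <- read_haplotype_table(f), "sex chromosomes")
  expect_equal(unique(h$chrom), "chr1")
  h2 <- suppressMessages(read_haplotype_table(f, drop_sex_chrom = FALSE))
  expect_equal(sort(unique(h2$chrom)), c("chr1", "chrX"))
})

test_that("aggregate_allele_expression sums per haplotype", {
  f <- write_hap_table(c(
    "S1\tliver\tB1\tchr1\t100\tA\tG",
    "S1\tliver\tB1\tchr1\t200\tC\tT",
    "S1\tliver\tB2\tchr1\t900\tA\tC"
  ))
  h <- read_haplotype_table(f)
  tal <- parse_mpileup(text = c(
    "chr1\t100\tA\t40\t..........,,,,,,,,,,..........GGGGGggggg\tIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII",
    "chr1\t200\tC\t40\tCCCCCCCCCCCCCCCCCCCCCCCCCtttTTTTTTTTTTTT\tIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII"
  ))
  ae <- aggregate_allele_expression(h, tal)
  b1 <- ae[ae$block == "B1", ]
  expect_equal(b1$expr_h1, 30L + 25L)
  expect_equal(b1$expr_h2, 10L + 15L)
  expect_equal(b1$n_loci_observed, 2L)
  # uncovered block: zeros, not an error
  b2 <- ae[ae$block == "B2", ]
  expect_equal(c(b2$expr_h1, b2$expr_h2, b2$n_loci_observed), c(0L, 0L, 0L))
})

test_that("non-phased reads are ignored but retained as other_count", {
  f <- write_hap_table("S1\tliver\tB1\tchr1\t100\tA\tG")
  h <- read_haplotype_table(f)
  tal <- parse_mpileup(text = "chr1\t100\tA\t20\t..........GGGGGTTTTT\tIIIIIIIIIIIIIIIIIIII")
  ae <- aggregate_allele_expression(h, tal)
  expect_equal(ae$expr_h1, 10L)
  expect_equal(ae$expr_h2, 5L)
  expect_equal(ae$other_count, 5L)
})

test_that("aggregation matches the brute-force oracle on random fixtures", {
  set.seed(99)
  for (rep in 1:20) {
    n_blocks <- sample(1:5, 1)
    rows <- character(0)
    tal_lines <- character(0)
    pos0 <- 0
    for (b in seq_len(n_blocks)) {
      n <- sample(1:6, 1)
      pos <- pos0 + sort(sample(1000, n)); pos0 <- pos0 + 2000
      for (p in pos) {
        al <- sample(c("A", "C", "G", "T"), 2)
        rows <- c(rows, sprintf("S1\tliver\tB%d\tchr1\t%d\t%s\t%s", b, p, al[1], al[2]))
        if (runif(1) < 0.8) {  # some loci uncovered
          cnt <- sample(0:30, 4, replace = TRUE)
          bases <- paste0(strrep("A", cnt[1]), strrep("C", cnt[2]),
                          strrep("G", cnt[3]), strrep("T", cnt[4]))
          if (nchar(bases) == 0) bases <- "A"
          tal_lines <- c(tal_lines, sprintf("chr1\t%d\tN\t%d\t%s\t%s",
                                            p, nchar(bases), bases,
                                            strrep("I", nchar(bases))))
        }
      }
    }
    h <- read_haplotype_table(write_hap_table(rows))
    tal <- parse_mpileup(text = tal_lines)
    got <- aggregate_allele_expression(h, tal)
    exp <- oracle_aggregate(h, tal)
    m <- match(got$block, exp$block)
    expect_equal(got$expr_h1, exp$expr_h1[m])
    expect_equal(got$expr_h2, exp$expr_h2[m])
    expect_equal(got$other_count, exp$other_count[m])
    expect_equal(got$n_loci_observed, exp$n_loci_observed[m])
    # conservation: allele evidence cannot exceed total depth
    expect_true(all(got$expr_h1 + got$expr_h2 + got$other_count <= sum(tal$depth)))
  }
})

test_that("swapping the phased alleles swaps expression exactly", {
  f <- write_hap_table(c(
    "S1\tliver\tB1\tchr1\t100\tA\tG",
    "S1\tliver\tB1\tchr1\t200\tC\tT"
  ))
  h <- read_haplotype_table(f)
  tal <- parse_mpileup(text = c(
    "chr1\t100\tA\t12\t.......GGGgg\tIIIIIIIIIIII",
    "chr1\t200\tC\t9\tCCCCttTTT\tIIIIIIIII"
  ))
  ae <- aggregate_allele_expression(h, tal)
  h_swapped <- h
  h_swapped$allele_h1 <- h$allele_h2
  h_swapped$allele_h2 <- h$allele_h1
  ae_sw <- aggregate_allele_expression(h_swapped, tal)
  expect_equal(ae$expr_h1, ae_sw$expr_h2)
  expect_equal(ae$expr_h2, ae_sw$expr_h1)
  # permutation invariance in locus order
  ae_rev <- aggregate_allele_expression(h[rev(seq_len(nrow(h))), ], tal)
  expect_equal(ae_rev$expr_h1, ae$expr_h1)
  expect_equal(ae_rev$expr_h2, ae$expr_h2)
})
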
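cons_frame <- function(consequence) {
  data.frame(chrom = "chr1", pos = seq_along(consequence) * 10L,
             gene_id = "G1", gene_symbol = "G1",
             consequence = consequence, stringsAsFactors = FALSE)
}

test_that("filter_consequences removes exclusively intronic/intergenic loci", {
  cons <- cons_frame(c("intron_variant",
                       "intron_variant&missense_variant",
                       "3_prime_UTR_variant",
                       "intergenic_variant",
                       "intron_variant&intergenic_variant",
                       "splice_region_variant&intron_variant"))
  fc <- filter_consequences(cons)
  expect_equal(fc$removed$consequence,
               c("intron_variant", "intergenic_variant",
                 "intron_variant&intergenic_variant"))
  expect_equal(nrow(fc$kept) + nrow(fc$removed), nrow(cons))
  expect_equal(intersect(fc$kept$pos, fc$removed$pos), integer(0))
  # idempotent on the kept set
  fc2 <- filter_consequences(fc$kept)
  expect_equal(fc2$kept, fc$kept)
  expect_equal(nrow(fc2$removed), 0)
})

test_that("unknown consequence terms warn and are kept", {
  expect_warning(fc <- filter_consequences(cons_frame("made_up_term")),
                 "made_up_term")
  expect_equal(nrow(fc$kept), 1)
})

test_that("consequence_type_summary reports combination percentages", {
  cons <- cons_frame(c(rep("3_prime_UTR_variant", 335),
                       rep("missense_variant", 135),
                       rep("synonymous_variant", 774 - 335 - 135)))
  s <- consequence_type_summary(cons)
  expect_equal(s$percent[s$consequence == "3_prime_UTR_variant"], 43.28)
  expect_equal(s$percent[s$consequence == "missense_variant"], 17.44)
  s1 <- consequence_type_summary(cons_frame("stop_gained"))
  expect_equal(s1$percent, 100)
  # term sets are sorted before joining, so order never splits a combination
  s2 <- consequence_type_summary(
    cons_frame(c("missense_variant&splice_region_variant",
                 "splice_region_variant&missense_variant")))
  expect_equal(nrow(s2), 1)
  expect_equal(s2$count, 2L)
})

test_that("read_consequence_table merges VEP rows per locus", {
  f <- tempfile()
  writeLines(c(
    "## VEP output",
    paste("#Uploaded_variation", "Location", "Allele", "Gene", "Feature",
          "Feature_type", "Consequence", "Extra", sep = "\t"),
    "v1\tchr1:100\tA\tENSECAG1\tT1\tTranscript\tintron_variant\tSYMBOL=ABC",
    "v1\tchr1:100\tA\tENSECAG1\tT2\tTranscript\tmissense_variant\tSYMBOL=ABC",
    "v2\tchr2:50\tG\tENSECAG2\tT3\tTranscript\t3_prime_UTR_variant\t-"
  ), f)
  cons <- read_consequence_table(f)
  expect_equal(nrow(cons), 2)
  expect_equal(cons$consequence[cons$pos == 100],
               "intron_variant&missense_variant")
  expect_equal(cons$gene_symbol[1], "ABC")
  # the merged locus survives filtering ("exclusively" fails)
  fc <- filter_consequences(cons)
  expect_equal(nrow(fc$removed), 0)
})

test_that("haplotype_region spans first to last heterozygous position", {
  h <- read_haplotype_table(write_hap_table(c(
    "S1\tliver\tB1\tchr1\t400\tA\tG",
    "S1\tliver\tB1\tchr1\t100\tC\tT",
    "S1\tliver\tB1\tchr1\t250\tA\tT",
    "S1\tliver\tB2\tchr2\t77\tA\tG"
  )))
  r <- haplotype_region(h)
  expect_equal(r$start[r$block == "B1"], 100L)
  expect_equal(r$end[r$block == "B1"], 400L)
  expect_equal(c(r$start[r$block == "B2"], r$end[r$block == "B2"]), c(77L, 77L))
})

test_that("overlap_marks intersects closed intervals per tissue and sample", {
  regions <- data.frame(sample = "S1", tissue = "liver", block = c("B1", "B2"),
                        chrom = "chr1", start = c(100L, 100L), end = c(200L, 200L),
                        stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chr1", start = c(150L, 201L), end = c(250L, 300L),
                      mark = "H3K27ac", tissue = "liver",
                      sample = c("S1", "S1"), stringsAsFactors = FALSE)
  out <- overlap_marks(regions[1, ], peaks[1, ])
  expect_true(out$H3K27ac)
  # adjacency in closed coordinates is not overlap
  out2 <- overlap_marks(regions[1, ], peaks[2, ])
  expect_false(out2$H3K27ac)
  # other-sample peaks do not count unless cross_sample = TRUE
  peaks$sample <- "S2"
  expect_false(overlap_marks(regions[1, ], peaks[1, ])$H3K27ac)
  expect_true(overlap_marks(regions[1, ], peaks[1, ], cross_sample = TRUE)$H3K27ac)
})

test_that("overlap_marks agrees with the all-pairs oracle on random intervals", {
  set.seed(13)
  n <- 300
  regions <- data.frame(
    sample = sample(c("S1", "S2"), n, TRUE),
    tissue = sample(c("liver", "heart"), n, TRUE),
    block = paste0("B", seq_len(n)),
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    start = sample(10000L, n, TRUE), stringsAsFactors = FALSE)
  regions$end <- regions$start + sample(0:500, n, TRUE)
  peaks <- data.frame(
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    start = sample(10000L, n, TRUE), stringsAsFactors = FALSE)
  peaks$end <- peaks$start + sample(0:500, n, TRUE)
  peaks$mark <- sample(equase_marks(), n, TRUE)
  peaks$tissue <- sample(c("liver", "heart"), n, TRUE)
  peaks$sample <- sample(c("S1", "S2"), n, TRUE)
  got <- overlap_marks(regions, peaks)
  want <- oracle_overlap(regions, peaks)
  for (mk in equase_marks()) expect_equal(got[[mk]], unname(want[, mk]))
  # symmetry: swapping region/peak roles finds the same intersecting pairs
  rev_regions <- data.frame(sample = peaks$sample, tissue = peaks$tissue,
                            block = paste0("P", seq_len(n)), chrom = peaks$chrom,
                            start = peaks$start, end = peaks$end,
                            stringsAsFactors = FALSE)
  rev_peaks <- data.frame(chrom = regions$chrom, start = regions$start,
                          end = regions$end, mark = "H3K27ac",
                          tissue = regions$tissue, sample = regions$sample,
                          stringsAsFactors = FALSE)
  got_rev <- overlap_marks(rev_regions, rev_peaks)
  want_rev <- oracle_overlap(rev_regions, rev_peaks)
  expect_equal(got_rev$H3K27ac, unname(want_rev[, "H3K27ac"]))
})

test_that("read_peaks converts BED coordinates and validates marks", {
  f <- tempfile()
  writeLines(c("chr1\t99\t200\tH3K27ac\tliver\tS1",
               "chr1\t0\t10\tH3K4me3\tliver\tS1"), f)
  p <- read_peaks(f)
  expect_equal(p$start, c(100L, 1L))  # 0-based half-open -> 1-based closed
  expect_equal(p$end, c(200L, 10L))
  f2 <- tempfile()
  writeLines("chr1\t5\t50\tH3K99x\tliver\tS1", f2)
  expect_error(read_peaks(f2), "unknown histone mark")
  f3 <- tempfile()
  writeLines("chr1\t5\t50", f3)
  expect_error(read_peaks(f3), "labels")
  p3 <- read_peaks(f3, mark = "H3K4me1", tissue = "liver", sample = "S1")
  expect_equal(p3$mark, "H3K4me1")
})

test_that("mark_combination_summary counts marks and exclusive combinations", {
  mk <- data.frame(H3K27ac = c(TRUE, TRUE, FALSE, FALSE),
                   H3K4me1 = c(TRUE, FALSE, FALSE, FALSE),
                   H3K4me3 = c(FALSE, FALSE, TRUE, FALSE),
                   H3K27me3 = FALSE)
  s <- mark_combination_summary(mk)
  expect_equal(s$n_any, 3L)
  expect_equal(s$n_multi, 1L)
  expect_equal(sum(s$combinations$count), s$n_any)
  expect_equal(s$per_mark$count[s$per_mark$mark == "H3K27ac"], 2L)
  # printed-precision reproduction: 497/774 and 369/497
  mk2 <- data.frame(H3K27ac = rep(c(TRUE, TRUE, FALSE), c(369, 128, 277)),
                    H3K4me1 = rep(c(TRUE, FALSE), c(369, 405)),
                    H3K4me3 = FALSE, H3K27me3 = FALSE)
  s2 <- mark_combination_summary(mk2)
  expect_equal(s2$pct_any, 64.2)
  expect_equal(s2$pct_multi, 74.2)
  # no peaks: all counts zero
  s3 <- mark_combination_summary(mk[0, ])
  expect_equal(s3$n_any, 0L)
})
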
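# Small in-code fixtures shared across test files.

mpileup_line <- function(chrom, pos, ref, bases, quals = strrep("I", nchar(bases))) {
  paste(chrom, pos, ref, nchar(gsub("[$^+0-9<>]|\\^.", "", bases)), bases, quals,
        sep = "\t")
}

# Random mpileup base column with known counts; returns list(string, counts).
random_tally_string <- function(max_depth = 40) {
  ref <- sample(c("A", "C", "G", "T"), 1)
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  depth <- sample.int(max_depth, 1)
  syms <- character(0)
  for (i in seq_len(depth)) {
    b <- sample(c("A", "C", "G", "T"), 1)
    counts[b] <- counts[b] + 1L
    syms <- c(syms, if (b == ref) sample(c(".", ","), 1)
              else sample(c(b, tolower(b)), 1))
  }
  list(string = paste(sample(syms), collapse = ""), ref = ref, counts = counts)
}

hap_table_text <- function(rows) {
  header <- "sample\ttissue\thaplotype_block_id\tchrom\tpos\tallele_h1\tallele_h2"
  c(header, rows)
}

write_hap_table <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  writeLines(hap_table_text(rows), f)
  f
}

# A minimal allele-expression data frame for call_ase().
ae_frame <- function(expr_h1, expr_h2, sample = "S1", tissue = "liver") {
  n <- length(expr_h1)
  data.frame(
    sample = rep_len(sample, n), tissue = rep_len(tissue, n),
    block = paste0("B", seq_len(n)), gene_id = NA_character_,
    chrom = "chr1", start = seq_len(n) * 100L, end = seq_len(n) * 100L + 50L,
    n_loci = 1L, n_loci_observed = 1L,
    expr_h1 = as.integer(expr_h1), expr_h2 = as.integer(expr_h2),
    other_count = 0L, stringsAsFactors = FALSE
  )
}

# Run the full simulate -> parse -> aggregate -> call chain in memory.
run_chain <- function(cfg, out_dir = tempfile()) {
  sim <- simulate_cohort(cfg, out_dir)
  res <- run_discovery(list(haplotypes = file.path(out_dir, "haplotypes.tsv"),
                            pileup_dir = file.path(out_dir, "pileup"),
                            out = file.path(out_dir, "out")))
  list(sim = sim, res = res)
}

# The validation cohort shape whose printed summary numbers the study
# reports: 155 loci, 8,849 comparisons, 7,436 significant, 7,019 of those in
# the discovery direction, 85 loci significant in >= 90% of their samples.
acceptance_validation_frame <- function() {
  n_per <- rep(57L, 155); n_per[1:14] <- 58L          # sums to 8,849
  sig_per <- integer(155)
  sig_per[1:85] <- n_per[1:85]                        # fully replicating loci
  sig_per[86:142] <- 37L                              # partial replication,
  sig_per[143:155] <- 36L                             # below the 90% bar
  rows <- do.call(rbind, lapply(1:155, function(i) {
    data.frame(sample_id = paste0("V", seq_len(n_per[i])),
               chrom = "chr1", pos = i,
               significant = rep(c(TRUE, FALSE), c(sig_per[i], n_per[i] - sig_per[i])),
               direction_match = TRUE, stringsAsFactors = FALSE)
  }))
  sig_idx <- which(rows$significant)
  rows$direction_match[sig_idx[1:417]] <- FALSE       # 7,436 - 7,019 discordant
  rows
}
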
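#' Read a phased heterozygous-locus table
#'
#' Consumes the tab-delimited phased-loci format produced downstream of
#' long-read isoform phasing: one row per heterozygous locus with the
#' nucleotide carried by each haplotype. Rows are grouped into haplotype
#' blocks by (sample, tissue, haplotype_block_id); loci within a block are
#' sorted by position and must be unique and on a single chromosome.
#' Blocks on sex chromosomes are dropped by default (the analysis is
#' restricted to autosomes).
#'
#' @param file path to a tab-delimited table (optionally gzipped) with
#'   columns `sample`, `tissue`, `haplotype_block_id`, `chrom`, `pos`,
#'   `allele_h1`, `allele_h2` and optionally `gene_id`.
#' @param drop_sex_chrom drop blocks on chrX/chrY (default TRUE).
#' @return data frame of class `equase_haplotypes`, one row per locus,
#'   ordered by sample, tissue, block and position.
#' @export
read_haplotype_table <- function(file, drop_sex_chrom = TRUE) {
  con <- open_text(file)
  df <- read.delim(con, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample", "tissue", "haplotype_block_id", "chrom", "pos",
                "allele_h1", "allele_h2")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("haplotype table is missing column(s): %s",
          paste(missing, collapse = ", "))
  if (!"gene_id" %in% names(df)) df$gene_id <- NA_character_
  df$pos <- as.integer(df$pos)
  df$allele_h1 <- toupper(df$allele_h1)
  df$allele_h2 <- toupper(df$allele_h2)

  bad_allele <- !(df$allele_h1 %in% BASES & df$allele_h2 %in% BASES)
  if (any(bad_allele))
    stopf("non-ACGT allele in block '%s' at %s:%d",
          df$haplotype_block_id[bad_allele][1],
          df$chrom[bad_allele][1], df$pos[bad_allele][1])
  hom <- df$allele_h1 == df$allele_h2
  if (any(hom))
    stopf("locus %s:%d in block '%s' is not heterozygous (both haplotypes '%s')",
          df$chrom[hom][1], df$pos[hom][1],
          df$haplotype_block_id[hom][1], df$allele_h1[hom][1])

  key <- group_key(df$sample, df$tissue, df$haplotype_block_id)
  n_chrom <- tapply(df$chrom, key, function(x) length(unique(x)))
  if (any(n_chrom > 1))
    stopf("haplotype block '%s' spans multiple chromosomes",
          df$haplotype_block_id[key == names(n_chrom)[n_chrom > 1][1]][1])
  dup <- duplicated(cbind(key, df$pos))
  if (any(dup))
    stopf("duplicate position %s:%d within block '%s'",
          df$chrom[dup][1], df$pos[dup][1], df$haplotype_block_id[dup][1])

  if (drop_sex_chrom) {
    sex <- toupper(sub("^chr", "", df$chrom, ignore.case = TRUE)) %in% c("X", "Y")
    if (any(sex)) {
      message(sum(sex), " loci on sex chromosomes dropped (",
              length(unique(key[sex])), " block(s)); use drop_sex_chrom = FALSE to keep")
      df <- df[!sex, , drop = FALSE]
    }
  }
  df <- df[order(df$sample, df$tissue, df$haplotype_block_id, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("equase_haplotypes", "data.frame")
  df
}

#' Sum per-locus nucleotide counts into haplotype allele expression
#'
#' For each haplotype block, the read count supporting the haplotype-1
#' nucleotide is summed across the block's covered loci, and likewise for
#' haplotype 2. Loci absent from the tally lookup contribute zero and are
#' excluded from `n_loci_observed`. Reads of a nucleotide matching neither
#' phased allele are not allele evidence; their total is retained per block
#' as `other_count` for QC.
#'
#' @param haps an `equase_haplotypes` data frame (see
#'   [read_haplotype_table()]).
#' @param tally a `locus_tally` data frame (see [parse_mpileup()]); loci are
#'   matched on (chrom, pos).
#' @return data frame with one row per haplotype block: `sample`, `tissue`,
#'   `block`, `gene_id`, `chrom`, `start`, `end`, `n_loci`,
#'   `n_loci_observed`, `expr_h1`, `expr_h2`, `other_count`.
#' @export
aggregate_allele_expression <- function(haps, tally) {
  stopifnot(is.data.frame(haps), is.data.frame(tally))
  key <- group_key(haps$sample, haps$tissue, haps$haplotype_block_id)
  ukey <- unique(key)
  m <- match(group_key(haps$chrom, haps$pos), group_key(tally$chrom, tally$pos))
  covered <- !is.na(m)
  cmat <- as.matrix(tally[, BASES, drop = FALSE])
  slot1 <- match(haps$allele_h1, BASES)
  slot2 <- match(haps$allele_h2, BASES)
  c1 <- c2 <- tot <- integer(nrow(haps))
  if (any(covered)) {
    c1[covered] <- cmat[cbind(m[covered], slot1[covered])]
    c2[covered] <- cmat[cbind(m[covered], slot2[covered])]
    tot[covered] <- rowSums(cmat[m[covered], , drop = FALSE])
  }
  f <- factor(key, levels = ukey)
  first <- !duplicated(key)
  out <- data.frame(
    sample = haps$sample[first],
    tissue = haps$tissue[first],
    block = haps$haplotype_block_id[first],
    gene_id = haps$gene_id[first],
    chrom = haps$chrom[first],
    start = as.integer(tapply(haps$pos, f, min)),
    end = as.integer(tapply(haps$pos, f, max)),
    n_loci = as.integer(tabulate(f, nbins = length(ukey))),
    n_loci_observed = as.integer(tapply(covered, f, sum)),
    expr_h1 = as.integer(tapply(c1, f, sum)),
    expr_h2 = as.integer(tapply(c2, f, sum)),
    other_count = as.integer(tapply(tot - c1 - c2, f, sum)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
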
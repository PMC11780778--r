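# Controlled vocabulary of consequence terms the filter recognises (the
# commonly emitted VEP/SO terms). Unknown terms trigger a warning and are
# treated as functional (kept).
VEP_TERMS <- c(
  "transcript_ablation", "splice_acceptor_variant", "splice_donor_variant",
  "stop_gained", "frameshift_variant", "stop_lost", "start_lost",
  "transcript_amplification", "inframe_insertion", "inframe_deletion",
  "missense_variant", "protein_altering_variant", "splice_region_variant",
  "splice_donor_region_variant", "splice_donor_5th_base_variant",
  "splice_polypyrimidine_tract_variant", "incomplete_terminal_codon_variant",
  "start_retained_variant", "stop_retained_variant", "synonymous_variant",
  "coding_sequence_variant", "mature_miRNA_variant", "5_prime_UTR_variant",
  "3_prime_UTR_variant", "non_coding_transcript_exon_variant",
  "intron_variant", "NMD_transcript_variant", "non_coding_transcript_variant",
  "upstream_gene_variant", "downstream_gene_variant", "intergenic_variant"
)

# Terms that, when they exhaust a locus's annotation, exclude it.
NONFUNCTIONAL_TERMS <- c("intron_variant", "intergenic_variant")

split_terms <- function(x) strsplit(x, "[&,;]\\s*")

join_terms <- function(terms) {
  vapply(terms, function(t) paste(sort(unique(t)), collapse = "&"), "")
}

#' Read a variant-consequence table
#'
#' Accepts either the standard VEP tab-delimited output (header line starting
#' with `#Uploaded_variation`; one row per variant-feature pair, `Location`
#' as `chrom:pos`, comma-separated `Consequence`, `SYMBOL=` picked out of
#' `Extra` when present) or a simple dialect with columns
#' `chrom, pos, gene_id, gene_symbol, consequence`. Rows for one locus are
#' merged by the union of their terms before filtering.
#'
#' @param file path (optionally gzipped).
#' @return data frame with one row per locus: `chrom`, `pos`, `gene_id`,
#'   `gene_symbol`, `consequence` (sorted, ampersand-joined term union).
#' @export
read_consequence_table <- function(file) {
  con <- open_text(file)
  lines <- readLines(con)
  if (inherits(con, "connection")) close(con)
  lines <- lines[!grepl("^##", lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      gene_id = character(), gene_symbol = character(),
                      consequence = character(), stringsAsFactors = FALSE))
  if (startsWith(lines[1], "#Uploaded_variation")) {
    lines[1] <- sub("^#", "", lines[1])
    df <- read.delim(text = lines, stringsAsFactors = FALSE, check.names = FALSE)
    loc <- strsplit(df$Location, "[:-]")
    chrom <- vapply(loc, `[[`, "", 1L)
    pos <- as.integer(vapply(loc, `[[`, "", 2L))
    symbol <- rep(NA_character_, nrow(df))
    if ("Extra" %in% names(df)) {
      hit <- regmatches(df$Extra, regexpr("SYMBOL=[^;]+", df$Extra))
      has <- grepl("SYMBOL=", df$Extra)
      symbol[has] <- sub("SYMBOL=", "", hit)
    }
    raw <- data.frame(chrom = chrom, pos = pos,
                      gene_id = df$Gene, gene_symbol = symbol,
                      consequence = df$Consequence, stringsAsFactors = FALSE)
  } else {
    raw <- read.delim(text = lines, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("chrom", "pos", "consequence")
    if (!all(need %in% names(raw)))
      stopf("consequence table must have columns %s", paste(need, collapse = ", "))
    if (!"gene_id" %in% names(raw)) raw$gene_id <- NA_character_
    if (!"gene_symbol" %in% names(raw)) raw$gene_symbol <- NA_character_
    raw$pos <- as.integer(raw$pos)
  }
  key <- group_key(raw$chrom, raw$pos)
  f <- factor(key, levels = unique(key))
  first <- !duplicated(key)
  terms <- tapply(raw$consequence, f, function(x) unlist(split_terms(x)))
  pick <- function(x) {
    x <- x[!is.na(x) & x != "" & x != "-"]
    if (length(x)) x[1] else NA_character_
  }
  out <- data.frame(
    chrom = raw$chrom[first], pos = raw$pos[first],
    gene_id = as.character(tapply(raw$gene_id, f, pick)),
    gene_symbol = as.character(tapply(raw$gene_symbol, f, pick)),
    consequence = join_terms(terms),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Exclude loci annotated exclusively as intronic or intergenic
#'
#' A locus is removed iff every consequence term attached to it (across all
#' of its annotations) is `intron_variant` or `intergenic_variant`; any
#' functional component (UTR, coding, splice, ...) rescues it. Compound
#' annotations such as `splice_region_variant&intron_variant` are therefore
#' kept. Unknown terms raise a warning and count as functional.
#'
#' @param cons per-locus consequence data frame (see
#'   [read_consequence_table()]).
#' @return list with elements `kept` and `removed` (disjoint data frames
#'   whose union is the input).
#' @export
filter_consequences <- function(cons) {
  terms <- split_terms(cons$consequence)
  unknown <- setdiff(unique(unlist(terms)), VEP_TERMS)
  if (length(unknown))
    warnf("unknown consequence term(s) treated as functional: %s",
          paste(unknown, collapse = ", "))
  removed <- vapply(terms, function(t) all(t %in% NONFUNCTIONAL_TERMS), TRUE)
  list(kept = cons[!removed, , drop = FALSE],
       removed = cons[removed, , drop = FALSE])
}

#' Count consequence-combination frequencies
#'
#' Each locus contributes its full sorted, ampersand-joined term combination
#' once; percentages are against all loci in the input, half-up to two
#' decimals.
#'
#' @param cons per-locus consequence data frame (typically the `kept` set).
#' @return data frame `consequence`, `count`, `percent`, count-descending.
#' @export
consequence_type_summary <- function(cons) {
  combo <- join_terms(split_terms(cons$consequence))
  tab <- sort(table(combo), decreasing = TRUE)
  data.frame(
    consequence = names(tab),
    count = as.integer(tab),
    percent = round_half_up(100 * as.integer(tab) / nrow(cons), 2),
    stringsAsFactors = FALSE
  )
}

#' Genomic span of each haplotype block
#'
#' The interval from the first to the last heterozygous position of the
#' block, inclusive (a single-locus block spans 1 bp).
#'
#' @param haps an `equase_haplotypes` data frame.
#' @return data frame `sample`, `tissue`, `block`, `chrom`, `start`, `end`.
#' @export
haplotype_region <- function(haps) {
  key <- group_key(haps$sample, haps$tissue, haps$haplotype_block_id)
  f <- factor(key, levels = unique(key))
  first <- !duplicated(key)
  data.frame(
    sample = haps$sample[first], tissue = haps$tissue[first],
    block = haps$haplotype_block_id[first], chrom = haps$chrom[first],
    start = as.integer(tapply(haps$pos, f, min)),
    end = as.integer(tapply(haps$pos, f, max)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Read histone-mark peak intervals
#'
#' BED coordinates (0-based, half-open) are converted to 1-based closed
#' intervals on read. Either a merged BED3+3 file with columns
#' `chrom, start, end, mark, tissue, sample`, or a plain BED3 file plus
#' explicit `mark`/`tissue`/`sample` labels.
#'
#' @param file BED path (no header; optionally gzipped).
#' @param mark,tissue,sample labels applied to every record of a BED3 file.
#' @return data frame `chrom, start, end, mark, tissue, sample` (1-based
#'   closed coordinates).
#' @export
read_peaks <- function(file, mark = NULL, tissue = NULL, sample = NULL) {
  con <- open_text(file)
  df <- read.delim(con, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) >= 6) {
    df <- df[, 1:6]
    names(df) <- c("chrom", "start", "end", "mark", "tissue", "sample")
  } else if (ncol(df) >= 3) {
    if (is.null(mark) || is.null(tissue) || is.null(sample))
      stopf("BED3 peak file needs explicit mark/tissue/sample labels")
    df <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
                     mark = mark, tissue = tissue, sample = sample,
                     stringsAsFactors = FALSE)
  } else {
    stopf("peak file must have at least 3 columns")
  }
  bad <- !df$mark %in% MARKS
  if (any(bad))
    stopf("unknown histone mark '%s' (expected %s)",
          df$mark[bad][1], paste(MARKS, collapse = ", "))
  df$start <- as.integer(df$start) + 1L  # BED -> 1-based closed
  df$end <- as.integer(df$end)
  if (any(df$end < df$start)) stopf("peak with end < start after BED conversion")
  df
}

#' Overlap haplotype regions with histone-mark peaks
#'
#' A mark is attributed to a region iff any peak of that mark from the same
#' tissue and sample intersects the region by at least 1 bp
#' (closed-interval intersection). Matching is per tissue and sample by
#' default, mirroring how the ChIP-seq data were generated.
#'
#' @param regions data frame from [haplotype_region()] (needs `chrom`,
#'   `start`, `end`, `tissue`, `sample`).
#' @param peaks data frame from [read_peaks()].
#' @param cross_sample if TRUE, peaks from any sample of the same tissue
#'   count.
#' @return `regions` with one logical column per mark
#'   (`H3K27ac`, `H3K4me1`, `H3K4me3`, `H3K27me3`).
#' @export
overlap_marks <- function(regions, peaks, cross_sample = FALSE) {
  for (mk in MARKS) regions[[mk]] <- logical(nrow(regions))
  if (nrow(regions) == 0 || is.null(peaks) || nrow(peaks) == 0) return(regions)
  rkey <- if (cross_sample) group_key(regions$chrom, regions$tissue)
          else group_key(regions$chrom, regions$tissue, regions$sample)
  pkey <- if (cross_sample) group_key(peaks$chrom, peaks$tissue)
          else group_key(peaks$chrom, peaks$tissue, peaks$sample)
  for (k in intersect(unique(rkey), unique(pkey))) {
    ri <- which(rkey == k)
    qr <- IRanges::IRanges(start = regions$start[ri], end = regions$end[ri])
    for (mk in MARKS) {
      pi <- which(pkey == k & peaks$mark == mk)
      if (!length(pi)) next
      sr <- IRanges::IRanges(start = peaks$start[pi], end = peaks$end[pi])
      regions[[mk]][ri] <- regions[[mk]][ri] | IRanges::countOverlaps(qr, sr) > 0
    }
  }
  regions
}

#' Summarise histone-mark overlap combinations
#'
#' @param x data frame carrying the four logical mark columns (one row per
#'   locus or event, e.g. the output of [overlap_marks()]).
#' @return list with `n` (rows), `per_mark` (count and percent of rows per
#'   mark, 1 decimal), `n_any`/`pct_any` (rows in >= 1 mark), `n_multi`/
#'   `pct_multi` (rows with >= 2 marks, percent of `n_any`), and
#'   `combinations` (upset-style exclusive combination counts whose sum
#'   equals `n_any`).
#' @export
mark_combination_summary <- function(x) {
  mk <- as.matrix(x[, MARKS, drop = FALSE])
  n <- nrow(mk)
  nmk <- rowSums(mk)
  per_mark <- data.frame(
    mark = MARKS,
    count = as.integer(colSums(mk)),
    percent = if (n > 0) round_half_up(100 * colSums(mk) / n, 1) else NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  n_any <- sum(nmk >= 1)
  n_multi <- sum(nmk >= 2)
  combos <- if (n_any > 0) {
    lab <- apply(mk[nmk >= 1, , drop = FALSE], 1,
                 function(r) paste(MARKS[r], collapse = "&"))
    tab <- sort(table(lab), decreasing = TRUE)
    data.frame(combination = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(combination = character(), count = integer(),
               stringsAsFactors = FALSE)
  }
  list(
    n = n, per_mark = per_mark,
    n_any = n_any,
    pct_any = if (n > 0) round_half_up(100 * n_any / n, 1) else NA_real_,
    n_multi = n_multi,
    pct_multi = if (n_any > 0) round_half_up(100 * n_multi / n_any, 1) else NA_real_,
    combinations = combos
  )
}
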
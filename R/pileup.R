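#' Tally nucleotide calls in mpileup base columns
#'
#' Walks the samtools mpileup base-column grammar and counts the nucleotides
#' observed at each position. `.` and `,` are credited to the reference base;
#' upper/lower case calls are folded (strand-insensitive); `^` consumes the
#' following mapping-quality character; `$` is a marker; `+k`/`-k` indel runs
#' consume `k` bases without counting them; `*` is a deletion placeholder;
#' `N`/`n` are counted separately; `>`/`<` (reference skips, common at splice
#' junctions in RNA-seq) go to a `skip` counter and never into the
#' nucleotide counts.
#'
#' @param bases character vector of mpileup base columns.
#' @param ref reference base per element (recycled if length 1).
#' @param quals optional base-quality strings, required when
#'   `min_base_quality > 0`.
#' @param min_base_quality minimum phred base quality for a call to be
#'   counted; 0 (the default) disables quality filtering.
#' @param where optional label per element used in error messages
#'   (e.g. "chr1:100").
#' @return integer matrix with one row per input and columns
#'   `A, C, G, T, N, del, skip`.
#' @examples
#' tally_bases(",,..", "A")
#' tally_bases("..GgG.^].$,", "A")
#' @export
tally_bases <- function(bases, ref, quals = character(),
                        min_base_quality = 0, where = NULL) {
  n <- length(bases)
  ref <- toupper(rep_len(as.character(ref), n))
  if (is.null(where)) where <- paste0("input ", seq_len(n))
  if (min_base_quality > 0 && length(quals) != n)
    stopf("base-quality strings are required when min_base_quality > 0")
  cpp_tally(as.character(bases), ref, as.character(quals),
            as.integer(min_base_quality), as.character(where))
}

#' Parse samtools mpileup text into per-locus tallies
#'
#' Reads line-oriented mpileup text (single sample: chrom, pos, ref, depth,
#' bases, quals) and returns one tally row per line, in input order. The
#' reported depth column is reconciled against the parsed calls; on mismatch
#' a warning summarises the discrepancies and the parsed totals win. Depth
#' here is the number of base-level observations, `A+C+G+T+N+del`; reference
#' skips are kept in their own column. Zero-depth lines (`0 * *`, as emitted
#' by `samtools mpileup -a`) yield an all-zero tally.
#'
#' @param file path to an mpileup file (optionally gzipped).
#' @param text alternatively, a character vector of mpileup lines.
#' @param min_base_quality minimum phred base quality (default 0 = off).
#' @return data frame of class `locus_tally` with columns
#'   `chrom, pos, ref, A, C, G, T, N, del, skip, depth`.
#' @export
parse_mpileup <- function(file = NULL, text = NULL, min_base_quality = 0) {
  if (is.null(text)) {
    con <- open_text(file)
    text <- readLines(con)
    if (inherits(con, "connection")) close(con)
  }
  empty <- data.frame(
    chrom = character(), pos = integer(), ref = character(),
    A = integer(), C = integer(), G = integer(), T = integer(),
    N = integer(), del = integer(), skip = integer(), depth = integer(),
    stringsAsFactors = FALSE
  )
  if (length(text) == 0) {
    class(empty) <- c("locus_tally", "data.frame")
    return(empty)
  }
  fields <- strsplit(text, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6))
    stopf("mpileup line %d has %d column(s); at least 6 required",
          which(nf < 6)[1], nf[which(nf < 6)[1]])
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  refb <- toupper(vapply(fields, `[[`, "", 3L))
  depth_rep <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  bases <- vapply(fields, `[[`, "", 5L)
  quals <- vapply(fields, `[[`, "", 6L)
  if (anyNA(pos))
    stopf("non-integer position on mpileup line %d", which(is.na(pos))[1])
  if (anyNA(depth_rep))
    stopf("non-integer depth on mpileup line %d", which(is.na(depth_rep))[1])
  if (any(pos < 1))
    stopf("position < 1 on mpileup line %d", which(pos < 1)[1])

  # samtools writes "0 <tab> * <tab> *" at uncovered positions
  zero <- depth_rep == 0L & bases %in% c("*", "")
  counts <- matrix(0L, length(text), 7,
                   dimnames = list(NULL, c("A", "C", "G", "T", "N", "del", "skip")))
  if (any(!zero)) {
    counts[!zero, ] <- tally_bases(
      bases[!zero], refb[!zero], quals[!zero], min_base_quality,
      where = paste0(chrom[!zero], ":", pos[!zero],
                     " (line ", which(!zero), ")")
    )
  }
  depth <- as.integer(rowSums(counts[, c("A", "C", "G", "T", "N", "del"), drop = FALSE]))
  parsed_total <- depth + counts[, "skip"]
  if (min_base_quality == 0 && any(parsed_total != depth_rep)) {
    bad <- which(parsed_total != depth_rep)
    warnf("reported depth disagrees with parsed calls on %d line(s) (first: line %d, reported %d, parsed %d); parsed totals win",
          length(bad), bad[1], depth_rep[bad[1]], parsed_total[bad[1]])
  }
  out <- data.frame(
    chrom = chrom, pos = pos, ref = refb,
    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"], T = counts[, "T"],
    N = counts[, "N"], del = counts[, "del"], skip = counts[, "skip"],
    depth = depth, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("locus_tally", "data.frame")
  out
}

#' Write a per-locus tally table
#'
#' @param x a `locus_tally` data frame from [parse_mpileup()].
#' @param file output path (tab-delimited).
#' @export
write_tally_table <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
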
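#' Heterozygosity filter for validation loci
#'
#' A validation sample is informative at a discovery locus only if it is
#' itself heterozygous there: both discovery alleles must be supported by at
#' least `min_minor` reads (default 2, which excludes sequencing-error
#' heterozygote mimics at typical depths).
#'
#' @param count_a1,count_a2 read counts for the two discovery alleles.
#' @param min_minor minimum count per allele.
#' @return logical vector, TRUE = keep.
#' @export
heterozygosity_filter <- function(count_a1, count_a2, min_minor = 2) {
  count_a1 >= min_minor & count_a2 >= min_minor
}

#' Extract per-locus discovery alleles from ASE calls
#'
#' Builds the per-locus table the validation stage needs: for every locus of
#' every significant discovery event, the favored allele (allele 1 of the
#' validation comparison, so that direction concordance reduces to
#' aeFC > 0) and the alternate allele.
#'
#' @param results an `ase_results` data frame with `favored`.
#' @param haps the `equase_haplotypes` table the calls were made from.
#' @param significant_only restrict to significant events (default TRUE).
#' @return data frame `chrom`, `pos`, `block`, `allele_fav`, `allele_alt`.
#' @export
discovery_loci <- function(results, haps, significant_only = TRUE) {
  res <- results[!significant_only | results$significant, , drop = FALSE]
  res <- res[res$favored != "none", , drop = FALSE]
  m <- match(group_key(haps$sample, haps$tissue, haps$haplotype_block_id),
             group_key(res$sample, res$tissue, res$block))
  sel <- !is.na(m)
  fav <- res$favored[m[sel]]
  h1 <- haps$allele_h1[sel]
  h2 <- haps$allele_h2[sel]
  out <- data.frame(
    chrom = haps$chrom[sel], pos = haps$pos[sel],
    block = haps$haplotype_block_id[sel],
    allele_fav = ifelse(fav == "h1", h1, h2),
    allele_alt = ifelse(fav == "h1", h2, h1),
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Replicate discovery ASE loci in an independent cohort
#'
#' For each validation sample x discovery locus with pileup counts: apply
#' the heterozygosity filter, orient allele 1 to the discovery-favored
#' allele, compute aeFC and the exact binomial p-value, BH-adjust across
#' the whole validation cohort (single family), and call significance with
#' the discovery criteria (|aeFC| >= threshold and adjusted p <= alpha; no
#' coverage/min-expr clause beyond the heterozygosity filter).
#' `direction_match` is TRUE when the validation comparison favors the same
#' allele as discovery (aeFC > 0).
#'
#' @param val_counts data frame of validation pileup tallies with columns
#'   `sample_id`, `chrom`, `pos`, `A`, `C`, `G`, `T` (e.g. per-sample
#'   [parse_mpileup()] outputs rbound with a `sample_id` column).
#' @param discovery data frame from [discovery_loci()].
#' @param cfg a [significance_config()]; only `aefc_threshold`, `alpha` and
#'   `pseudocount` are used.
#' @param min_minor heterozygosity threshold (default 2).
#' @return data frame of class `validation_comparisons`: `sample_id`,
#'   `chrom`, `pos`, `count_a1`, `count_a2`, `aefc`, `p_raw`, `p_adj`,
#'   `significant`, `direction_match`.
#' @export
replicate_ase <- function(val_counts, discovery, cfg = significance_config(),
                          min_minor = 2) {
  m <- match(group_key(val_counts$chrom, val_counts$pos),
             group_key(discovery$chrom, discovery$pos))
  if (anyNA(m)) {
    miss <- unique(paste0(val_counts$chrom[is.na(m)], ":", val_counts$pos[is.na(m)]))
    warnf("%d validation locus/loci absent from the discovery set skipped (first: %s)",
          length(miss), miss[1])
    val_counts <- val_counts[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  cmat <- as.matrix(val_counts[, BASES, drop = FALSE])
  a1 <- cmat[cbind(seq_len(nrow(cmat)), match(discovery$allele_fav[m], BASES))]
  a2 <- cmat[cbind(seq_len(nrow(cmat)), match(discovery$allele_alt[m], BASES))]
  keep <- heterozygosity_filter(a1, a2, min_minor)
  out <- data.frame(
    sample_id = val_counts$sample_id[keep],
    chrom = val_counts$chrom[keep], pos = val_counts$pos[keep],
    count_a1 = as.integer(a1[keep]), count_a2 = as.integer(a2[keep]),
    stringsAsFactors = FALSE
  )
  out$aefc <- compute_aefc(out$count_a1, out$count_a2, cfg$pseudocount)
  out$p_raw <- if (nrow(out)) binomial_test(out$count_a1, out$count_a1 + out$count_a2) else numeric(0)
  out$p_adj <- if (nrow(out)) bh_adjust(out$p_raw) else numeric(0)
  out$significant <- abs(out$aefc) >= cfg$aefc_threshold & out$p_adj <= cfg$alpha
  out$direction_match <- out$aefc > 0
  rownames(out) <- NULL
  class(out) <- c("validation_comparisons", "data.frame")
  out
}

#' Concordance summary for a validation cohort
#'
#' Reports the fraction of comparisons confirming ASE, the fraction of
#' significant comparisons agreeing with the discovery direction, and
#' per-locus replication: loci significant in at least one sample, and loci
#' significant in >= 90% of their own surviving samples. The overall
#' significant percentage is reported at integer precision and the rest at
#' one decimal, matching the published formatting.
#'
#' @param comparisons a `validation_comparisons` data frame.
#' @return list with counts, percents and a `per_locus` data frame
#'   (`locus`, `n_samples`, `n_significant`, `replication_fraction`).
#' @export
concordance_summary <- function(comparisons) {
  n <- nrow(comparisons)
  if (n == 0) {
    return(list(n_comparisons = 0L, n_significant = NA_integer_,
                pct_significant = NA_real_, n_same_direction = NA_integer_,
                pct_same_direction = NA_real_, n_loci = 0L,
                n_loci_any = NA_integer_, pct_loci_any = NA_real_,
                n_loci_90 = NA_integer_, pct_loci_90 = NA_real_,
                per_locus = data.frame()))
  }
  n_sig <- sum(comparisons$significant)
  n_dir <- sum(comparisons$significant & comparisons$direction_match)
  locus <- paste0(comparisons$chrom, ":", comparisons$pos)
  f <- factor(locus, levels = unique(locus))
  n_samples <- as.integer(table(f))
  n_sig_locus <- as.integer(tapply(comparisons$significant, f, sum))
  frac <- n_sig_locus / n_samples
  per_locus <- data.frame(
    locus = levels(f), n_samples = n_samples, n_significant = n_sig_locus,
    replication_fraction = frac, stringsAsFactors = FALSE
  )
  list(
    n_comparisons = n,
    n_significant = n_sig,
    pct_significant = round_half_up(100 * n_sig / n, 0),
    n_same_direction = n_dir,
    pct_same_direction = if (n_sig > 0) round_half_up(100 * n_dir / n_sig, 1) else NA_real_,
    n_loci = nlevels(f),
    n_loci_any = sum(n_sig_locus >= 1),
    pct_loci_any = round_half_up(100 * sum(n_sig_locus >= 1) / nlevels(f), 1),
    n_loci_90 = sum(frac >= 0.9),
    pct_loci_90 = round_half_up(100 * sum(frac >= 0.9) / nlevels(f), 1),
    per_locus = per_locus
  )
}

#' One-way ANOVA with eta-squared effect size
#'
#' Fixed-effects one-way ANOVA by direct sums-of-squares decomposition;
#' eta-squared = SS_between / SS_total. With zero total variance the F
#' statistic is undefined (`NA`) and eta-squared is 0.
#'
#' @param values numeric response (e.g. aeFC per comparison).
#' @param groups group labels (e.g. breed), same length.
#' @return list `f_statistic`, `df_between`, `df_within`, `p_value`,
#'   `eta_squared`.
#' @export
anova_eta_squared <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values)
  values <- values[ok]
  groups <- factor(groups[ok])
  if (nlevels(groups) < 2) stopf("anova_eta_squared: need >= 2 groups")
  sizes <- table(groups)
  if (all(sizes < 2)) stopf("anova_eta_squared: need >= 1 group with >= 2 values")
  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  ss_between <- sum(as.numeric(sizes) * (gm - grand)^2)
  ss_within <- sum((values - gm[groups])^2)
  ss_total <- ss_between + ss_within
  df_b <- nlevels(groups) - 1L
  df_w <- length(values) - nlevels(groups)
  if (ss_total == 0) {
    return(list(f_statistic = NA_real_, df_between = df_b, df_within = df_w,
                p_value = NA_real_, eta_squared = 0))
  }
  f_stat <- (ss_between / df_b) / (ss_within / df_w)
  list(
    f_statistic = f_stat, df_between = df_b, df_within = df_w,
    p_value = pf(f_stat, df_b, df_w, lower.tail = FALSE),
    eta_squared = ss_between / ss_total
  )
}
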
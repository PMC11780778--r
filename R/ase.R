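#' Significance configuration for ASE calling
#'
#' Bundles the filter and significance thresholds. Defaults are the study's
#' stringent criteria: a comparison is excluded unless at least one allele
#' expression value reaches `coverage_min` (10); a surviving comparison is a
#' significant ASE event when |aeFC| >= `aefc_threshold` (2 on the log2
#' scale, i.e. 4-fold), the BH-adjusted binomial p-value is <= `alpha`
#' (0.05), and the larger allele expression value is >= `min_expr` (5).
#'
#' @param coverage_min minimum of the larger allele expression value for a
#'   comparison to enter testing.
#' @param aefc_threshold minimum |aeFC| (log2 scale) for significance.
#' @param alpha adjusted p-value cutoff.
#' @param min_expr minimum of the larger allele expression value for
#'   significance (redundant under the default `coverage_min`, kept so that
#'   user-modified thresholds behave as written).
#' @param fdr_family grouping for the BH adjustment: `"sample_tissue"`
#'   (default; one family per sample x tissue batch) or `"global"`.
#' @param pseudocount added to both allele expression values before the
#'   fold-change (default 0; zero-count sides then give infinite aeFC,
#'   which passes any finite threshold).
#' @return a list of class `significance_config`.
#' @export
significance_config <- function(coverage_min = 10, aefc_threshold = 2,
                                alpha = 0.05, min_expr = 5,
                                fdr_family = c("sample_tissue", "global"),
                                pseudocount = 0) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(coverage_min > 0, aefc_threshold > 0, min_expr > 0,
            alpha > 0, alpha < 1, pseudocount >= 0)
  structure(
    list(coverage_min = coverage_min, aefc_threshold = aefc_threshold,
         alpha = alpha, min_expr = min_expr, fdr_family = fdr_family,
         pseudocount = pseudocount),
    class = "significance_config"
  )
}

#' Coverage filter for allele expression comparisons
#'
#' Keep a comparison iff the larger of the two allele expression values
#' meets or exceeds the threshold (boundary inclusive).
#'
#' @param expr_h1,expr_h2 numeric vectors of allele expression values.
#' @param coverage_min threshold (default 10).
#' @return logical vector, TRUE = keep.
#' @export
coverage_filter <- function(expr_h1, expr_h2, coverage_min = 10) {
  pmax(expr_h1, expr_h2) >= coverage_min
}

#' Allele expression fold change
#'
#' `aeFC = log2(expr_h1) - log2(expr_h2)`. A zero on exactly one side gives
#' a signed infinity; (0, 0) gives `NA` (such comparisons are removed by the
#' coverage filter before testing).
#'
#' @param expr_h1,expr_h2 numeric vectors.
#' @param pseudocount added to both sides before the logs (default 0).
#' @return numeric vector of log2 fold changes.
#' @export
compute_aefc <- function(expr_h1, expr_h2, pseudocount = 0) {
  out <- log2(expr_h1 + pseudocount) - log2(expr_h2 + pseudocount)
  out[is.nan(out)] <- NA_real_
  out
}

#' Exact two-sided binomial test at p = 0.5
#'
#' Tests the null hypothesis that the two alleles are equally expressed.
#' The two-sided p-value uses the minimum-likelihood definition (the
#' convention of mainstream exact implementations): the sum of P(X = i)
#' over all outcomes no more likely than the observed one.
#'
#' @param k successes (reads supporting allele 1); vectorised.
#' @param n trials (total reads across both alleles); vectorised.
#' @return numeric vector of p-values in (0, 1].
#' @export
binomial_test <- function(k, n) {
  k <- as.integer(k)
  n <- as.integer(rep_len(n, length(k)))
  if (any(n < 1)) stopf("binomial_test: n must be >= 1")
  if (any(k < 0 | k > n)) stopf("binomial_test: k must be in [0, n]")
  vapply(seq_along(k), function(i) {
    d <- dbinom(0:n[i], n[i], 0.5)
    min(1, sum(d[d <= d[k[i] + 1] * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment, optionally within families
#'
#' Step-up FDR adjustment: with the p-values of a family ranked ascending,
#' `adj_(i) = min_{j >= i} (m / j) p_(j)`, capped at 1, mapped back to the
#' original order. Ties share identical adjusted values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param family optional grouping vector (one family per unique value);
#'   `NULL` treats all p-values as one family.
#' @return numeric vector of adjusted p-values, original order.
#' @export
bh_adjust <- function(p, family = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stopf("bh_adjust: p-values must be in [0, 1] and non-missing")
  adjust_one <- function(x) {
    m <- length(x)
    o <- order(x, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(m / (m:1) * x[o]))[ro]
  }
  if (is.null(family)) return(adjust_one(p))
  out <- numeric(length(p))
  for (idx in split(seq_along(p), family)) out[idx] <- adjust_one(p[idx])
  out
}

#' Call significant allele-specific expression
#'
#' Fixed pipeline order: coverage filter, aeFC, exact binomial p-value,
#' BH adjustment within the configured family, then the significance
#' criterion |aeFC| >= threshold AND adjusted p <= alpha AND
#' max(expr) >= min_expr. Infinite aeFC passes the fold-change criterion.
#'
#' @param ae allele-expression data frame from
#'   [aggregate_allele_expression()] (needs `expr_h1`, `expr_h2` and, for
#'   per-batch FDR, `sample` and `tissue`).
#' @param cfg a [significance_config()].
#' @return the surviving comparisons with columns `aefc`, `p_raw`, `p_adj`,
#'   `significant` and `favored` (`h1`, `h2` or `none`) appended; class
#'   `ase_results`. The number of comparisons dropped by the coverage
#'   filter is in `attr(, "n_filtered")`.
#' @export
call_ase <- function(ae, cfg = significance_config()) {
  stopifnot(is.data.frame(ae), inherits(cfg, "significance_config"))
  keep <- coverage_filter(ae$expr_h1, ae$expr_h2, cfg$coverage_min)
  res <- ae[keep, , drop = FALSE]
  res$aefc <- compute_aefc(res$expr_h1, res$expr_h2, cfg$pseudocount)
  res$p_raw <- if (nrow(res)) binomial_test(res$expr_h1, res$expr_h1 + res$expr_h2) else numeric(0)
  fam <- if (cfg$fdr_family == "sample_tissue") group_key(res$sample, res$tissue) else NULL
  res$p_adj <- if (nrow(res)) bh_adjust(res$p_raw, fam) else numeric(0)
  res$significant <- (abs(res$aefc) >= cfg$aefc_threshold) &
    res$p_adj <= cfg$alpha &
    pmax(res$expr_h1, res$expr_h2) >= cfg$min_expr
  res$favored <- ifelse(res$aefc > 0, "h1", ifelse(res$aefc < 0, "h2", "none"))
  rownames(res) <- NULL
  attr(res, "n_input") <- nrow(ae)
  attr(res, "n_filtered") <- sum(!keep)
  class(res) <- c("ase_results", "data.frame")
  res
}

#' Per-tissue summary of ASE calls
#'
#' @param results an `ase_results` data frame (needs `tissue` and
#'   `significant`).
#' @return data frame with `tissue`, `comparisons`, `n_significant` and
#'   `percent` (half-up, 2 decimals; `NA` for an empty tissue).
#' @export
tissue_summary <- function(results) {
  f <- factor(results$tissue)
  comparisons <- as.integer(table(f))
  n_sig <- as.integer(tapply(results$significant, f, sum, default = 0L))
  out <- data.frame(
    tissue = levels(f),
    comparisons = comparisons,
    n_significant = n_sig,
    percent = ifelse(comparisons > 0,
                     round_half_up(100 * n_sig / comparisons, 2), NA_real_),
    stringsAsFactors = FALSE
  )
  out[order(-out$percent), , drop = FALSE]
}
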
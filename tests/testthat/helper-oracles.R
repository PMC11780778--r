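# Independent oracles, deliberately written on different code paths from the
# package implementations they check.

# Regex-free character walk over the mpileup base-column grammar.
oracle_tally <- function(s, ref, chars = NULL) {
  ref <- toupper(ref)
  out <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L, del = 0L, skip = 0L)
  cs <- strsplit(s, "")[[1]]
  i <- 1L
  while (i <= length(cs)) {
    c <- cs[i]
    if (c %in% c(".", ",")) {
      out[ref] <- out[ref] + 1L
      i <- i + 1L
    } else if (toupper(c) %in% c("A", "C", "G", "T")) {
      out[toupper(c)] <- out[toupper(c)] + 1L
      i <- i + 1L
    } else if (c %in% c("N", "n")) {
      out["N"] <- out["N"] + 1L
      i <- i + 1L
    } else if (c == "*") {
      out["del"] <- out["del"] + 1L
      i <- i + 1L
    } else if (c %in% c(">", "<")) {
      out["skip"] <- out["skip"] + 1L
      i <- i + 1L
    } else if (c == "^") {
      i <- i + 2L
    } else if (c == "$") {
      i <- i + 1L
    } else if (c %in% c("+", "-")) {
      j <- i + 1L
      digits <- ""
      while (j <= length(cs) && cs[j] %in% as.character(0:9)) {
        digits <- paste0(digits, cs[j])
        j <- j + 1L
      }
      stopifnot(nchar(digits) > 0)
      i <- j + as.integer(digits)
    } else {
      stop("oracle: unknown character ", c)
    }
  }
  out
}

# Full-enumeration two-sided binomial p at p = 0.5, via log-choose (a
# different numeric path from dbinom), minimum-likelihood rule.
oracle_binom <- function(k, n) {
  logp <- lchoose(n, 0:n) - n * log(2)
  p_obs <- exp(logp[k + 1])
  min(1, sum(exp(logp)[exp(logp) <= p_obs * (1 + 1e-7)]))
}

# Naive O(m^2) BH step-up: adj_(i) = min_{j >= i} (m / j) p_(j), capped.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m / (i:m) * ps[i:m]))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# All-pairs closed-interval intersection, one mark at a time.
oracle_overlap <- function(regions, peaks) {
  hits <- matrix(FALSE, nrow(regions), length(equase_marks()))
  colnames(hits) <- equase_marks()
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(peaks))) {
      if (regions$chrom[i] == peaks$chrom[j] &&
          regions$tissue[i] == peaks$tissue[j] &&
          regions$sample[i] == peaks$sample[j] &&
          regions$start[i] <= peaks$end[j] &&
          peaks$start[j] <= regions$end[i]) {
        hits[i, peaks$mark[j]] <- TRUE
      }
    }
  }
  hits
}

equase_marks <- function() c("H3K27ac", "H3K4me1", "H3K4me3", "H3K27me3")

# Brute-force haplotype aggregation by explicit per-locus lookup.
oracle_aggregate <- function(haps, tally) {
  key <- paste(haps$sample, haps$tissue, haps$haplotype_block_id)
  do.call(rbind, lapply(unique(key), function(k) {
    sub <- haps[key == k, , drop = FALSE]
    e1 <- e2 <- other <- obs <- 0L
    for (r in seq_len(nrow(sub))) {
      hit <- which(tally$chrom == sub$chrom[r] & tally$pos == sub$pos[r])
      if (length(hit) == 0) next
      obs <- obs + 1L
      row <- tally[hit[1], c("A", "C", "G", "T")]
      e1 <- e1 + row[[sub$allele_h1[r]]]
      e2 <- e2 + row[[sub$allele_h2[r]]]
      other <- other + sum(unlist(row)) - row[[sub$allele_h1[r]]] - row[[sub$allele_h2[r]]]
    }
    data.frame(block = sub$haplotype_block_id[1], expr_h1 = e1, expr_h2 = e2,
               n_loci_observed = obs, other_count = other,
               stringsAsFactors = FALSE)
  }))
}
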
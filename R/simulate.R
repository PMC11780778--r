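#' Simulation configuration
#'
#' Describes the synthetic cohort: phased two-haplotype genes with 1-20
#' heterozygous loci, negative-binomial per-locus depth, binomial allele
#' sampling with a configurable cis-consistent imbalance, uniform base
#' miscalls, and histone peaks placed to overlap haplotype spans with
#' per-mark probabilities. Defaults emulate the discovery study's scale:
#' 1,200 genes x 4 samples x 9 tissues gives ~43,200 comparisons over
#' ~86,400 pileup rows (the study compared 42,900 events over 87,174 loci);
#' `prop_ase` defaults to 0.05 (genome-wide ASE prevalence estimates run
#' 1-20%), `effect` to an allele-1 fraction of 0.8, `error_rate` to 0.001
#' (reads are Q30-filtered upstream), and the per-mark peak overlap
#' probabilities to the study's printed per-mark percentages.
#'
#' @param seed master seed (mandatory; every stream derives from it).
#' @param n_genes number of genes (= haplotype blocks per sample x tissue).
#' @param loci_lambda mean of the truncated Poisson (min 1) for loci per gene.
#' @param loci_max cap on loci per gene.
#' @param depth_mu,depth_size negative-binomial depth mean and dispersion.
#' @param prop_ase fraction of genes with true allelic imbalance.
#' @param effect true allele-1 fraction for ASE genes (in (0.5, 1)).
#' @param error_rate per-read miscall probability (to a uniform other base).
#' @param n_samples number of samples.
#' @param tissues character vector of tissue names.
#' @param peak_overlap named per-mark probability that a gene's span gets an
#'   overlapping peak in a given tissue x sample.
#' @param intronic_frac fraction of loci annotated intronic/intergenic-only.
#' @param beta_binomial if TRUE, draw each locus's allele fraction from a
#'   Beta distribution centred on the gene's true fraction (robustness
#'   experiments only; default off, pure binomial).
#' @param beta_theta Beta concentration when `beta_binomial = TRUE`.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_genes = 1200,
                              loci_lambda = 2,
                              loci_max = 20,
                              depth_mu = 100,
                              depth_size = 2,
                              prop_ase = 0.05,
                              effect = 0.8,
                              error_rate = 0.001,
                              n_samples = 4,
                              tissues = c("lamina", "liver", "lung", "heart",
                                          "longissimus", "skin",
                                          "parietal_cortex", "testis", "ovary"),
                              peak_overlap = c(H3K27ac = 0.553, H3K4me1 = 0.394,
                                               H3K4me3 = 0.430, H3K27me3 = 0.249),
                              intronic_frac = 0.1,
                              beta_binomial = FALSE,
                              beta_theta = 200) {
  if (missing(seed)) stopf("simulation_config: seed is mandatory")
  stopifnot(prop_ase >= 0, prop_ase <= 1,
            effect > 0.5, effect < 1,
            error_rate >= 0, error_rate <= 0.05,
            n_genes >= 0, depth_mu > 0, depth_size > 0,
            loci_lambda > 0, loci_max >= 1, n_samples >= 1,
            all(names(peak_overlap) %in% MARKS))
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         loci_lambda = loci_lambda, loci_max = as.integer(loci_max),
         depth_mu = depth_mu, depth_size = depth_size,
         prop_ase = prop_ase, effect = effect, error_rate = error_rate,
         n_samples = as.integer(n_samples), tissues = tissues,
         peak_overlap = peak_overlap, intronic_frac = intronic_frac,
         beta_binomial = beta_binomial, beta_theta = beta_theta),
    class = "simulation_config"
  )
}

# One RNG stream per (sample, tissue), derived from the master seed by a
# stable polynomial string hash, so adding samples never perturbs existing
# streams. Kept below 2^31.
stream_seed <- function(master, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer(((h + master) * 69069 + 1) %% 2147483647)
}

# Observed consequence-combination frequencies in the discovery study's
# Table of variant types, used as sampling weights for functional loci.
CONSEQUENCE_WEIGHTS <- c(
  "3_prime_UTR_variant" = 335,
  "missense_variant" = 135,
  "synonymous_variant" = 134,
  "5_prime_UTR_variant" = 131,
  "non_coding_transcript_exon_variant" = 9,
  "intron_variant&splice_polypyrimidine_tract_variant&splice_region_variant" = 6,
  "splice_region_variant&synonymous_variant" = 4,
  "missense_variant&splice_region_variant" = 4,
  "intron_variant&splice_donor_region_variant" = 4,
  "stop_lost" = 4,
  "stop_gained" = 3,
  "5_prime_UTR_variant&splice_region_variant" = 2,
  "intron_variant&splice_polypyrimidine_tract_variant" = 1,
  "intron_variant&splice_region_variant" = 1,
  "missense_variant&stop_retained_variant" = 1
)

#' Simulate pileup counts at heterozygous loci
#'
#' Depth is negative-binomial; allele-1 reads are Binomial(depth, fraction);
#' each read is independently miscalled with probability `error_rate` to one
#' of the three other bases uniformly. Counts conserve depth by
#' construction. Vectorised over loci; uses the current RNG state.
#'
#' @param allele_h1,allele_h2 phased nucleotides per locus.
#' @param allele_fraction true allele-1 fraction per locus (in (0, 1)).
#' @param depth_mu,depth_size negative-binomial depth parameters.
#' @param error_rate per-read miscall probability.
#' @param depth optional fixed depth vector overriding the draw.
#' @return integer matrix with columns `A, C, G, T` plus a `depth` column.
#' @export
simulate_locus_counts <- function(allele_h1, allele_h2, allele_fraction,
                                  depth_mu = 100, depth_size = 2,
                                  error_rate = 0, depth = NULL) {
  n <- length(allele_h1)
  stopifnot(length(allele_h2) == n,
            all(allele_fraction > 0 & allele_fraction < 1))
  allele_fraction <- rep_len(allele_fraction, n)
  if (is.null(depth)) depth <- rnbinom(n, mu = depth_mu, size = depth_size)
  depth <- as.integer(rep_len(depth, n))
  k1 <- rbinom(n, depth, allele_fraction)
  k2 <- depth - k1
  counts <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
  s1 <- match(allele_h1, BASES)
  s2 <- match(allele_h2, BASES)
  e1 <- rbinom(n, k1, error_rate)
  e2 <- rbinom(n, k2, error_rate)
  counts[cbind(seq_len(n), s1)] <- k1 - e1
  counts[cbind(seq_len(n), s2)] <- counts[cbind(seq_len(n), s2)] + (k2 - e2)
  for (i in which(e1 + e2 > 0L)) {
    others1 <- setdiff(1:4, s1[i])
    others2 <- setdiff(1:4, s2[i])
    if (e1[i] > 0) {
      d <- tabulate(sample(others1, e1[i], replace = TRUE), nbins = 4)
      counts[i, ] <- counts[i, ] + d
    }
    if (e2[i] > 0) {
      d <- tabulate(sample(others2, e2[i], replace = TRUE), nbins = 4)
      counts[i, ] <- counts[i, ] + d
    }
  }
  cbind(counts, depth = depth)
}

# Render one row of counts as an mpileup base column: reference reads as
# './,' (forward/reverse), mismatches as upper/lower letters, order
# shuffled. Uses the current RNG state.
format_bases <- function(counts, ref) {
  syms <- character(0)
  for (b in BASES) {
    k <- counts[[b]]
    if (k == 0) next
    fwd <- rbinom(1, k, 0.5)
    syms <- c(syms,
              if (b == ref) c(rep(".", fwd), rep(",", k - fwd))
              else c(rep(b, fwd), rep(tolower(b), k - fwd)))
  }
  if (!length(syms)) return("*")
  paste(if (length(syms) > 1) sample(syms) else syms, collapse = "")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Simulate a full discovery cohort
#'
#' Generates gene/haplotype structure, ground-truth imbalance labels,
#' per-sample x tissue mpileup text, a merged histone-peak BED, a
#' variant-consequence table and a truth table, all in the formats the
#' pipeline reads. The gene structure and truth are drawn from the master
#' seed; counts and peaks use one derived stream per (sample, tissue), so
#' the same seed gives byte-identical outputs and adding samples never
#' perturbs existing ones. ASE genes share one true allele fraction across
#' their loci (a cis-acting haplotype effect).
#'
#' @param cfg a [simulation_config()].
#' @param out_dir output directory (created if needed); when `NULL`, tables
#'   are returned in memory only.
#' @return invisibly, a list with the in-memory tables (`haplotypes`,
#'   `truth`, `peaks`, `consequences`), per-(sample, tissue) pileup line
#'   vectors, and the paths written (if any).
#' @export
simulate_cohort <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  samples <- sprintf("S%02d", seq_len(cfg$n_samples))

  set.seed(cfg$seed)
  ng <- cfg$n_genes
  if (ng > 0) {
    n_loci <- rpois(ng, cfg$loci_lambda)
    while (any(n_loci < 1)) n_loci[n_loci < 1] <- rpois(sum(n_loci < 1), cfg$loci_lambda)
    n_loci <- pmin(n_loci, cfg$loci_max)
    chrom <- paste0("chr", sample(1:31, ng, replace = TRUE))
    gene_id <- sprintf("GENE%05d", seq_len(ng))
    # deterministic non-overlapping slots: gene i owns [i*1e5, i*1e5+5e4)
    slot <- as.integer(seq_len(ng)) * 100000L
    gi <- rep(seq_len(ng), n_loci)
    pos <- unlist(lapply(seq_len(ng), function(i)
      slot[i] + sort(sample(50000L, n_loci[i]))), use.names = FALSE)
    ab <- t(vapply(seq_along(gi), function(i) sample(BASES, 2), character(2)))
    ref <- ifelse(runif(length(gi)) < 0.5, ab[, 1], ab[, 2])
    is_ase <- runif(ng) < cfg$prop_ase
    favored <- ifelse(runif(ng) < 0.5, "h1", "h2")
    true_fraction <- ifelse(!is_ase, 0.5,
                            ifelse(favored == "h1", cfg$effect, 1 - cfg$effect))
    cons_pool <- names(CONSEQUENCE_WEIGHTS)
    cons <- ifelse(
      runif(length(gi)) < cfg$intronic_frac,
      ifelse(runif(length(gi)) < 0.5, "intron_variant", "intergenic_variant"),
      sample(cons_pool, length(gi), replace = TRUE,
             prob = CONSEQUENCE_WEIGHTS)
    )
  } else {
    n_loci <- integer(0); chrom <- character(0); gene_id <- character(0)
    gi <- integer(0); pos <- integer(0)
    ab <- matrix(character(0), 0, 2); ref <- character(0)
    is_ase <- logical(0); favored <- character(0); true_fraction <- numeric(0)
    cons <- character(0)
  }

  loci <- data.frame(
    gene = gi, chrom = chrom[gi], pos = pos,
    allele_h1 = ab[, 1], allele_h2 = ab[, 2], ref = ref,
    consequence = cons, stringsAsFactors = FALSE
  )
  ord <- order(factor(loci$chrom, levels = paste0("chr", 1:31)), loci$pos)
  loci <- loci[ord, , drop = FALSE]

  truth <- data.frame(
    gene_id = gene_id, is_ase = is_ase, true_fraction = true_fraction,
    favored = ifelse(is_ase, favored, "none"), stringsAsFactors = FALSE
  )

  # haplotype table: the same phased block for every sample x tissue
  hap_one <- data.frame(
    haplotype_block_id = gene_id[loci$gene],
    chrom = loci$chrom, pos = loci$pos,
    allele_h1 = loci$allele_h1, allele_h2 = loci$allele_h2,
    gene_id = gene_id[loci$gene], stringsAsFactors = FALSE
  )
  grid <- expand.grid(tissue = cfg$tissues, sample = samples,
                      stringsAsFactors = FALSE)
  hap_cols <- c("sample", "tissue", "haplotype_block_id", "chrom", "pos",
                "allele_h1", "allele_h2", "gene_id")
  if (nrow(hap_one) > 0) {
    haplotypes <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
      cbind(sample = grid$sample[i], tissue = grid$tissue[i], hap_one,
            stringsAsFactors = FALSE)))
    haplotypes <- haplotypes[, hap_cols]
  } else {
    haplotypes <- data.frame(sample = character(), tissue = character(),
                             haplotype_block_id = character(),
                             chrom = character(), pos = integer(),
                             allele_h1 = character(), allele_h2 = character(),
                             gene_id = character(), stringsAsFactors = FALSE)
  }

  consequences <- data.frame(
    chrom = loci$chrom, pos = loci$pos,
    gene_id = ifelse(loci$consequence == "intergenic_variant", "-",
                     gene_id[loci$gene]),
    gene_symbol = ifelse(loci$consequence == "intergenic_variant", "-",
                         gene_id[loci$gene]),
    consequence = loci$consequence, stringsAsFactors = FALSE
  )

  # per-(sample, tissue) pileups and peaks, each from its own stream
  pileups <- list()
  peak_rows <- list()
  # spans aligned to gene index 1..ng (tapply sorts names as character)
  sp_min <- tapply(loci$pos, loci$gene, min)
  sp_max <- tapply(loci$pos, loci$gene, max)
  span_start <- as.integer(sp_min[as.character(seq_len(ng))])
  span_end <- as.integer(sp_max[as.character(seq_len(ng))])
  span_chrom <- chrom
  frac_loci <- true_fraction[loci$gene]
  for (i in seq_len(nrow(grid))) {
    s <- grid$sample[i]; t <- grid$tissue[i]
    set.seed(stream_seed(cfg$seed, paste0("counts|", s, "|", t)))
    frac <- frac_loci
    if (cfg$beta_binomial && nrow(loci) > 0) {
      th <- cfg$beta_theta
      frac <- stats::rbeta(nrow(loci), frac * th, (1 - frac) * th)
      frac <- pmin(pmax(frac, 1e-6), 1 - 1e-6)
    }
    if (nrow(loci) > 0) {
      cm <- simulate_locus_counts(loci$allele_h1, loci$allele_h2, frac,
                                  cfg$depth_mu, cfg$depth_size, cfg$error_rate)
      lines <- vapply(seq_len(nrow(loci)), function(j) {
        d <- cm[j, "depth"]
        if (d == 0L)
          return(paste(loci$chrom[j], loci$pos[j], loci$ref[j], 0L, "*", "*",
                       sep = "\t"))
        bases <- format_bases(as.list(cm[j, BASES]), loci$ref[j])
        paste(loci$chrom[j], loci$pos[j], loci$ref[j], d, bases,
              strrep("I", d), sep = "\t")
      }, character(1))
    } else lines <- character(0)
    pileups[[paste0(s, "_", t)]] <- lines

    set.seed(stream_seed(cfg$seed, paste0("peaks|", s, "|", t)))
    if (ng > 0) for (mk in names(cfg$peak_overlap)) {
      hit <- runif(ng) < cfg$peak_overlap[[mk]]
      if (any(hit)) {
        st <- pmax(1L, as.integer(span_start[hit] - floor(runif(sum(hit), 0, 2000))))
        en <- as.integer(span_end[hit] + floor(runif(sum(hit), 100, 2000)))
        peak_rows[[length(peak_rows) + 1L]] <- data.frame(
          chrom = span_chrom[hit], start = st - 1L, end = en,  # BED 0-based
          mark = mk, tissue = t, sample = s, stringsAsFactors = FALSE)
      }
      # background peaks in gene deserts (slots +60k..+90k never hold loci)
      nbg <- max(1L, ng %/% 2L)
      bg_gene <- sample(ng, nbg, replace = TRUE)
      bg_start <- as.integer(bg_gene) * 100000L + 60000L +
        as.integer(floor(runif(nbg, 0, 25000)))
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        chrom = chrom[bg_gene], start = bg_start - 1L,
        end = bg_start + as.integer(floor(runif(nbg, 200, 2000))),
        mark = mk, tissue = t, sample = s, stringsAsFactors = FALSE)
    }
  }
  peaks <- if (length(peak_rows)) do.call(rbind, peak_rows)
           else data.frame(chrom = character(), start = integer(),
                           end = integer(), mark = character(),
                           tissue = character(), sample = character(),
                           stringsAsFactors = FALSE)

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "pileup"), recursive = TRUE, showWarnings = FALSE)
    paths$haplotypes <- write_tsv(haplotypes, file.path(out_dir, "haplotypes.tsv"))
    paths$truth <- write_tsv(truth, file.path(out_dir, "truth.tsv"))
    paths$consequences <- write_tsv(consequences, file.path(out_dir, "consequences.tsv"))
    pf <- file.path(out_dir, "peaks.bed")
    write.table(peaks, pf, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths$peaks <- pf
    paths$pileup_dir <- file.path(out_dir, "pileup")
    for (nm in names(pileups))
      writeLines(pileups[[nm]], file.path(out_dir, "pileup", paste0(nm, ".mpileup")))
  }
  invisible(list(haplotypes = haplotypes, truth = truth, peaks = peaks,
                 consequences = consequences, pileups = pileups,
                 paths = paths, config = cfg))
}

#' Simulate a validation cohort at discovery loci
#'
#' Writes one mpileup file per validation sample, restricted to the supplied
#' discovery loci, plus a sample sheet with group (breed) labels. Each
#' heterozygous sample expresses the discovery-favored allele at fraction
#' `effect`; a locus is homozygous in a given sample with probability
#' `prop_homozygous` (such samples are what the heterozygosity filter must
#' remove).
#'
#' @param discovery data frame from [discovery_loci()].
#' @param n_samples number of validation samples.
#' @param groups group labels recycled across samples (e.g. breeds).
#' @param effect true fraction of the discovery-favored allele.
#' @param depth_mu,depth_size negative-binomial depth parameters.
#' @param error_rate per-read miscall probability.
#' @param prop_homozygous probability a sample is homozygous at a locus.
#' @param seed master seed.
#' @param out_dir output directory; when `NULL`, in-memory only.
#' @return invisibly, list with `sample_sheet`, per-sample pileup lines and
#'   paths.
#' @export
simulate_validation <- function(discovery, n_samples = 66,
                                groups = c("QuarterHorse", "Warmblood",
                                           "Thoroughbred", "Arabian"),
                                effect = 0.8, depth_mu = 100, depth_size = 2,
                                error_rate = 0.001, prop_homozygous = 0.2,
                                seed, out_dir = NULL) {
  if (missing(seed)) stopf("simulate_validation: seed is mandatory")
  samples <- sprintf("V%03d", seq_len(n_samples))
  sheet <- data.frame(sample_id = samples,
                      group = rep_len(groups, n_samples),
                      stringsAsFactors = FALSE)
  pileups <- list()
  for (s in samples) {
    set.seed(stream_seed(seed, paste0("validation|", s)))
    nl <- nrow(discovery)
    hom <- runif(nl) < prop_homozygous
    frac <- ifelse(hom, ifelse(runif(nl) < 0.5, 1 - 1e-9, 1e-9), effect)
    frac <- pmin(pmax(frac, 1e-9), 1 - 1e-9)
    cm <- simulate_locus_counts(discovery$allele_fav, discovery$allele_alt,
                                frac, depth_mu, depth_size, error_rate)
    lines <- vapply(seq_len(nl), function(j) {
      d <- cm[j, "depth"]
      ref <- discovery$allele_fav[j]
      if (d == 0L)
        return(paste(discovery$chrom[j], discovery$pos[j], ref, 0L, "*", "*",
                     sep = "\t"))
      paste(discovery$chrom[j], discovery$pos[j], ref, d,
            format_bases(as.list(cm[j, BASES]), ref), strrep("I", d),
            sep = "\t")
    }, character(1))
    pileups[[s]] <- lines
  }
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "pileup"), recursive = TRUE, showWarnings = FALSE)
    paths$sample_sheet <- write_tsv(sheet, file.path(out_dir, "sample_sheet.tsv"))
    paths$pileup_dir <- file.path(out_dir, "pileup")
    for (s in samples)
      writeLines(pileups[[s]], file.path(out_dir, "pileup", paste0(s, ".mpileup")))
  }
  invisible(list(sample_sheet = sheet, pileups = pileups, paths = paths))
}
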
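#' Discovery pipeline configuration
#'
#' Builds the configuration list for [run_discovery()] / [run_validation()],
#' filling in the default thresholds. Any CLI flag mirrors one of these keys.
#'
#' @param ... configuration keys (see [run_discovery()]).
#' @return a plain list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(...)
  defaults <- list(coverage_min = 10, aefc = 2, alpha = 0.05, min_expr = 5,
                   fdr_family = "sample_tissue", pseudocount = 0,
                   min_minor = 2, drop_sex_chrom = TRUE)
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  cfg
}

input_record <- function(path) {
  list(path = path, md5 = unname(tools::md5sum(path)))
}

pileup_path <- function(dir, name) {
  p <- file.path(dir, paste0(name, ".mpileup"))
  if (!file.exists(p)) {
    pg <- paste0(p, ".gz")
    if (file.exists(pg)) return(pg)
  }
  p
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the discovery stage end-to-end
#'
#' Executes pileup parsing, haplotype aggregation, ASE calling and (when
#' consequence / peak inputs are given) annotation; writes the master
#' allele-expression resource, per-tissue subsets, the removed-loci sidecar
#' and a run manifest with per-stage counts. The filter chain counts in the
#' manifest are monotonically nonincreasing.
#'
#' @param config list with keys: `haplotypes` (path), `pileup_dir`
#'   (directory of `<sample>_<tissue>.mpileup` files), `out` (output
#'   directory), optional `peaks` and `consequences` paths, and thresholds
#'   (`coverage_min`, `aefc`, `alpha`, `min_expr`, `fdr_family`,
#'   `pseudocount`, `drop_sex_chrom`); see [pipeline_config()].
#' @return invisibly, list with `results`, `allele_expression`, `summary`
#'   (per tissue), `manifest` and output `paths`.
#' @export
run_discovery <- function(config) {
  config <- do.call(pipeline_config, config)
  for (k in c("haplotypes", "pileup_dir", "out"))
    if (is.null(config[[k]]))
      stopf("configuration error: '%s' is required", k)
  if (!file.exists(config$haplotypes))
    stopf("configuration error: haplotype table '%s' not found", config$haplotypes)
  if (!dir.exists(config$pileup_dir))
    stopf("configuration error: pileup directory '%s' not found", config$pileup_dir)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  haps <- read_haplotype_table(config$haplotypes,
                               drop_sex_chrom = config$drop_sex_chrom)
  loci_read <- nrow(haps)
  tick("read_haplotypes")

  units <- unique(haps[, c("sample", "tissue")])
  inputs <- list(haplotypes = input_record(config$haplotypes))
  ae <- do.call(rbind, lapply(seq_len(nrow(units)), function(i) {
    s <- units$sample[i]; t <- units$tissue[i]
    p <- pileup_path(config$pileup_dir, paste0(s, "_", t))
    if (!file.exists(p))
      stopf("configuration error: pileup for sample '%s' tissue '%s' not found (%s)",
            s, t, p)
    tal <- parse_mpileup(p)
    sub <- haps[haps$sample == s & haps$tissue == t, , drop = FALSE]
    aggregate_allele_expression(sub, tal)
  }))
  if (is.null(ae)) ae <- aggregate_allele_expression(haps, parse_mpileup(text = character()))
  message(sprintf("[discovery] %d loci -> %d comparisons", loci_read, nrow(ae)))
  tick("aggregate")

  scfg <- significance_config(config$coverage_min, config$aefc, config$alpha,
                              config$min_expr, config$fdr_family,
                              config$pseudocount)
  results <- call_ase(ae, scfg)
  message(sprintf("[discovery] %d comparisons survive coverage filter, %d significant",
                  nrow(results), sum(results$significant)))
  tick("call_ase")

  removed <- data.frame()
  if (!is.null(config$consequences)) {
    cons <- read_consequence_table(config$consequences)
    inputs$consequences <- input_record(config$consequences)
    fc <- filter_consequences(cons)
    removed <- fc$removed
    m <- match(group_key(haps$chrom, haps$pos),
               group_key(cons$chrom, cons$pos))
    haps$consequence <- cons$consequence[m]
    haps$locus_kept <- !is.na(m) &
      group_key(haps$chrom, haps$pos) %in% group_key(fc$kept$chrom, fc$kept$pos)
    bk <- group_key(haps$sample, haps$tissue, haps$haplotype_block_id)
    kept_by_block <- tapply(haps$locus_kept, bk, any)
    gene_by_block <- tapply(cons$gene_id[m], bk, function(x) {
      x <- x[!is.na(x) & x != "-"]
      if (length(x)) x[1] else NA_character_
    })
    rk <- group_key(results$sample, results$tissue, results$block)
    results$gene_id <- as.character(gene_by_block[rk])
    results$consequence_kept <- as.logical(kept_by_block[rk])
  }
  if (!is.null(config$peaks)) {
    peaks <- read_peaks(config$peaks)
    inputs$peaks <- input_record(config$peaks)
    regions <- haplotype_region(haps)
    regions <- overlap_marks(regions, peaks)
    m <- match(group_key(results$sample, results$tissue, results$block),
               group_key(regions$sample, regions$tissue, regions$block))
    for (mk in MARKS) results[[mk]] <- regions[[mk]][m]
  }
  tick("annotate")

  summary <- tissue_summary(results)
  paths <- list(resource = file.path(config$out, "resource.tsv"),
                manifest = file.path(config$out, "manifest.json"))
  write_tsv(as.data.frame(results), paths$resource)
  for (t in unique(results$tissue)) {
    p <- file.path(config$out, paste0("resource_", t, ".tsv"))
    write_tsv(as.data.frame(results[results$tissue == t, , drop = FALSE]), p)
    paths[[paste0("resource_", t)]] <- p
  }
  if (nrow(removed)) {
    paths$removed_loci <- write_tsv(removed, file.path(config$out, "removed_loci.tsv"))
  }
  paths$summary <- write_tsv(summary, file.path(config$out, "tissue_summary.tsv"))
  tick("write")

  manifest <- list(
    tool = "equase", version = as.character(utils::packageVersion("equase")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stage = "discovery",
    config = config[c("coverage_min", "aefc", "alpha", "min_expr",
                      "fdr_family", "pseudocount", "drop_sex_chrom")],
    inputs = inputs,
    counts = list(
      loci_read = loci_read,
      comparisons_formed = attr(results, "n_input"),
      comparisons_surviving = nrow(results),
      significant_calls = sum(results$significant)
    ),
    timings = timings
  )
  write_manifest(manifest, paths$manifest)
  invisible(list(results = results, allele_expression = ae, summary = summary,
                 manifest = manifest, paths = paths))
}

#' Run the validation stage
#'
#' Replicates the discovery ASE loci in an independent cohort: reads the
#' discovery resource and haplotype table to orient alleles, parses one
#' mpileup per validation sample, applies the heterozygosity filter,
#' re-tests at the validation criteria, and writes the comparison table,
#' the concordance summary (tab-delimited + a one-page text version) and a
#' manifest. When at least two groups are present, a one-way ANOVA of aeFC
#' on group with eta-squared is included.
#'
#' @param config list with keys `resource` (discovery resource path),
#'   `haplotypes`, `sample_sheet` (TSV: `sample_id`, `group`),
#'   `pileup_dir` (directory of `<sample_id>.mpileup`), `out`, plus
#'   thresholds `aefc`, `alpha`, `min_minor`.
#' @return invisibly, list with `comparisons`, `concordance`, `anova`,
#'   `manifest`, `paths`.
#' @export
run_validation <- function(config) {
  config <- do.call(pipeline_config, config)
  for (k in c("resource", "haplotypes", "sample_sheet", "pileup_dir", "out"))
    if (is.null(config[[k]]) || !file.exists(config[[k]]) && k != "out")
      stopf("configuration error: '%s' missing or not found", k)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)

  resource <- read.delim(config$resource, stringsAsFactors = FALSE)
  if (!"favored" %in% names(resource))
    stopf("configuration error: discovery resource lacks the 'favored' column")
  class(resource) <- c("ase_results", "data.frame")
  haps <- read_haplotype_table(config$haplotypes,
                               drop_sex_chrom = config$drop_sex_chrom)
  disc <- discovery_loci(resource, haps)
  sheet <- read.delim(config$sample_sheet, stringsAsFactors = FALSE)
  paths <- list(comparisons = file.path(config$out, "validation_comparisons.tsv"),
                concordance = file.path(config$out, "concordance.tsv"),
                summary_txt = file.path(config$out, "concordance.txt"),
                manifest = file.path(config$out, "manifest.json"))
  if (nrow(sheet) == 0) {
    warnf("empty validation sample sheet; writing empty outputs")
    empty <- replicate_ase(
      data.frame(sample_id = character(), chrom = character(), pos = integer(),
                 A = integer(), C = integer(), G = integer(), T = integer()),
      disc)
    write_tsv(as.data.frame(empty), paths$comparisons)
    writeLines("no validation samples", paths$summary_txt)
    return(invisible(list(comparisons = empty,
                          concordance = concordance_summary(empty),
                          anova = NULL, paths = paths)))
  }

  val_counts <- do.call(rbind, lapply(seq_len(nrow(sheet)), function(i) {
    s <- sheet$sample_id[i]
    p <- pileup_path(config$pileup_dir, s)
    if (!file.exists(p))
      stopf("configuration error: pileup for validation sample '%s' not found (%s)", s, p)
    tal <- parse_mpileup(p)
    cbind(sample_id = s, as.data.frame(tal), stringsAsFactors = FALSE)
  }))
  scfg <- significance_config(config$coverage_min, config$aefc, config$alpha,
                              config$min_expr, "global", config$pseudocount)
  comparisons <- replicate_ase(val_counts, disc, scfg,
                               min_minor = config$min_minor)
  comparisons$group <- sheet$group[match(comparisons$sample_id, sheet$sample_id)]
  conc <- concordance_summary(comparisons)
  anv <- NULL
  if (length(unique(comparisons$group)) >= 2) {
    anv <- anova_eta_squared(comparisons$aefc, comparisons$group)
  }

  write_tsv(as.data.frame(comparisons), paths$comparisons)
  conc_df <- data.frame(
    metric = c("comparisons", "significant", "pct_significant",
               "same_direction", "pct_same_direction", "loci",
               "loci_replicated_any", "pct_loci_any",
               "loci_replicated_90pct", "pct_loci_90"),
    value = c(conc$n_comparisons, conc$n_significant, conc$pct_significant,
              conc$n_same_direction, conc$pct_same_direction, conc$n_loci,
              conc$n_loci_any, conc$pct_loci_any, conc$n_loci_90,
              conc$pct_loci_90)
  )
  write_tsv(conc_df, paths$concordance)
  txt <- c(
    sprintf("validation comparisons: %d over %d loci x %d samples",
            conc$n_comparisons, conc$n_loci, length(unique(comparisons$sample_id))),
    sprintf("significant (|aeFC| >= %g, p_adj <= %g): %d (%g%%)",
            config$aefc, config$alpha, conc$n_significant, conc$pct_significant),
    sprintf("same direction as discovery: %d (%g%% of significant)",
            conc$n_same_direction, conc$pct_same_direction),
    sprintf("loci replicated in >= 1 sample: %d (%g%%)",
            conc$n_loci_any, conc$pct_loci_any),
    sprintf("loci replicated in >= 90%% of samples: %d (%g%%)",
            conc$n_loci_90, conc$pct_loci_90),
    if (!is.null(anv))
      sprintf("group ANOVA: F(%d, %d) = %.2f, p = %.3g, eta-squared = %.4f",
              anv$df_between, anv$df_within, anv$f_statistic, anv$p_value,
              anv$eta_squared)
  )
  writeLines(txt, paths$summary_txt)
  manifest <- list(
    tool = "equase", version = as.character(utils::packageVersion("equase")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stage = "validation",
    config = config[c("aefc", "alpha", "min_minor")],
    inputs = list(resource = input_record(config$resource),
                  sample_sheet = input_record(config$sample_sheet)),
    counts = list(
      discovery_loci = nrow(disc),
      comparisons = conc$n_comparisons,
      significant = conc$n_significant
    )
  )
  write_manifest(manifest, paths$manifest)
  invisible(list(comparisons = comparisons, concordance = conc, anova = anv,
                 manifest = manifest, paths = paths))
}
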
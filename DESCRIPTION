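Package: equase
Title: Haplotype-Resolved Allele-Specific Expression Calling for Equine
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("FAANG", "Analyst", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls allele-specific expression (ASE) from phased heterozygous
    loci and short-read pileup counts. Parses samtools mpileup base columns,
    sums per-locus nucleotide counts into haplotype-level allele expression,
    tests allelic imbalance with an exact binomial test and Benjamini-Hochberg
    false-discovery-rate control under an allele-expression fold-change
    (aeFC) criterion, annotates events with variant consequences and histone
    modification peak overlap, and replicates calls in an independent cohort
    with direction-concordance statistics and one-way ANOVA effect sizes.
    Includes a synthetic cohort generator that emits ground-truth-labelled
    inputs in all the formats the pipeline reads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
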
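---
title: "Calling allele-specific expression from phased haplotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling allele-specific expression from phased haplotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

In a diploid cell the two alleles of an autosomal gene are usually expressed
at similar levels; cis-acting regulatory variation can bias expression toward
one haplotype. `equase` detects such allele-specific expression (ASE) from
two inputs that modern equine (and other livestock) functional-annotation
projects produce routinely: phased heterozygous loci derived from full-length
long-read transcripts, and short-read RNA-seq pileups at those loci.

For one gene in one sample and tissue, let the haplotype block carry loci
$1, \dots, L$ with phased nucleotides $(a_\ell^{(1)}, a_\ell^{(2)})$, and let
$c_\ell(b)$ be the short-read count of nucleotide $b$ at locus $\ell$. The
allele expression values are the haplotype-wise sums

$$E_1 = \sum_\ell c_\ell(a_\ell^{(1)}), \qquad
  E_2 = \sum_\ell c_\ell(a_\ell^{(2)}),$$

and the imbalance statistic is the allele expression fold change

$$\mathrm{aeFC} = \log_2 E_1 - \log_2 E_2 .$$

Under the null hypothesis of balanced expression, $E_1$ given $E_1 + E_2$ is
Binomial$(E_1+E_2,\ 1/2)$. The package computes the exact two-sided p-value
under the minimum-likelihood convention (sum of the probabilities of all
outcomes no more likely than the observed one — the convention of mainstream
exact-test implementations; the direction of deviation is not privileged),
then applies Benjamini–Hochberg step-up FDR adjustment.

A comparison enters testing only if $\max(E_1, E_2) \ge 10$ (the coverage
filter, boundary inclusive), and is called a significant ASE event when all
three criteria hold:

* $|\mathrm{aeFC}| \ge 2$ (i.e. at least 4-fold imbalance; an infinite
  aeFC from a zero side passes, since the coverage filter guarantees the
  other side is well supported),
* BH-adjusted $p \le 0.05$,
* $\max(E_1, E_2) \ge 5$.

The third criterion is redundant under the default coverage filter; it is
implemented exactly as stated so that user-modified thresholds behave
predictably.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `coverage_min` | 10 reads | minimum of the larger allele expression value to test a comparison |
| `aefc_threshold` | 2 (log2 units) | minimum absolute fold change for significance |
| `alpha` | 0.05 | adjusted p-value cutoff |
| `min_expr` | 5 reads | minimum of the larger allele expression value for significance |
| `fdr_family` | sample × tissue | BH family; comparisons are compiled per sample/tissue batch, so the adjustment is applied within each batch by default (`"global"` available) |
| `pseudocount` | 0 | optional stabiliser added to both sides of the fold change |
| `min_minor` (validation) | 2 reads | per-allele count required to treat a validation sample as heterozygous at a discovery locus |

Design choices where the method description was genuinely open:

* **Sidedness of the binomial test.** Two-sided: the null is equality and
  deviation in either direction is of interest.
* **Allele-1 orientation.** In discovery, allele 1 is haplotype 1 as phased
  (phase order, not reference or expression rank). In validation, allele 1
  is re-oriented to the discovery-favored allele, so direction concordance
  reduces to $\mathrm{aeFC} > 0$.
* **Third-allele reads.** Pileup calls matching neither phased nucleotide
  are excluded from allele evidence and retained per block as an
  `other_count` QC column.
* **Reference skips and indels** in the pileup (`>`/`<`, `+k`/`-k`, `*`)
  are never counted as allele calls; RNA-seq pileups routinely contain
  skips at splice junctions. Zero-depth placeholder lines are accepted.
* **Depth reconciliation.** When the mpileup depth column disagrees with
  the parsed calls, the parsed total wins (with a warning), making results
  independent of the upstream tool version.
* **Sex chromosomes** are excluded by default (autosomal focus), with a
  flag to retain them.
* **Consequence filtering.** A locus is dropped only when *every* term
  attached to it is `intron_variant` or `intergenic_variant`; compound
  annotations with any functional component (splice region, UTR, coding)
  are kept. Unknown terms warn and count as functional.
* **Histone marks** are attributed through the haplotype span (first to
  last heterozygous position, closed coordinates; BED input is converted
  from 0-based half-open on read) against peaks of the *same tissue and
  sample*; every significant locus in a region inherits the region's mark
  set.
* **Validation BH family** is the whole validation cohort (one family);
  validation significance uses $|\mathrm{aeFC}| \ge 2$ and adjusted
  $p \le 0.05$ only — direction disagreement is reported separately as
  concordance, not folded into significance.

## The synthetic cohort generator

`simulate_cohort()` emits the statistical structure the pipeline assumes, in
exactly the formats it reads, with ground-truth labels. The stated world of
its defaults: 1,200 genes × 4 samples × 9 tissues (≈43,200 comparisons over
≈86,400 pileup rows, the scale of the motivating study's 42,900 comparisons
and 87,174 loci); truncated-Poisson loci per gene (λ = 2, min 1, max 20);
negative-binomial depth (μ = 100, size = 2 — overdispersion lives in depth,
not in the allele fraction, matching the binomial test's assumption; a
beta-binomial option exists for robustness experiments); `prop_ase` = 0.05
(published genome-wide estimates of genes with detectable ASE span roughly
1–20% depending on filtering stringency); a cis-consistent allele-1
fraction of 0.8 shared by all loci of an ASE gene; per-read miscall rate
0.001 (reads are quality-filtered at Q30 upstream); and per-mark peak
placement probabilities equal to the study's printed per-mark overlap
percentages. One RNG stream per (sample, tissue) is derived from the master
seed by a stable string hash, so outputs are byte-reproducible and adding
samples never perturbs existing ones.

What the generator deliberately does **not** emulate: alignment and mapping
artefacts (reference bias, mismapping near indels), splicing structure,
correlated errors within reads, linkage between neighbouring genes, and
imprinting. A green recovery test therefore establishes that the caller is
correct *for its own model* — counts that really are (negative-binomially
thinned) binomial draws — not that it is robust to every artefact of real
sequencing data.

## Numerical choices

* Two-sided p-values use a relative tolerance of $10^{-7}$ when comparing
  outcome likelihoods, mirroring standard exact-test implementations; for
  $p = 1/2$ the nearest distinct binomial coefficients differ by far more,
  so the outcome set is unambiguous.
* BH adjustment is the $O(m \log m)$ cummin formulation; it is exactly
  (bitwise) equal to the naive $\min_{j \ge i} (m/j) p_{(j)}$ step-up,
  ties included.
* Summary percentages are rounded half *up* (away from zero), matching the
  conventions of the published tables: 2 decimals for tissue and
  variant-type tables, 1 decimal for histone and per-locus validation
  percentages, integer precision for the overall validation replication
  rate.
* Degenerate inputs: $(0,0)$ expression pairs yield an `NA` fold change
  and are removed by the coverage filter; empty tissues yield `NA`
  percentages; an all-constant ANOVA response reports `NA` F and zero
  eta-squared.

## A known power boundary

The significance criterion $|\mathrm{aeFC}| \ge 2$ sits exactly at the true
effect size of a 0.8/0.2 allele split ($\log_2(0.8/0.2) = 2$). For a gene
whose true fraction is exactly 0.8, the sampling distribution of the
estimated aeFC straddles the threshold, so detection power converges to
~50% as depth grows — more sequencing sharpens the estimate around the
boundary rather than pushing it across. The package's parameter-recovery
acceptance check at effect 0.8 measures this (~0.51 pooled sensitivity, with
empirical FDR well controlled) and is reported honestly as failing a ≥0.9
sensitivity bar; effects clearly above threshold (e.g. fraction 0.9,
$\mathrm{aeFC} \approx 3.17$) are recovered at ≥95% sensitivity in the unit
suite. Practically: events whose true imbalance is near 4-fold are
under-ascertained by this criterion, a conservatism inherited from the
method being reproduced.

## Limitations

* Only biallelic, two-haplotype blocks are modelled; loci with a third
  segregating allele contribute QC counts but no allele evidence.
* The binomial model ignores biological overdispersion across loci of a
  block; a beta-binomial test is a possible extension (the generator can
  already produce overdispersed fractions for benchmarking it).
* Homozygous loci can still show regulatory imbalance (e.g. imprinting
  without a transcribed marker); the method is blind to them by design.
* ANOVA on validation fold changes treats comparisons as independent,
  ignoring repeated measures per locus — adequate for effect-size
  screening (eta-squared), not for confirmatory inference.
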
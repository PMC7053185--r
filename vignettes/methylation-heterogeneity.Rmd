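---
title: "Quantifying DNA methylation heterogeneity from bisulfite reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA methylation heterogeneity from bisulfite reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylhet)
library(dplyr)
```

## The measurement problem

Whole-genome bisulfite sequencing reports, for every sequenced DNA
fragment, the methylation state of each CpG the fragment covers:
unmethylated cytosines read as T, methylated cytosines as C. Averaging
these calls per CpG gives the familiar beta value, but discards the
molecule-level structure: two samples with identical 50% average
methylation may consist of a clean half-and-half mixture of fully
methylated and fully unmethylated molecules, or of molecules that are
each internally disordered. In tumours this distinction matters — locally
disordered methylation reflects epigenetic instability of the underlying
cell population and has repeatedly been associated with clinical
behaviour.

`methylhet` works at three scales:

1. **Read level.** Each fragment is reduced to an *epiread*: its ordered
   CpG states over `{M, U, missing}` indexed against the reference CpG
   frame.
2. **Locus level.** Consecutive quartets of CpGs define epiallele loci; a
   read contributes a length-4 pattern when it covers all four CpGs with
   informative states. The pattern frequency distribution at a locus is
   scored by epipolymorphism (Gini–Simpson), epiallele entropy (Shannon,
   bits), and per-CpG PDR.
3. **Sample level.** Unweighted means over eligible loci/CpGs, global
   methylation, and the coefficient of variation of 5-kb tile methylation,
   feeding the group contrasts and survival analyses.

## Definitions and filters

For pattern counts $n_1,\dots,n_{16}$ with total $N$ and frequencies
$p_i = n_i/N$:

$$\mathrm{epipolymorphism} = 1 - \sum_i p_i^2, \qquad
  H = -\sum_{p_i > 0} p_i \log_2 p_i .$$

Epipolymorphism ranges over $[0, 0.9375]$, entropy over $[0, 4]$ bits. The
entropy is reported both raw and divided by 4; published entropy summaries
in this field are often on an unstated scale, so both variants are always
emitted and the normalised one is the default in plots.

A read is *PDR-eligible* when it carries at least 4 informative CpG states;
it is *discordant* when those states include both `M` and `U`. Per CpG,

$$\mathrm{PDR} = \frac{\#\{\text{discordant eligible reads covering the CpG}\}}
                      {\#\{\text{eligible reads covering the CpG}\}},$$

defined only where the denominator **exceeds ten** (`min_reads_per_cpg =
11`). The same strictly-more-than-ten convention governs tile eligibility
(mean per-CpG depth in the tile must exceed `depth_threshold = 10`) and is
deliberately strict: a CpG seen by exactly ten eligible reads has no PDR,
a tile at mean depth exactly 10 has no methylation value. Epiallele loci
require `min_reads = 10` pattern-complete reads (loci at exactly 10 are
kept; the filter drops loci *below* the threshold). Undefined values
propagate as `NA`, never as 0.

Two sample-level PDR conventions exist in the literature: averaging
per-CpG PDR over defined CpGs, and pooling reads into a single
discordant/eligible ratio. Both are implemented (`sample_pdr(mode =
"per_cpg")` is the default, following the per-region averaging of the PDR
literature); on whole-locus simulated reads they coincide.

## Locus windowing

`enumerate_loci()` walks each contig's CpG index in quartets. The default
step of 4 gives non-overlapping loci, so no read is counted twice across
loci and locus metrics are independent given the generating distributions;
`step = 1` provides the sliding-window variant used by epiallele-shift
tools. Contigs with fewer than four CpGs yield no loci.

## The synthetic generator

Real WGBS read sets at cohort scale are terabytes; every stage of this
package is instead exercised against a generator whose ground truth is
known exactly.

**Reference.** A contig is built from an A/T background with `CG`
dinucleotides placed at sampled positions — four per locus, intra-locus
spacing jittered around `cpg_spacing` (default 20 bp, a dense CpG
neighbourhood typical of the regions where 4-CpG windows are found),
`locus_spacing` (150 bp) between loci. Because the background contains no
C or G, CpGs exist exactly where placed.

**Epiallele structure.** Each locus draws a clonal mixture: the first
clone is the *ancestral concordant epiallele* (`MMMM` or `UUUU`,
equiprobable) and `clonality − 1` further clone patterns are drawn
uniformly from the remaining 15. Mixing proportions are Dirichlet with an
asymmetric concentration: the ancestral clone at `ancestral_alpha = 5`,
each subclone at `clone_mix_alpha = 0.3`. Two deliberate choices sit here:

- *Ancestral concordance.* If clone patterns were drawn uniformly, a fully
  clonal locus could be a pure discordant pattern such as `MUUU` — zero
  entropy but PDR 1 — and the three metrics would decouple by
  construction. Anchoring each locus to a concordant ancestral state makes
  disorder enter only through subclones, so entropy, epipolymorphism and
  PDR rise together, which is how they behave in tumour data.
- *Asymmetric Dirichlet.* Under a symmetric Dirichlet the expected clone
  weights are $1/k$ regardless of concentration, so no concentration shift
  could move the expected discordant-read mass. Giving the ancestral clone
  a fixed, larger concentration makes the expected subclonal mass
  $\frac{(k-1)\alpha}{\alpha_0 + (k-1)\alpha}$, monotone in both clone
  number and `clone_mix_alpha` — a single dial that raises all three
  metrics jointly. The default `clone_mix_alpha = 0.3` keeps subclones
  minor populations (near-clonal loci), which is the realistic baseline
  for bulk tumour tissue.

**Observation model.** Read counts per locus are negative binomial with
mean `coverage_mean = 25` (matching the mid-20s median coverage of a
typical WGBS tumour cohort) and dispersion 5; Poisson and fixed-coverage
modes exist, the latter for checking sampling-theory identities at a known
depth $n$, e.g. the multinomial plug-in bias
$E[\widehat{\mathrm{epi}}] = (1 - 1/n)\,\mathrm{epi}$. Each read's pattern
is drawn from the locus distribution, then every CpG state flips
independently with `error_rate = 0.01` — a lumped bisulfite-conversion
failure plus sequencing-error channel. `expected_metrics()` propagates any
distribution through this channel exactly (the $16 \times 16$ transition
matrix has entries $e^h(1-e)^{4-h}$ for Hamming distance $h$) and returns
population values of all three metrics, the oracle against which plug-in
estimates are tested. By default reads observe whole loci; a
`partial_frac` mode truncates a uniform prefix/suffix of states to
exercise missing-data handling.

**Cohorts and survival.** `simulate_cohort()` draws two groups; group B
adds `group_effect = 1` to `clone_mix_alpha`, the high-heterogeneity
condition emulating a metastasis-positive contrast. Survival times are
exponential with hazard
$\lambda_0 \exp(\beta \cdot \bar{\mathrm{epi}})$ —
baseline `0.075` per month, chosen so that median survival at the
low-heterogeneity baseline sits near nine months as in aggressive
oesophageal disease, with `censoring_rate = 0.02` for independent
censoring. The exponential/log-linear form is the simplest model with a
controllable effect size for log-rank power studies.

**What the generator does not emulate:** PCR duplicates, mappability and
base-quality structure, strand-specific conversion artefacts, copy-number
driven coverage waves, CpG-density heterogeneity of real genomes, and any
correlation between neighbouring loci. Passing tests therefore validate
the *estimators and their sampling theory*, not robustness to alignment
artefacts — the extraction layer is validated separately against
hand-decoded alignments.

## Alignment decoding conventions

Extraction lays each read's sequence into reference space via its CIGAR.
Forward-flag reads are read at the C of each CpG (C→`M`, T→`U`, anything
else missing); reverse-flag reads follow the bottom-strand convention at
the G (G→`M`, A→`U`), and both strands' evidence collapses onto the
forward-strand C position, the standard symmetric-CpG treatment. Mates
sharing a query name merge into one fragment-level epiread; where both
cover a CpG the first mate in file order wins, avoiding double counting
with a deterministic rule. Base qualities are ignored by default — calls
stay minimal and reproducible; no SNP-aware filtering is attempted, so
C-to-T polymorphisms will read as unmethylated (unmodelled, as in any
genotype-blind extractor). Coordinates are 1-based at the CpG C
internally, matching Bioconductor convention; all interval tables and
written BED/bedGraph use 0-based half-open intervals.

## Clinical-association choices

Stratification splits at the cohort median, ties to the low stratum — the
cut rule is rarely stated in clinical methylation studies; the median is
the least-informative defensible default, and the tie policy is explicit
and configurable. The Kaplan–Meier estimator counts subjects censored at
an event time as still at risk at that time (the standard convention), and
the log-rank test uses the hypergeometric variance with the usual
$(N-d)/(N-1)$ correction, skipping risk sets of size one. Group contrasts
use the Mann–Whitney U test — exact when both groups are ≤ 8 and tie-free,
otherwise the tie-corrected normal approximation — and region-wise
comparisons adjust across regions with Benjamini–Hochberg. Locus-to-region
assignment for the copy-number contrast uses midpoint overlap against
half-open intervals (a locus midpoint exactly at a region start is
inside); full-containment mode is available.

## Numerical and degenerate-input conventions

- Entropy terms with $p_i = 0$ are dropped (the $0 \log 0 = 0$ limit).
- Zero-read loci, uncovered CpGs, CpG-free tiles, all-ineligible tile
  sets, and event-free log-rank inputs all yield flagged `NA`s, never
  silent zeros; constant metrics make stratification an error rather than
  an arbitrary split.
- Probability vectors must sum to 1 within 1e-9; the oracle-equivalence
  tests hold plug-in metrics to brute-force summation within 1e-12.
- Determinism: one master seed; per-sample child seeds derive from it by a
  fixed integer recurrence, so cohorts are reproducible read-for-read and
  the pipeline manifest checksums are stable across reruns.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run the generator at sizes
chosen to make Monte-Carlo error small relative to the tested effect while
staying desk-scale: 2,000 loci at fixed coverage 50 for the plug-in bias
law (tolerance 0.005), cohorts of 2 × 20 samples × 200 loci for the group
contrast, 200 null and 100 alternative replicates at n = 50–100 per arm
for log-rank size and power, 320 loci (20 per clonality level 1–16) at
coverage 200 for cross-metric rank agreement, and a 1,000-locus × 30-sample
end-to-end run. Published cohort-level values from terabyte-scale WGBS
(global methylation percentages, cohort CV ranges, counted DMRs) are not
recomputable from synthetic data; of those only closed arithmetic — the
DMR direction bookkeeping — is asserted exactly.

## Limitations

Beyond the generator's simplifications listed above: the epiallele-shift
(between-sample) statistic of methclone-style analyses, de novo DMR
segmentation, tumour-purity correction, Cox regression and annotation
enrichment are intentionally out of scope; region lists, CNA segments and
gene models are consumed as BED input. PDR's sample-level value depends on
the eligibility filters; comparisons across studies should fix
`min_cpgs_per_read` and `min_reads_per_cpg` explicitly.
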
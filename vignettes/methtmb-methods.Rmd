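---
title: "Methods: linking tumor mutation burden to methylome aberrance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking tumor mutation burden to methylome aberrance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methTMB)
```

# The analysis

methTMB implements an integrated tumor-genomics analysis for paired
tumor/normal NSCLC-style cohorts profiled by whole-exome sequencing and an
EPIC-style methylation array. The question it addresses is whether tumors
that carry more somatic mutations also carry more DNA-methylation
aberrance, and the pipeline quantifies that association stage by stage:

1. **TMB stage.** Somatic calls are filtered to high-confidence variants
   (read depth ≥ 10, allele fraction ≥ 5%, ≥ 3 supporting reads; all
   bounds inclusive). TMB is computed both ways: the raw count of
   nonsynonymous coding mutations per tumor (NOM; SNVs and short indels
   both count) and NOM divided by the size of the annotated coding region
   in megabases (33.4 Mb for UCSC Refseq annotations; the region size is a
   required parameter, since the capture kit footprint — 36 Mb here — and
   the annotation footprint legitimately differ). Samples are stratified
   into TMB tertiles by sorting NOMs in decreasing order and splitting
   into three contiguous groups; with $n = 3q + r$ the $r$ leftover
   samples go to the outer groups, high first, then low. That remainder
   rule is a genuine design choice — it is the unique rule that splits a
   cohort of 89 into high 30 / medium 29 / low 30 — and ties break by
   sample identifier so the stratification is a deterministic function of
   the input.

2. **Signature stage.** Somatic SNVs (synonymous included; indels are
   excluded here because the 96 substitution classes are SNV-only) are
   tabulated over the 96 pyrimidine-normalized trinucleotide contexts,
   ordered substitution-major (`C>A`, `C>G`, `C>T`, `T>A`, `T>C`, `T>G`)
   with flanks alphabetical. Purine-reference calls are folded onto the
   pyrimidine strand by reverse complementing reference, alternate and
   flanks, so the spectrum is invariant to reporting strand. Spectra can
   be renormalized from one region's trinucleotide composition to
   another's (each entry scaled by target/observed context frequency, then
   renormalized); the direction is the caller's choice by passing the two
   censuses, with exome-to-genome as the intended default. Exposures are
   refit by nonnegative least squares,
   $\min_{w \ge 0} \lVert f - S w \rVert_2$, where $f$ is the spectrum's
   frequency view and $S$ the signature catalogue. Weights below 0.06 are
   zeroed and the survivors rescaled to the pre-pruning explained fraction
   (capped at one), the established refitting convention; unconstrained
   regression is deliberately avoided because negative weights contradict
   the interpretation of an exposure as a per-sample signature
   contribution. The unexplained fraction is reported as the residual.

3. **Methylation stage.** Beta values (methylated intensity fraction, in
   $[0,1]$) are compared two ways. Per sample: the count of probes whose
   tumor-minus-normal difference exceeds 0.2 in absolute value — the
   quantity correlated against NOM. Per cohort: a per-probe Welch
   two-sample t between the tumor and normal groups with
   Benjamini–Hochberg adjustment; probes with $|\Delta\beta| > 0.2$ and
   adjusted $p < 0.01$ are methylation variable positions (MVPs), hyper-
   or hypomethylated by the sign of $\Delta\beta$. Differentially
   methylated regions are found by bump hunting: maximal runs of at least
   3 probes with $|\Delta\beta| > 0.2$, consistent sign, and at most
   1000 bp between consecutive probes, scored by the sum of absolute
   deltas; significance comes from a genome-wide-maximum permutation null
   built by shuffling the tumor/normal labels (default 200 permutations;
   the reported $p$ uses the add-one estimator, so its floor is
   $1/(n_{perm}+1)$). Informative probes for clustering must pass four
   screens on per-pair $\Delta\beta$: pooled s.d. across the high and low
   TMB groups above 0.2, within-group s.d. below 0.1 in the high **or**
   the low group, group-mean difference above 0.2, and BH-adjusted Welch
   $p < 0.05$. Consensus clustering runs k-means repeatedly on random 80%
   subsamples of the samples, accumulates the co-clustering frequency
   among co-sampled pairs, and cuts an average-linkage tree of one minus
   the consensus matrix into $k$ groups. Genes with more than three MVPs
   in promoter features (TSS1500, TSS200, 5'UTR, 1stExon) are reported,
   and hyper- versus hypomethylated MVPs are contrasted on signed
   distance to the transcription start site with a two-sided Wilcoxon
   rank-sum test.

4. **CNA stage.** Per-probe copy-number log ratios are
   $\log_2(\text{tumor}/\text{mean normal})$, median-centered per sample
   to remove the global intensity scale. Chromosome arms with at least 10
   probes are called gained when the arm mean exceeds +0.15, lost below
   −0.15, neutral between, and `NA` otherwise; the aneuploidy score is
   the count of gained-or-lost arms. The thresholds are implementation
   defaults in the spirit of array-CNV tooling and are exposed as
   parameters.

5. **Association stage.** Pearson correlation (two-sided t-based $p$)
   between per-sample DMP counts and NOMs — reported both for the
   threshold-only count and, labelled separately, for the count restricted
   to cohort-significant probes, since either reading of the per-sample
   definition is defensible; Welch's unpaired t for group contrasts
   (chosen over the pooled-variance t because equal variances are not
   asserted anywhere); pairwise two-sided Fisher exact tests on
   gene-by-sample mutation presence for co-occurrence/mutual exclusivity
   (two-sided by summation of tables with probability at most the
   observed table's, the standard convention; direction by the sample
   odds ratio), BH-adjusted across pairs; and exact gene-set
   intersections.

`runPipeline()` executes all stages on a synthetic cohort and returns a
machine-readable report (per-sample NOM/TMB/tertile/DMP counts, the MVP
and DMR tables, exposures, arm calls, and the association statistics) with
provenance (seed and configuration hash); reruns with the same seed are
bit-identical.

# The synthetic cohort generator

No patient-level data accompany the analysis this package implements, so
the generator is a first-class, tested component that defines the study
conditions. It emulates:

* **NOM distribution**: log-normal with median 104 (log-sd 0.55), the
  scale of a treatment-naive NSCLC WES cohort.
* **Mutation records**: trinucleotide contexts drawn from a known mixture
  of catalogue signatures, written into a private per-sample reference
  sequence (a random half of SNVs are reported on the purine strand to
  exercise strand folding); 75% of calls nonsynonymous, 5% short
  insertions, and 20% engineered to fail at least one confidence filter.
  The ground-truth NOM is the realized count of filter-passing
  nonsynonymous calls, so recovery through the TMB stage is exact.
* **Methylation coupling**: each pair's shifted-probe fraction is
  $\mathrm{clamp}(a + b\,z, 0.01, 0.6)$ with $z$ the z-scored log-NOM
  ($a = 0.15$, $b = 0.10$ by default; $b = 0$ decouples the layers). Every
  probe is shifted with that probability, so realized counts carry
  binomial dispersion. Shift magnitudes are uniform on $[0.25, 0.5]$ —
  above the 0.2 detection threshold in expectation but not razor-edge —
  and 70% of shifts lose methylation.
* **Recurrence**: 60% of each sample's shifts come from a cohort-shared,
  spatially blocked aberrant-probe pool taken as a nested prefix, so
  heavily mutated samples recapitulate the aberrations of lightly mutated
  ones. Without this, per-probe group means average out across samples
  and no cohort-level MVPs, DMRs or informative probes exist to detect —
  recurrence is precisely what makes tumor methylation aberrance visible
  at cohort level. Baselines are bimodal (Beta(2,18) and Beta(18,2) modes
  near 0.1 and 0.9) and block-coherent over runs of ~10 probes, so
  losses land on methylated blocks and gains on unmethylated ones and
  clipping at $[0,1]$ does not erase the engineered effect.
* **Arm events**: the expected aneuploid-arm count is
  $\mathrm{clamp}(4 + 2z, 0, 39)$; gained arms multiply tumor intensities
  by 1.5 and lost arms by 0.5 over a shared per-probe affinity with
  log-scale noise (s.d. 0.1).

A single `set.seed()` at the top of `simulateCohort()` threads one
generator through every draw, so a seed fully reproduces a cohort.

What the generator does **not** emulate — and therefore what passing
recovery tests do not establish about real data: array normalization
artifacts and batch effects, cell-type composition differences,
probe-level measurement error structure beyond i.i.d. Gaussian noise,
linkage between the mutation and methylation layers other than the single
coupling coefficient, focal (sub-arm) copy-number events, and real
genomic context composition (each sample's reference is a synthetic
concatenation of drawn contexts). Recovery results show the pipeline's
statistics are implemented correctly and are well-calibrated under the
stated model, not that the biological effect sizes are as clean in real
cohorts.

# Numerical choices and degenerate inputs

* Printed TMB values use half-away-from-zero rounding at one decimal
  (`roundHalfUp()`); base R's round-half-to-even would print 2.45 as 2.4.
  All downstream statistics use unrounded values.
* A probe with zero variance in both groups gets Welch $p = 1$ when the
  means agree (never `NaN`) and $p = 0$ when they differ.
* Undefined correlations (zero variance, as with an all-zero NOM vector)
  are reported as `NA` with a textual flag rather than raising inside
  `runPipeline()`.
* Beta values must be in $[0,1]$; probes with any missing value are
  dropped with a message before analysis (no imputation is attempted,
  since none is described for the source analysis).
* Signature catalogue columns are renormalized when their sum is within
  $10^{-3}$ of one and rejected otherwise; spectra all of whose mass
  falls outside the catalogue's support fit to zero weights with residual
  one; an all-zero spectrum is an error ("no mutations to fit").
* Consensus clustering falls back to an average-linkage cut within a
  resample when k-means cannot seed enough distinct centers (duplicated
  samples); consensus entries for never-co-sampled pairs are zero.
* DMR candidate runs are defined on probes sorted by (chromosome,
  position); unsorted input is an error, not silently reordered.
* Median centering makes a uniform whole-genome gain uncallable — the
  standard limitation of relative-ratio copy-number methods — and is kept
  because uncentered ratios confound arm calls with global ploidy.

# Design choices where the design was open

* **Welch t, not a moderated t.** The per-probe test is an ordinary
  unequal-variance t. An empirical-Bayes moderated test would gain power
  at small group sizes; it is deliberately out of scope, and the
  difference matters mainly below ~5 pairs per group.
* **The within-group s.d. screen is read as "or".** The informative-probe
  caption condition "s.d. < 0.1 in high or low TMB group" is applied
  literally (either group tight suffices); probes loose in both groups
  are excluded under every reading. The alternative (both groups, or raw
  tumor betas instead of per-pair deltas) would tighten the screen; the
  choice is fixed here and exposed via the threshold parameters.
* **Consensus clustering is implemented in-package** (subsampled k-means,
  consensus ratio of co-clustered to co-sampled, hierarchical cut),
  following the convention of the widely used consensus-clustering
  tooling, so the package has no dependency beyond base R's `kmeans` and
  `hclust` for it.
* **Tertile remainder rule** as above: outer groups absorb extras, high
  before low.
* **Context normalization direction** is not hard-coded: the caller
  passes observed and target censuses, so exome-to-genome and
  genome-to-exome are both one call.
* **Pruning threshold 0.06** for exposures follows the established
  refitting convention and empirically trades a small bias on minor
  signatures for stability of the reported profile.

# Problem sizes used by the test suite

The suite exercises the pipeline at 12–29 pairs and 3,000–20,000 probes
(the thresholds are scale-free, so 20,000 probes stands in for an 850k
array), 100-replicate studies at 20 pairs × 20,000 probes for the
coupling-detection properties, 20-seed recovery runs at 5,000 sampled
mutations for signature refitting, and 10-arm cohorts (with the
aneuploid-arm load scaled proportionally) for CNA recovery. At these
sizes the whole suite runs in a few minutes on one core.

# Known limitations

* Arm calls use fixed mean-ratio thresholds rather than segmentation;
  focal events and subclonal fractions are out of scope.
* The permutation DMR $p$ has resolution $1/(n_{perm}+1)$ and tests
  against the genome-wide maximum, which is conservative for secondary
  regions; with very few pairs the label-permutation null is coarse.
* The per-sample DMP count under decoupled layers ($b=0$) is nearly
  constant up to binomial noise, so its sample correlation with NOM
  follows the usual null distribution for the cohort size — at 20 pairs
  the sample $|r|$ exceeds 0.2 in roughly a third of replicates even
  though the population correlation is exactly zero. Replicate studies of
  the null should report the distribution of $r$, not a single-replicate
  band.
* Signature refitting assumes the catalogue is correct and complete up to
  the residual; it does not extract signatures de novo.
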
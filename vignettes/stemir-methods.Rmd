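---
title: "Methods and design of the stemir pipeline"
author: "stemir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the stemir pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemir)
```

# Scope and model of the data

`stemir` implements the quantitative core of a miRNA-in-carcinoma study:
identify dysregulated miRNAs in tumor versus control cultures, nominate
their targets, vet targets against survival data, and quantify the cellular
phenotypes (spheroid formation, in-situ miRNA abundance, migration,
relative expression) that connect the miRNA to cancer-stem-cell-like
behavior. Expression inputs are assumed to be *post-normalization log2
intensities*; low-level microarray processing is deliberately out of scope,
which is why the synthetic generator produces data directly on the log2
scale.

Because the real study inputs (GEO accessions, TCGA clinical data,
versioned target databases) are external and versioned, the package's
correctness argument is built entirely on synthetic data with planted
ground truth plus independent statistical oracles, not on reproducing any
specific published number.

# Differential screen

Each feature is tested with an unpaired two-sided t-test between two sample
groups. The default is Student's pooled-variance flavor, since that is the
test named in the wet-lab conventions this pipeline accompanies; Welch's
test is available via `varEqual = FALSE`. P-values are adjusted with
Benjamini–Hochberg (the field default for array screens; the adjustment is
delegated to `stats::p.adjust` behind the validating wrapper `bhFdr()`, and
the test suite checks it against a from-scratch step-up implementation).

A feature *passes* iff all three hold: estimated fold change
$2^{|\widehat{\Delta}|} \ge$ `fcMin` (up- and down-regulation are treated
symmetrically through the absolute value, with a separate direction flag),
$p \le$ `pMax`, and FDR $\le$ `fdrMax`. Defaults (2, 0.05, 0.2) are the
thresholds conventional for miRNome screens of this design.

Degenerate features that are constant across all samples have an undefined
t-statistic; they are reported with $p = 1$ and never pass. A feature with
zero within-group variance but differing means is reported with $p = 0$
(perfect separation).

One property of the composite filter worth knowing: the fold-change gate
applies to the *estimated* fold change. At small sample sizes the estimator
$\widehat{\Delta} \sim N(\Delta, \sigma\sqrt{1/n_1 + 1/n_2})$ falls below
the threshold with substantial probability even when the true effect sits
exactly at the nominal cut — e.g. a true 2.2-fold effect with per-sample sd
0.3 and $n = 4$ vs 6 is retained in only ~72–76% of repetitions, with the
p/FDR conditions almost never binding. The recovery tests assert against
this computed rate rather than against an optimistic round number.

PCA is computed on centered, unscaled log2 values (`stats::prcomp`);
scaling is optional because array data are already on a comparable scale.
Group separation is summarized as the mean silhouette width of samples over
their group labels in score space — near 1 for cleanly separated clusters.

# Target nomination

Interaction tables from validated (miRTarbase-like) and predicted
(TargetScan-like) sources are merged into a deduplicated repository;
a pair present in both kinds of source gets evidence `"both"`. Candidate
genes are the intersection of the differentially expressed genes with the
targets of the miRNA family of interest.

Candidates are ranked by Pearson correlation between the gene's log2
values and the per-sample miRNA signal, ascending (most negative first).
Choices made here, where the underlying convention is genuinely open:

- **Correlation**: Pearson on log2 values, because log2 array intensities
  are approximately linear-Gaussian; Spearman is available via `method`.
- **miRNA signal**: arithmetic mean of the family member rows
  (`mirFamilySignal`), which reduces to the single miRNA's row when one
  member is given — both family-level and single-miRNA analyses are
  therefore the same code path.
- **Tie-breaking**: lexicographic by gene id, for full determinism.
- Constant candidates (or a constant signal) have undefined correlation and
  are dropped with a warning rather than silently ranked.

Over-representation of nominated genes in user-supplied GMT gene sets uses
the one-sided hypergeometric tail (`stats::phyper`) with BH across sets.
The test suite calibrates it against the *exact* null rejection rate
computed by enumeration, since the discrete p-value makes the naive
"rejection rate = α" expectation wrong at small set sizes.

# Survival analysis

Subjects are stratified at the linear-interpolation (R type-7) sample
quantile of the gene's expression, default $q = 0.75$: "high" means
*strictly above* the quantile, everything else is "mid/low". Strictness
plus the interpolated quantile gives a deterministic rule reproducing the
usual 75%-quantile split.

The Kaplan–Meier estimator and the two-group log-rank test are implemented
from first principles (and cross-checked against the `survival` package in
the test suite): deaths are processed before censorings at tied times, the
log-rank variance is the hypergeometric form at each distinct event time,
and no continuity correction is applied.

"Mean survival time" is realized as the *restricted mean* — the area under
the KM step function up to a truncation time `tau`, by default the largest
observed time across the compared strata. This is the only mean that is
well-defined under right censoring; with no censoring and `tau` at the last
event it reduces exactly to the arithmetic mean of the event times. Reports
based on it should state `tau`, since its value depends on follow-up
length.

`survivalScreen` applies stratify → KM → log-rank → restricted mean per
candidate gene and sorts by p-value. A gene whose stratification fails
(e.g. constant expression) yields an NA row and a warning instead of
aborting the whole screen.

# Spheroid morphometrics

Well images are segmented by global Otsu thresholding followed by
8-connective connected-component labeling (implemented as a union-find
merge of diagonal adjacencies on top of `EBImage::bwlabel`, which is
4-connective) and a minimum-area filter (default 4 px). No watershed
splitting is attempted by default: the synthetic truth renders
non-overlapping disks, and a parameter-free deterministic default is
preferred; touching aggregates in real images would require enabling a
splitting step upstream.

Distributions of object cross-section areas are compared with the exact
two-sample KS statistic evaluated at all pooled points (ties handled
exactly). The null distribution is Monte-Carlo: the pooled sample is
randomly re-partitioned into the observed group sizes (permutation without
replacement — an exact conditional null; bootstrap resampling is available
behind `method = "bootstrap"` and is flagged in the result object), and the
p-value uses the add-one formula $(1 + \#\{D^* \ge D\})/(B+1)$, which is
never zero and makes the test exact-level at achievable α. Three-condition
designs (parental / knock-out / mixed) are run as all pairwise tests with
BH across the pairs (`pairwiseKsTests`).

# In-situ single-cell quantification

Coordinate conventions: row-major rasters, origin top-left, masks are
integer label images with 0 = background. Nuclei are segmented from the
nuclear (DAPI) channel by Otsu + hole filling + labeling + min-area filter.
Cells are the Otsu foreground of the marker channel, with nucleus-free
components discarded and the remaining pixels assigned to the nearest
nucleus centroid — deterministic and adequate for non-touching cells; a
distance-transform watershed would be the upgrade path for confluent
fields.

Per cell, the probe channel is background-corrected (median of
outside-cell pixels, subtracted per pixel and clipped at 0) and integrated:
`total` over the cell, `nuclear` over the cell∩nucleus pixels, and
`cytoplasmic = total − nuclear` exactly — the un-dilated nuclear mask is
subtracted, confining the readout to the cytoplasm where mature miRNA
resides. Two invariants follow by construction and are asserted on every
image: conservation (total = nuclear + cytoplasmic) and invariance of all
measurements to a constant intensity offset (absorbed by the background
estimate as long as the foreground/background partition is unchanged).

Per-sample densities use a Gaussian kernel with Silverman's bandwidth on a
512-point grid extended four bandwidths beyond the data range, so the curve
integrates to 1 within 10⁻³. Distribution comparisons always use the raw
per-cell values, never the smoothed curves.

# Assay statistics

**ΔΔCq.** Per sample, ΔCq = mean Cq(target) − per-reference mean Cq,
averaged over reference genes (arithmetic mean of per-reference ΔCq, which
equals normalizing expression by the geometric mean of the references —
standard with two references such as GAPDH and TUBA1). ΔΔCq subtracts the
control-group mean ΔCq, so the control group's geometric-mean RQ is exactly
1 by construction. The group test is an unpaired two-sided t-test on ΔCq
(log2 scale, where normality is plausible), not on RQ. The whole analysis
is invariant to a constant Cq machine offset.

**Gap closure.** Series are normalized to the first timepoint; closure time
is linearly interpolated at a 1% remaining-gap threshold, with `NA` for
"not closed". Because the field's readout convention at a fixed timepoint
varies, `gapReadout` reports all three quantities (gap area, gap fraction,
percent closure) at the requested time (default 6 h), and
`compareGapClosure` t-tests the fractions across replicate series.

**Proliferation confounder.** Log-linear growth rates are fitted per
replicate (`lm(log(count) ~ day)`) and compared between conditions; the
verdict is "confounded" iff rates differ at α = 0.05. On exact exponential
data the fitted rate equals ln 2 / doubling time to numerical precision.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults encode the
study conditions the pipeline is meant to handle:

- Expression: groups of 6 control vs 4 tumor cultures, per-sample log2
  noise sd 0.3, planted fold changes around 2.2-fold, planted miRNA→target
  slopes of −1 with residual sd 0.2 — effect and noise scales typical of
  primary-culture array screens.
- Survival: n = 200 subjects, exponential event times with a protective
  hazard ratio of 3 for the top expression quartile, baseline hazard
  1/1000 per day and independent exponential censoring at 1/4000 per day —
  a cohort with mean survival on the order of years and a realistic
  censoring fraction. Censoring is independent exponential because that is
  the simplest mechanism consistent with the KM assumptions.
- Images: cells and aggregates are rendered as non-overlapping axis-aligned
  disks, which keeps segmentation ground truth exact up to pixelation;
  per-cell probe totals are lognormal, with a configurable nuclear fraction.
- Spheroids: lognormal area mixtures; the stable-former condition puts 90%
  of mass in a large-object component, the fragmenting condition 60% in the
  small-object component.
- qPCR/migration: planted fold 4 with Cq sd 0.2 cycles; linear gap closure
  at a configurable fraction per hour.

Every generator takes one integer seed and evaluates under a temporarily
seeded RNG that is restored afterwards, giving bit-identical outputs for
identical configurations and leaving the caller's RNG stream untouched.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: probe-level array artifacts and normalization
residuals, touching/overlapping cells and aggregates, spatially varying
backgrounds and illumination, non-exponential hazards, and informative
censoring. The segmentation defaults in particular are validated only for
well-separated objects.

# Numerical and testing choices

Problem sizes in the test suite and the acceptance script are chosen to
give stable Monte-Carlo estimates on a single CPU within minutes: 200–500
replicate seeds for calibration and recovery rates (99% binomial intervals
are used as tolerances), B = 2000 resamples for null-calibration runs of
the MC-KS test and B = 10000 for single demonstrations, 2000-feature
matrices for FDR-context screens, and n = 10⁴ draws for moment-convergence
checks (asserted within 3 standard errors). Oracle-equivalence checks
(log-rank vs brute-force risk-set enumeration, KS vs ECDF enumeration, BH
vs the step-up definition) use tolerance 10⁻¹⁰ or tighter on hundreds of
random small instances.

Known limitations: the screen's t-test assumes approximate normality on
the log2 scale and offers no empirical-Bayes variance moderation (out of
scope by design); Pearson ranking is sensitive to single-sample outliers at
n = 10 matched samples (Spearman is the robust alternative); the restricted
mean depends on the truncation time; and the nearest-centroid cell
assignment under-performs watershed methods on confluent fields.
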
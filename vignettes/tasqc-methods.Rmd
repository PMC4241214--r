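---
title: "Methods: QC and adaptive variant calling for FFPE amplicon sequencing"
author: "tasqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QC and adaptive variant calling for FFPE amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tasqc)
```

# The problem

Deep targeted amplicon sequencing (TAS) is the workhorse for detecting
low-abundance somatic mutations in clinical tumor material. The hard cases
are formalin-fixed paraffin-embedded (FFPE) samples: fixation fragments the
DNA and deaminates cytosines, which inflates the background of G>A / C>T
substitutions (written GC>AT throughout), and the pool of amplifiable
template can be a small fraction of what a spectrophotometer reports. A
calling pipeline that treats such a sample like intact DNA either floods
the report with false positives or, if thresholds are raised globally,
throws away real low-abundance variants.

`tasqc` implements the analysis layer that addresses this end to end. The
unit of analysis everywhere is the *hypothesis*: one of the three possible
base substitutions at a panel position, so a panel of $n$ positions exposes
$3n$ hypotheses. The package consumes post-alignment per-hypothesis tables
(position, ref, alt, depth, alt-supporting depth, percent variant, log
variant score); read-level processing (trimming, alignment, recalibration)
is out of scope.

# Systematic variants from the Hardy-Weinberg envelope

Recurrent technical artifacts ("systematic variants", SVs) are specific to
a panel/library-prep/platform combination and appear with similar
percent variant in many samples. Real germline variation behaves
differently across a cohort: for a biallelic site with non-reference allele
frequency $p$ under Hardy-Weinberg equilibrium the genotypes occur at
$(1-p)^2$, $2p(1-p)$, $p^2$, the cohort mean allele fraction is $p$, and
the cohort standard deviation is

$$\mathrm{SD}(p) = \sqrt{p(1-p)/2}.$$

Plotting per-hypothesis cohort SD against cohort mean, true variants trace
this parabola; SVs sit far off it (typically high mean, tiny SD).

`simulate_envelope()` turns the parabola into an acceptance band: for each
penetrance on a grid it draws cohorts of `n_samples` multinomial genotype
vectors, maps genotypes to noisy percent variants through a measurement
model, and pools the (mean, SD) pairs into 100 equal-width mean bins. The
central 99.8% interval of SD within each bin (the "3 SD" band under
normality) is the envelope. `classify_svs()` then flags a hypothesis as an
SV when all three criteria hold: its (mean, SD) falls outside the band at
its mean, it carries no annotation (dbSNP/COSMIC-style membership is an
input file), and it reaches at least 2% variant in at least one sample.
Annotated out-of-band hypotheses are counted and excluded rather than
listed.

Decisions that were genuinely open:

* **Measurement model.** The source procedure samples "percent variant
  estimates corresponding to the appropriate genotypes" without naming a
  distribution. The default parametric model draws wild type as
  $|N(0,\sigma_0)|$ with $\sigma_0 = 0.5$ percent (a half-normal noise
  floor), heterozygotes as $N(50, \sigma_1)$ and homozygotes as
  $100 - |N(0,\sigma_1)|$ (a normal truncated at the 100% boundary),
  $\sigma_1 = 3$ percent by default and configurable; an
  empirical-resampling model (`empirical_measurement_model()`) accepts
  user-supplied genotype clusters. Note the truncated homozygote draw
  slightly shrinks the high-$p$ arm of the parabola; because
  classification compares data against the *simulated* band built with the
  same model, this is self-consistent.
* **Conditioning.** The band is conditioned on the observed cohort mean
  (binned), not on an estimated penetrance; the two coincide in
  expectation. A mean falling in a bin that no Hardy-Weinberg-consistent
  cohort ever reached is an outlier by construction.
* **Missing measurements.** Mean and SD are computed over available
  samples, but a hypothesis measured in fewer than 80% of samples is
  reported "unevaluable" instead of being classified — SD estimates from
  tiny $n$ would otherwise dominate the out-of-band set.
* **Envelope scale.** Bands are cohort-size-specific; `classify_svs()`
  refuses an envelope built for a different cohort size.

The analytic identity $E[S^2] = 5000\,p(1-p)$ (percent scale) is exact for
the sample variance, so the envelope records both the mean and the
root-mean-square of the simulated SDs; convergence tests compare the RMS
against the parabola (the mean sample SD has the usual small-sample
downward bias, which is not a property of the method).

# Sample-adaptive two-dimensional thresholds

Because the GC>AT background moves with sample quality while the other ten
substitution classes stay comparatively clean, a single score cutoff
cannot serve both. `grid_search()` evaluates every pair
$(t_{GC>AT}, t_{other})$ of log-score thresholds on an evenly spaced grid
(default 2 to 20 by 0.5) and accepts pairs whose resulting call set
satisfies three SNP-rediscovery constraints:

1. **Calls per kb** in $[0.36, 1.5]$ — germline variation dominates a
   broad panel at roughly one variant per kb;
2. **Percent annotated** $\ge 75$ — annotation membership is a surrogate
   for PPV;
3. **Ti/Tv** in $[1.58, 4.53]$ — the expected transition/transversion
   range for germline SNV sets.

Among feasible pairs the one closest (Euclidean) to the fresh-frozen
default $(6, 6)$ is returned; exact ties break towards smaller
$t_{GC>AT}$, then smaller $t_{other}$, favoring sensitivity. An infeasible
sample is a *qualification failure* — a first-class outcome that the
pipeline reports rather than forcing calls. Score comparison is inclusive
(`>=`) so the default pair is attainable on integer-scored data. The
constraint metrics are computed per sample over the hypotheses that
survive the depth filter (at least 100 reads and 10% of the sample median
by default), because thresholds are set in a sample-specific manner.

The package ships a reference scorer, `reference_score()`: $-\log_{10}$ of
the Poisson upper-tail probability of the observed alt count given an
expected background `depth * error_rate`. It is a pluggable stand-in — the
grid search only needs *some* continuous log-scale score and is agnostic
to the caller that produced it.

# Orthogonal-platform confirmation

Platform-private SVs cap single-platform performance: suppressing them
costs sensitivity. Measuring the same material on a second, independent
enrichment/sequencing technology exposes them, because a private artifact
shows signal on one platform and essentially zero on the other.
`joint_call()` predicts a positive only when percent variant strictly
exceeds the threshold on *both* platforms (restricted to positions covered
on both after each platform's own depth filtering);
`grid_optimize()` exhaustively maximizes the f-measure — the harmonic mean
of sensitivity and PPV — over the Cartesian grid of per-platform percent
thresholds (default 0–50% by 0.5%), with a deterministic lexicographic
tie-break. On synthetic two-platform data the joint optimum dominates the
best single-platform optimum and does so at equal-or-lower thresholds.

`confirm_workflow()` implements sequential confirmation: primary
thresholds are relaxed multiplicatively on the log-score scale
($t \to (1 - 0.2)\,t$ by default — the relaxation is interpreted on the
score thresholds, not on percent variant), candidates are then required to
show at least 1% variant on the confirmation platform, and candidates with
no confirmation measurement are reported "unconfirmable" and excluded from
the confusion counts. Exact binomial confidence intervals
(`clopper_pearson()`, beta-quantile inversion) accompany sensitivity and
PPV; the choice of the exact method is deliberate, since for $x = n$ its
lower bound is $(\alpha/2)^{1/n}$, the form the reference results for
all-success counts follow.

# Reference DNA mixtures

`greedy_select()` orders candidate reference samples by iteratively adding
the sample contributing the most loci whose genotype (alt dosage 0/1/2) is
not yet represented in the selection — ties break to the
lexicographically smallest identifier, so the design is reproducible.
Mass fractions are treated as genome-copy fractions (equal genome sizes
assumed). For mixing coefficients $c_k$ and dosages $d_k$,
`expected_pct_variant()` returns $100\sum_k c_k d_k / 2$ per locus, and
`expected_cdf()` summarizes how strongly a design enriches for
low-fraction variants. Agreement between observed and expected percent
variant is scored with Lin's concordance correlation coefficient
(`ccc()`, $2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$, $1/n$
moments), which penalizes location and scale error, not just correlation.
`precision_summary()` reports per-level medians and type-7 interpolated
IQRs and their medians across levels; the quartile convention is stated
because IQR values are quantities of record. Mixture-coefficient
optimization beyond exhaustive search over a user-supplied candidate set
is intentionally not provided.

# QFI sample qualification

The quantitative functional index is the percentage of nominal input
templates that actually amplify. `fit_calibration()` fits Cq against
$\log_{10}(\text{copies})$ from a titration of intact DNA (the reference
series is 5-fold from 50 ng to 16 pg, about 3.5 logs);
`compute_qfi()` inverts a sample's Cq through the curve and divides by the
copies implied by the input mass. Constants and conventions:

* `copies_per_ng = 303` by default (one haploid genome is ~3.3 pg); the
  constant is configurable because the reported QFI scale depends on it.
* "Not detected" means no Cq by cycle 50; such samples are
  `UNDETECTABLE` with QFI 0.
* The qualification gate is strict `> 3%` (with a 1e-9 epsilon so a value
  equal to the gate up to floating-point dust does not pass); detected
  samples at or below the gate are `MEASURABLE_LOW` — analyzable, but at
  documented risk of coverage loss.
* QFI above 100% flags a calibration anomaly and is reported unclipped.

`stratify_concordance()` tabulates per-tier agreement against a reference
platform at a hotspot set, with explicit `LOW_COVERAGE` (<100 reads) and
`NO_COVERAGE` categories so each tier's entries always total
samples x hotspots; `tier_association()` is Fisher's exact test on the
tier-by-status table (delegated to `stats::fisher.test`).

# What the synthetic data emulates — and what it does not

All generators are pure functions of (parameters, seed) and ship ground
truth. The defaults encode the study conditions the package is validated
under:

* **Backgrounds** are zero-inflated exponentials whose empirical 99th
  percentile matches class- and preset-specific anchors: GC>AT 2.6% at
  2000 ng FFPE rising to 8.4% at 250 ng, with other substitutions lower
  (1.3–2.0%); intact DNA stays at 2.0–2.7%. Only the percentiles are
  anchored observations — the exponential family is a declared
  calibration convenience, not an inference.
* **Heterozygote dispersion** follows the titration ladder 5.1 -> 15.6
  percent SD (FFPE) and 3.0 -> 5.5 (intact) across 2000 -> 250 ng, with
  geometric interpolation at the intermediate masses.
* **Depths** are negative binomial (size 8) with a 7% uniform low-coverage
  dropout component, tuned so roughly 89%/92% of amplicons fall within
  2-fold/5-fold of the median at the intact high-input preset.
* **Planted SNP classes** are stratified at 35% GC>AT, 36% other
  transitions, 29% transversions (Ti/Tv about 2.45) so that callset-level
  Ti/Tv reflects composition rather than multinomial noise.
* **Problem sizes** are the package's own choices for tractable
  validation: titration samples use a median depth of 150 reads over
  100 planted heterozygotes and ~25,000 background hypotheses on a
  nominal 100 kb panel; the reference scorer uses `error_rate = 0.02`
  there, which places clean-sample calls near the fresh-frozen default
  threshold of 6 on the log-score scale. Envelope validation uses
  10,000 replicates per grid point (the envelope default is 100,000).

What passing tests on this material do *not* show: sequence-context error
structure (the generators know substitution classes, not motifs), amplicon
dropout driven by GC/entropy, PCR duplicate structure, contamination, or
real inter-run batch effects. A cohort result on synthetic data
demonstrates that the algorithms recover the parameters they were designed
around, not that a particular wet-lab panel meets a performance number.

# Numerical conventions and degenerate inputs

* Medians and quartiles use the linear-interpolation (type 7) convention
  everywhere.
* Percent variant is $100\,\text{alt depth}/\text{depth}$ (alt over total
  at the position); zero-depth hypotheses are kept with a `no_coverage`
  flag but excluded from every statistic, and the TSV dialect round-trips
  numerics bit-exactly via `%.17g`.
* BED intervals are 0-based half-open; hypothesis positions are 1-based.
* `titv_ratio()` returns `Inf` with transitions and no transversions
  (which fails the Ti/Tv range constraint) and `NaN` for an empty call
  set (infeasible by definition).
* Empty tables, all-zero depth vectors, rank-deficient calibrations and
  degenerate (zero-width) envelopes warn or error early rather than
  propagating `NaN`s.

# Known limitations

Indels, CNVs and translocations are out of scope, as is germline
genotype calling and any population-structure correction to the
Hardy-Weinberg model. The SV test assumes cohort samples are unrelated and
broadly disease-free at panel loci; a recurrent true somatic hotspot in a
cohort of tumors could, in principle, violate the parabola and be flagged
— the annotation-exclusion criterion is the guard, and catalogs should be
built from normal-tissue cohorts. The adaptive threshold search inherits
the resolution of its grid; thresholds finer than the step are not
distinguished.
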
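---
title: "Methods: methylation-based carcinogenic risk estimation for NASH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation-based carcinogenic risk estimation for NASH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrisk)
```

## Overview

`methrisk` implements a discovery-to-classification pipeline for
estimating hepatocellular-carcinoma (HCC) risk from the DNA methylation of
liver tissue in non-alcoholic steatohepatitis (NASH). The design premise is
that methylation alterations present in non-cancerous NASH tissue from
patients in whom HCC has arisen (NASH-W), relative to normal liver tissue
(NLT), are established at the precancerous stage and carried into the
tumour; markers of that state, applied to biopsies of patients without
HCC, flag elevated carcinogenic risk. This vignette documents the models,
the tunable parameters and their defaults, the numerical choices, and what
the synthetic-data generator does and does not emulate.

## The β-value cohort model

Array methylation is expressed as the β value — methylated signal over
total signal at one CpG site, in [0, 1]. `simulate_beta_cohort()` draws,
for each probe, a baseline mean from a bimodal mixture (Beta(2, 8) or
Beta(8, 2) with equal probability), reflecting the characteristic
two-mode distribution of array β values. Sample-level noise is
Beta-distributed around the group mean with concentration `beta_precision`
(mean *m* gives shape parameters *m·φ* and *(1 − m)·φ*). A Beta noise
model was chosen because it respects the [0, 1] support and reproduces the
heteroscedasticity of β values — variance shrinks toward the 0 and 1
boundaries — which a Gaussian model would not. The default φ = 50 gives a
within-group SD of about 0.07 at β = 0.5, a realistic replicate spread for
clinical tissue panels.

Planted differential probes shift the group mean by `delta_planted`
(alternating hyper/hypo sign) in groups whose label ends in `-W`, and by
`delta_planted + trend_gain` in tumour tissue `T`, producing the monotone
stage trend the screen is designed to detect. Groups with `-O` labels
(disease tissue from patients without HCC) stay at the NLT baseline,
mirroring the empirical observation that risk-marker methylation in
non-cancer-associated tissue resembles normal liver. All group means are
clamped to [0.01, 0.99] before noise. The default cohort design is
36 NLT / 91 NASH-O / 22 NASH-W / 22 T (171 samples), and
`validation_group_sizes()` provides the 55-sample validation design
(22 NLT / 9 NAFL-O / 3 NASH-O / 10 NAFL-W / 11 NASH-W). Manifest flags
default to the array-scale proportions of low-call probes (751/485,764)
and X/Y probes (11,648/485,764).

What the generator does *not* emulate: raw array intensities and probe
type (I/II) chemistry bias, batch effects, bisulfite-conversion or PCR
artefacts, correlation between neighbouring probes, and within-sample
cell-lineage mixtures at the β level (lineage heterogeneity is modelled
only on the chromatogram side, as multi-component peaks). Passing tests
therefore demonstrate the correctness of the statistical machinery under
clean, independent-probe conditions — not robustness to array artefacts,
which the pipeline assumes have been handled upstream of the β matrix.

## Probe screen

`filter_probes()` removes probes with detection call proportion below
`call_threshold` (default 0.90; low call proportions typically indicate
polymorphism at the probe site) and probes on `exclude_chromosomes`
(default X/Y, matched case-insensitively, avoiding sex-linked methylation
bias). Removal counts are reported per rule with their overlap, so
retained + removed always partitions the input.

`welch_screen()` computes row-wise Welch unequal-variance *t* statistics
with Welch–Satterthwaite degrees of freedom, vectorised over probes; the
scalar `welch_test()` shares the same core. The test is two-sided —
directionality is carried by Δβ, not by the test — since a discovery
screen should not prejudge the direction of alteration. Degenerate probes
(zero variance in both groups) return p = 1 when means agree and p = 0
with a flag otherwise. Probes with fewer than two non-missing values in a
group are skipped with a recorded reason.

`bonferroni_select()` applies `p < alpha_family` and `|Δβ| >
delta_threshold` with strict inequalities (the effect gate reads "more
than 0.1"). The per-test alpha is always supplied explicitly, in one of
two modes: `bonferroni_alpha(n_tested)` = 0.05/*n* computed from the
family actually tested after QC, or a fixed printed constant
(`alpha_fixed`, default 1.12 × 10⁻⁷). Both are supported because the
published constant for this design does not exactly equal 0.05/473,365
(≈ 1.056 × 10⁻⁷) and the family size behind it is not stated; the package
asserts neither as canonical.

## Jonckheere–Terpstra trend filter

For ≥ 3 ordered groups the statistic is the concordant cross-group pair
count J = Σ_{g<h} #{(x∈g, y∈h): y > x}, ties counting ½. Three null
distributions are implemented:

- **exact** (tie-free data): J decomposes as a sum of independent
  Mann–Whitney statistics of each group against its predecessors pooled,
  so the exact null is the convolution of `dwilcox` mass functions —
  cheap at any realistic size;
- **normal**: tie-corrected variance with a ±0.5 continuity correction;
- **permutation**: seeded Monte-Carlo with `nperm` draws.

`method = "auto"` uses the exact null for tie-free pooled *n* ≤ 12 and the
normal approximation otherwise. The normal route is the default inside
`trend_inherited_set()` because the screen evaluates thousands of probes
at cohort sizes (n ≈ 80) where the approximation is accurate (the test
suite verifies agreement with the exact null to within 0.02 at small *n*)
and a per-probe Monte-Carlo null would cost orders of magnitude more for
no inferential gain. The trend alternative per probe follows the sign of
its Δβ, and probes with one-sided p < `trend_alpha` (default 0.05) are
retained as "inherited or strengthened".

## Marker selection

`roc_auc()` computes AUC as the Mann–Whitney probability that a case
value exceeds a control value (ties ½), via ranks. The discrimination
direction is `hyper` when the case mean exceeds the control mean, `hypo`
otherwise, and the AUC is reported in that direction — one AUC plus a
direction per marker, the convention used in published marker tables.

`youden_cutoff()` maximises J = sensitivity + specificity − 1 over
midpoints of adjacent distinct pooled values. Midpoints are the natural
candidate set once the calling rule is fixed: positive at value ≥ cutoff
(hyper) or ≤ cutoff (hypo), so thresholds between the same two data values
are equivalent. Ties in J break toward the smaller cutoff, a fixed
deterministic rule. Degenerate inputs return J = 0 with the pooled median
as a flagged placeholder. Equality at the cutoff counts as positive — the
risk-sensitive choice for a screening assay, applied consistently here
and in `classify_cohort()`.

`select_panel()` is the two-stage gate: stage 1 keeps probes with AUC
strictly above `auc_threshold` (default 0.95, "larger than") against NLT
and fixes their Youden cutoffs on that comparison; stage 2 keeps those
whose specificity against NASH-O, evaluated with the stage-1 cutoff, is at
least `specificity_threshold` (default 0.85, "85% or more", hence ≥). The
stage-2 subset is always nested in stage 1; hyper and hypo counts
partition the stage-1 set.

`multivariate_risk_model()` fits outcome ~ ballooning + Brunt stage +
methylation by maximum-likelihood logistic regression. Ballooning is
dichotomised (0 = none, 1 = present) and Brunt stage coded ordinal 0–4;
the encoding is a package choice since score-to-covariate mappings vary
between studies. Separation — plausible here, since marker ORs in the
hundreds arise at these sample sizes — is detected from the glm fitted-
probability warning or from runaway estimates (|coef| > 15 or SE > 100);
a flagged fit reports profile-likelihood intervals instead of Wald. No
multiplicity correction is applied across per-marker model runs, matching
per-marker reporting tables.

## Chromatogram quantification

The measurement model: bisulfite conversion maps methylation state to
sequence, PCR products of methylated and unmethylated template differ in
retention on an anion-exchange column, and the UV trace therefore encodes
methylation level as peak position between the fully unmethylated (0%)
and fully methylated (100%) control products.

**Peak shape.** Components are exponentially modified Gaussians (EMG):
Gaussian centre μ and width σ with an exponential tail constant τ ≥ 0;
τ → 0 recovers the symmetric Gaussian. EMG is the standard model of
chromatographic asymmetry. Numerically the profile is evaluated through
the scaled complementary error function in two branches (with an
asymptotic-series patch for large arguments), which avoids the 0 · ∞
overflow of the naive exp·erfc form for small τ — the naive form fails
catastrophically inside an optimiser.

**Baseline.** `correct_baseline()` subtracts the line through the median
absorbance of a leading and trailing window (default 0.5 min). A
curvature heuristic — residuals from a within-window line fit large
relative to the window's own noise — warns when a peak intrudes into a
window; pure linear drift does not trigger it.

**Fitting and model choice.** `fit_peaks()` fits 1- and 2-component
models by bounded Levenberg–Marquardt least squares, with Savitzky–Golay
smoothed local maxima as position starts and a small multi-start sweep
over plausible widths (τ starting near the Gaussian limit), which in
practice removes the broad-pedestal local minimum. Component count is
chosen by small-sample-corrected AIC, with two guards: the 2-component
model must win by at least `aicc_margin` (default 10, "decisive" on the
usual information-criterion scale — without a margin, pure noise promotes
a phantom second component in roughly one noisy single-peak trace in
ten), and components under 1% of total area do not count as structure.
The noiseless residual floor is tied to the trace's own noise estimate so
the criterion remains defined when residuals vanish.

**Pattern rule.** One fitted component → `single`. Two components →
`bimodal` when the fitted curve's valley drops below `valley_frac`
(default 0.8) of the lower mode, else `single_with_shoulder`; a fitted
two-component curve with a single mode is always a shoulder. On noiseless
traces this boundary is a deterministic function of component separation
and width, which the tests verify analytically.

**Calibration and rates.** `calibrate()` anchors the affine map
percent(rt) = 100·(rt − rt₀)/(rt₁₀₀ − rt₀) on the dominant-peak retention
times of the control pair; either elution order is accepted, because
which product elutes first depends on column chemistry and is not assumed.
Controls separated by less than `resolution_floor` (default 0.05 min) are
a calibration error. `methylation_rate()` maps each component's apex
through the calibration and averages with area weights — the single-peak
case degenerates to the calibrated peak position. Rates outside [0, 100]
are clamped to the boundary and flagged rather than extrapolated.
Calibration is per run and per marker; between-run retention drift is not
corrected and is a known limitation.

**Simulated chromatograms.** `chrom_spec()` defaults: a 0–10 min window
(matching a 10-minute elution gradient), 120 points/min (enough to
resolve shoulder patterns at default widths), σ = 0.15 min, τ = 0,
constant baseline plus optional linear drift, and Gaussian noise.
Component retention times come from inverting the same linear calibration
used for quantification, so simulation and analysis share no code path
beyond that definition — recovery tests are end-to-end, not circular:
the trapezoidal-integration and valley-rule oracles in the test suite
operate on the raw simulated trace, independently of the fitting code.

## Composite risk call

`classify_cohort()` applies each panel marker's cutoff and direction to
each sample's rate (ties positive) and calls a sample risk-positive when
at least *k* of *n* criteria are satisfied (default 2, as in the
validated 2-of-3 design). Samples missing any marker rate are skipped
with a logged reason — no imputation, and no reduced-panel call, a
deliberately conservative choice. `cohort_performance()` reports
sensitivity pooled over the `-W` groups (NAFL-W ∪ NASH-W), matching how
mixed validation cohorts are summarised, specificity against the chosen
control groups (NLT by default; disease-control groups can be designated
instead, and both framings are meaningful), and the per-group histogram
of samples by number of satisfied criteria. Percentages are kept at full
precision internally and rounded to integer percent only in the printed
summary line.

## Pipeline, configuration and interfaces

`run_pipeline()` composes the stages in order and records a probe-count
cascade (input → QC-retained → differential → trend → AUC stage → panel),
which is non-increasing by construction. Every printed threshold lives in
`pipeline_config()` as a default — call threshold 0.90, |Δβ| > 0.1, trend
alpha 0.05, AUC > 0.95, specificity ≥ 0.85, k = 2 — and none is hard-coded
in stage logic. For HPLC quantification the pipeline carries the
`max_hplc_markers` highest-AUC panel markers (default 3, the size of the
validated composite), simulates sample rates from the samples' own β
values scaled to percent, and converts β-scale cutoffs by the same factor.
All randomness flows through seeds stored in the configuration; a given
configuration reproduces its result bundle byte for byte. The exported
functions and the plain-text format suite (TSV β matrix, CSV manifest and
annotation, CSV chromatogram with JSON sidecar, JSON panel, TSV rates)
are the package's interface; there is no shell entry point.

## Problem sizes and test design

The test and acceptance suites run at sizes chosen to make every
statistical claim checkable by an independent route in seconds: exact
trend-test nulls at pooled n ≤ 12 against the normal approximation (100
fixtures); AUC against brute-force pair enumeration; Youden against
exhaustive threshold search; logistic odds ratios against the closed-form
2×2 cross-product and a 50-replicate coefficient-recovery study at
n = 500; marker recovery at the study design of 36 vs 22 samples with
5000 probes, 50 planted effects of |Δβ| = 0.3 and φ = 50 over 20 seeds;
and chromatogram rate recovery over 20 seeds per pattern at 2%-of-peak
noise. The end-to-end pipeline example uses a reduced cohort (2000
probes), which exercises every stage while keeping the full suite fast.

## Known limitations

- No array normalisation, batch correction or probe-type bias adjustment;
  inputs are assumed to be final β values.
- The trend filter implements only the monotone-trend criterion; no
  additional pairwise NASH-W-vs-T significance requirement is imposed.
- Chromatogram deconvolution is limited to two components; unequal
  component widths are fitted by default (an equal-width constraint is
  available but off, since the true instrument constraint is unknown).
- Cross-run retention-time drift is not modelled or corrected.
- Risk calls for disease tissue from patients without HCC are reported,
  not adjudicated — whether such samples are false positives or
  yet-to-progress true positives is a question for longitudinal
  follow-up, outside the package's scope.
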
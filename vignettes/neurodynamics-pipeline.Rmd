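---
title: "Between-network neurodynamics: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Between-network neurodynamics: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsndyn)
```

`rsndyn` extracts four families of between-network connectivity and
dynamics metrics from resting-state network (RSN) activity time series,
screens them with permutation tests, and benchmarks small-sample
classifiers that separate a clinical group (here labelled ACA, accelerated
cognitive ageing in epilepsy) from controls. This vignette explains the
models behind each stage, the parameters that matter, what the synthetic
cohorts emulate, and the design decisions taken where the design was
genuinely open. Everything quantitative stated here is computed by the
package's tests or by `scripts/acceptance.R`; nothing is quoted from
external sources.

## The data model

A session is a `network_ts`: a T x N matrix of network activity (default
T = 208 samples at dt = 2 s, i.e. a 7-minute scan; N = 14 labelled
networks such as DMN, DAN, SN). A `cohort` collects sessions sharing one
network panel; observations are keyed by (subject, session) with two
sessions per subject (RS1, RS2) and a group label that is a property of
the subject. All timing is carried in seconds; no frame-index arithmetic
appears in metric APIs.

## Static functional connectivity (sFC)

Whole-record Pearson correlation between every pair of networks. The
N(N-1)/2 unique entries are vectorized in row-major upper-triangle order
and named `sFC-<A>-<B>` with A before B in panel order. For N = 14 this
yields 91 features. Because Pearson correlation is invariant to per-channel
affine rescaling, no normalization option is exposed.

## Conditional Granger causality (GC)

All series are demeaned and a VAR(p) is fitted by ordinary least squares.
The causality from source j to target i, conditional on the remaining
networks, is

  g_ij = log( RSS of target i in the reduced model omitting source j's lags
              / RSS in the full model ),

clamped at zero (the reduced model is refitted independently, so tiny
negative values can occur numerically). One common order p is used for
all pairs, selected by BIC on the full multivariate fit (orders 0..max
compared on a common effective sample); at the study geometry (T = 208,
N = 14) orders above 3 leave few degrees of freedom per equation and
trigger a warning. Summaries follow the convention that row sums of
G = {g_ij} are total causal inflow (DegIn), column sums total outflow
(DegOut), NetDeg = DegOut - DegIn (which telescopes to zero over
networks), and the pairwise net causality is g(A->B) - g(B->A).

Feature grammar: `A->B`, `A<-B`, `netgc_A->B` for each pair (A before B in
panel order; the arrow encodes direction), plus `GC_DegIn_*`,
`GC_DegOut_*`, `GC_NetDeg_*`: 3 * 91 + 3 * 14 = 315 features for N = 14.
Published feature lists in this literature do not use one consistent
pair-ordering rule for directed names; the bijective grammar above was
fixed so that every directed quantity has exactly one name.

For N = 2 the conditional estimator reduces to classical pairwise GC; the
test suite checks it against an independent `lm()`-based two-variable
implementation to 1e-8.

## Morlet wavelet coherence and time-of-coherence

The continuous wavelet transform uses the standard Morlet mother wavelet
(nondimensional frequency 6), 12 sub-octaves per octave, and log2-spaced
scales spanning periods 4-128 s; at dt = 2 s and T = 208 the full range is
resolvable. Squared coherence is the smoothed cross-spectrum magnitude
normalized by the smoothed auto-spectra, with the usual scale-dependent
Gaussian time smoothing and a 0.6-octave boxcar across scales; without
smoothing, coherence is identically 1. The phase of the smoothed
cross-spectrum is classified into four quadrants partitioning (-pi, pi]:
in-phase [-pi/4, pi/4), leading [pi/4, 3pi/4) (signal 1 leads),
anti-phase [3pi/4, pi] and [-pi, -3pi/4), lagging [-3pi/4, -pi/4).
Interval notation with open boundaries on both sides would not partition
the circle, so lower boundaries are closed.

Significance is assessed pointwise against AR(1) surrogate pairs matched
to each channel's lag-1 autocorrelation: the per-scale threshold is the
(1 - alpha) quantile of surrogate coherence pooled over in-cone times
(alpha = 0.05, 300 surrogates by default; tests use 100 where noted). The
null coherence distribution depends on the inputs only through (T, dt,
the two autocorrelations), so the batch feature extractor shares
thresholds through a cache keyed by the autocorrelations rounded to 0.1 —
this is what makes 91 pairs x 48 sessions tractable, and the pointwise
null calibration is unaffected (a null AR(1) pair shows a significant
fraction of ~0.05 inside the cone, as the acceptance tests verify).

Time-of-coherence: for each of the five period bands [4,8), [8,16),
[16,32), [32,64), [64,128] s, a time point counts towards a phase class
if any in-band scale is significant at that time inside the cone of
influence (COI); when scales disagree the class of the
maximal-coherence significant cell wins, so per band the four phases sum
exactly to the total significant-time share. Values are percentages of
the scan duration. Two open choices were resolved as follows: cells
outside the COI never count (edge artifacts would otherwise inflate the
two slowest bands on a 416 s record), and counting is per time point
rather than per (time, scale) cell — the cell-counting variant remains
available behind `per_cell = TRUE`. Features are named
`ip|ap|lead|lag_<A>-<B>_s1..s5`: 4 * 5 * 91 = 1820 for N = 14.

A planted in-phase oscillation (20 s period, 50% contiguous window) is
recovered at its true share when the planted spectral power is comparable
to the background noise power. The estimator's behaviour away from that
regime is worth knowing: when noise dominates, the surrogate threshold
truncates the detected window (under-estimation), and when the planted
tone dominates, spectral smoothing spreads significance beyond the window
(over-estimation). The recovery studies therefore plant the oscillation
at unit signal-to-noise.

## EGN emulation and emulative powers

The evolutionary-game-on-networks (EGN) stage models each normalized
network activity x_i in (0, 1) as a mixed strategy evolving by replicator
dynamics driven by pairwise emulation weights:

  dx_i/dt = x_i (1 - x_i) * sum_{j != i} a_ij (2 x_j - 1).

A positive a_ij means network i tends to copy network j's activity
(emulate), a negative one to oppose it. The published account of this
model defers its exact payoff parameterization to prior work; the
two-strategy coordination form above is adopted because it preserves
every property used downstream — directed pairwise weights, sign-coded
emulation, and dependence on the *rate of change* of activity — and
because the forward simulator and the fitter share one form, making
recovery studies internally valid.

Fitting: each channel is affinely mapped onto [0.05, 0.95] (replicator
dynamics are degenerate on the boundary), derivatives are estimated by
central differences with endpoints dropped, and each row of A is solved
by ridge-regularized least squares (relative penalty 1e-3) of the
derivative on the regressors x_i(1-x_i)(2x_j-1). Samples lying exactly on
the normalization boundary are excluded from that row's regression — the
replicator form does not hold where the forward model clips — unless too
few samples would remain.

Emulative powers: Out-EP_i = row sum of A (how strongly i emulates the
others), In-EP_j = column sum (how strongly j is emulated), Net-EP =
Out-EP - In-EP (sums to zero by construction). The printed formulas win
over ambiguous prose about "summing columns"; both orientations remain
one transpose away. Features `In-EP_*`, `Out-EP_*`, `Net-EP_*`: 42 for
N = 14.

A point about estimability discovered while validating the fitter and
worth stating plainly: the coordination replicator converges to pure
strategies, so with very weak perturbation the trajectory saturates, the
regressors lose persistent excitation (a near-deterministic trajectory is
a one-dimensional curve, leaving source regressors collinear), and sign
recovery *worsens* as noise decreases. Recovery is best at a moderate
perturbation — the studies use noise_sd = 0.02 per step on the unit state
range, where mean sign agreement across 50 random sparse 5-network
systems exceeds 0.9 — and degrades again once noise dominates the drift
(tested at 0.02 / 0.1 / 0.3).

## Permutation screening and the coherence reduction rules

Every feature is tested for a group difference with a two-sided
permutation test: statistic |mean(ACA) - mean(controls)|, p-value
(1 + #{permuted >= observed}) / (n_perm + 1) (minimum attainable
1/5001 at the default 5000 permutations), one shared set of label
permutations across features. Thresholding is at uncorrected p < 0.05,
mirroring the screening this pipeline reproduces; a Benjamini-Hochberg
option exists but is off by default. With ~2268 features this admits on
the order of a hundred false positives by construction — the classifier
benchmark, not the screen, is the arbiter.

The coherence features additionally pass three reduction rules: (i) drop
features that also differ significantly between the two sessions within
controls (an unstable feature is not a trustworthy group marker); then
keep a feature only if (ii) its pair is significant in at least two bands
or two phases, or (iii) its evidence is stronger (p < 0.01). A feature
survives iff it passes (i) and ((ii) or (iii)); the rule combination is
configurable because published descriptions of such filters are usually
elliptical.

## Classification benchmark

Four algorithms with out-of-the-box set-ups: SVM with Gaussian kernel and
median-heuristic bandwidth (reported experience in this literature is
that switching to polynomial kernels worsens results), LDA with pooled
covariance falling back to a shrinkage estimator when features outnumber
observations (unavoidable at ~100 features x 24 subjects), 1-nearest
neighbour, and an unpruned Gini CART. Features are z-scored by
training-fold statistics for SVM/LDA/KNN; trees consume raw values.
Five validation schemes: train-RS1/validate-RS2 and the reverse, LOOCV
within each session (24 folds), and LOOCV on the concatenated sessions
(48 folds, leaving out one observation, not one subject; the stricter
leave-one-subject-out variant is available as `loso_metrics()` but is not
one of the five benchmark schemes). Sensitivity is anchored to the ACA class; a
degenerate everyone-is-a-case predictor on 10-vs-14 scores accuracy
0.417, sensitivity 1.000, specificity 0.000, which the tests assert
exactly. Per algorithm, set-ups are ranked by mean accuracy over the five
schemes, ties broken by sensitivity then name. Greedy subset refinement
admits features either used by a fitted tree or involving a configured
network set (default DMN, DAN, SN) and accepts single add/remove steps
that improve the best average accuracy, under a bounded iteration count.

Null behaviour of this harness at n = 48 is not exactly 0.5 and users
should expect that: under subject-level label permutations the RBF SVM on
~150 screened features collapses to majority voting (accuracy 14/24 =
0.583 every time), while 1-NN and LDA show the well-known below-chance
LOOCV pessimism (~0.38-0.42). Individual permuted runs stay within
0.5 +/- 0.15 and the grand mean within 0.5 +/- 0.05, which is what the
acceptance tests assert.

## The synthetic cohorts

`gen_benchmark_dataset()` emulates the study geometry: 10 ACA + 14
control subjects, two sessions each, 14 networks, T = 208, dt = 2 s,
background AR(1) noise with coefficient 0.3 (BOLD-like autocorrelation at
a 2 s sampling interval). Three effects are planted in the ACA group,
chosen to exercise one metric family each and sized as moderate-to-large
group differences a well-powered biomarker study would present:

- DMN/DAN evolve by two-node replicator dynamics whose DAN-emulates-DMN
  weight is +0.4 in controls and -0.4 in ACA (the patients' DMN is
  non-emulated, so fitted In-EP_DMN separates groups);
- a 20 s in-phase oscillation shared by DMN and MVISU covers 20% of the
  record in controls and 60% in ACA (in-phase time-of-coherence in the
  16-32 s band separates groups, and the shared tone also moves sFC);
- AUDI receives lag-1 input from DMN with coefficient 0.5 in ACA only
  (directed GC separates groups).

Per-subject effect magnitudes are jittered by ~15% (stable across the two
sessions, so cross-session validation is meaningful); per-session streams
are derived from the master seed by a string-keyed hash, so adding
subjects never perturbs existing ones, and `effects = FALSE` produces
exchangeable groups for null calibration. Planted coherence windows are
contiguous so the planted fraction maps directly onto time-of-coherence.

What the generator does *not* emulate — and hence what green tests do not
show about real data: hemodynamic convolution and measurement filtering,
head-motion and physiological artifacts, spatial leakage between ICA
components, non-stationary background connectivity, and realistic
between-subject heterogeneity beyond the magnitude jitter. The benchmark
demonstrates that the estimators recover what was planted and that the
harness is leak-free; it does not certify clinical accuracy.

## Problem sizes and numerical choices

Recovery studies use the sizes at which their oracles are sharp: VAR
direction recovery and EGN sign recovery at T = 2000 (50 seeds each),
coherence calibration at T = 2000 with 300 surrogates, the end-to-end
benchmark at the full study geometry with 100 surrogates per threshold
and 5000 permutations. Thresholds, ridge penalties, and the 0.1 rounding
of the surrogate cache key are stated above next to their stages.
Degenerate inputs fail loudly and early: constant channels are named in
errors, unstable VAR coefficient sets report their spectral radius,
boundary replicator starts and eps outside (0, 0.5) are refused, and
tables with missing values cannot be written.

## Known limitations

- The EGN payoff form is a declared reconstruction (see above); absolute
  weight magnitudes are not calibrated against any external standard,
  only signs and group contrasts are validated.
- Spectral/state-space GC variants and significance testing of individual
  GC entries are out of scope; GC here is time-domain OLS.
- The greedy refinement is a bounded reconstruction of an exploratory
  search; it is audited (full trace) but not guaranteed to reproduce any
  particular published subset.
- MAT-file ingestion of deposited archives is not provided; cohorts enter
  as delimited text plus a CSV manifest.
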
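---
title: "Methods: population analysis of visual familiarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population analysis of visual familiarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popfam)
```

This vignette documents the models, thresholds and numerical choices
behind `popfam`, and what the synthetic-data generator does and does
not emulate. It is the place where genuinely open design decisions
are recorded.

## From fluorescence to activity

A recording holds three neurons × frames matrices: somatic
fluorescence `F`, surround (neuropil) fluorescence `Fneu`, and a
deconvolved-activity matrix. Neuropil contamination is removed as
`Fcorr = F − c·Fneu` with `c = 0.5`, the standard correction factor
for GCaMP somata whose measured contamination ratio spans roughly
0.3–0.7.

The baseline `F0` depends on the session type:

* **multistim** sessions (many interleaved stimuli, no long quiet
  stretch): `F0` is the mode of the `Fcorr` density. The mode is
  computed from a Gaussian KDE with Silverman's bandwidth on a
  512-point grid spanning the trace range, ties broken toward the
  smaller value. The KDE choice is ours; "mode of the density" does
  not itself fix an estimator. `F0` is taken over the whole session —
  whether a per-block baseline would differ is unresolved, and the
  whole-session reading is the simpler one.
* **plasticity** sessions (60 s gray, then one 100-s grating block):
  `F0` is the arithmetic mean of the 10 s immediately preceding
  stimulus onset.

`dF/F0 = (Fcorr − F0)/F0` is stored as a fraction throughout (0.05 ≡
"5%"); every percentage threshold is divided by 100 at the interface.
All thresholds are strict inequalities.

Spike events are frames whose deconvolved amplitude strictly exceeds
mean + 2 SD of that neuron's full trace (including zeros); a
zero-variance trace yields no events. The package never deconvolves —
deconvolution is an upstream tool stage, and the generator emits a
simulated deconvolved matrix (ground-truth spikes plus small Gaussian
jitter) instead.

Quality control keeps neurons with at least one dF/F0 peak above 10%
anywhere in the series; plasticity sessions additionally drop neurons
whose `F0` is more than 2 population SDs from the population mean,
and a session is flagged low-quality when the mean population dF/F0
to a novel stimulus is below 1%.

## Response classification

Responses are trial-averaged over all cycles of a stimulus. A neuron
is **active** for a stimulus when its mean stimulus-window dF/F0
exceeds the threshold *and* differs from the equally long gray window
immediately preceding the stimulus (two-sided paired t test across
trials of per-trial means, p < 0.05). The high threshold is a fixed
5%; the low threshold is 2 SDs of the baseline. Two under-determined
points are resolved as follows: the paired baseline is the per-trial
preceding-gray mean, and the baseline SD for the low threshold is
taken across frames of the trial-averaged preceding-gray trace (the
simplest reading; a per-trial SD would be systematically larger).
Classes are `active_high` (passes both thresholds), `weak`
(low-threshold only) and `nonresponsive`; requiring the high class to
pass the low criterion keeps the class hierarchy nested by
construction. With zero trial variance the t test is undefined: the
neuron is then classified by thresholds alone and flagged, except
when stimulus and gray are identical, which is nonresponsive.

Response magnitude is the trapezoidal AUC of the dF/F0 trace (dF/F0
· s), over 3 s for multistim and 10 s for plasticity windows.

## Functional connectivity

Two binary event trains of length `T` are functionally connected when
their observed coactive-frame count (i) is at least 1 and (ii)
strictly exceeds the nearest-rank 95th percentile of counts from
1,000 surrogates, each applying independent uniform circular shifts
in `[1, T−1]` to both trains. Requiring a minimum observed count of 1
prevents degenerate edges between silent neurons. Internally all
shifted counts are read off the circular cross-correlation of the two
trains (computed once by FFT), which is numerically identical to
shifting and counting; surrogate lags are then sampled from it.
Calibration on independent stationary trains yields a flag rate a
little below the nominal 5% (the count distribution is discrete, so
the strict cut is conservative).

The multistim graph is built over the entire imaging period;
plasticity graphs use only the first 10 s of stimulus frames. Node
degree summarises each neuron's connections; the degree-distribution
skewness is the Fisher–Pearson moment coefficient g₁ without bias
correction. Tuning similarity of connected versus non-connected pairs
uses the doubled-angle circular difference, which ranges over
[0, π/2] for orientations.

## Ensembles

Frames with at least 3 coactive neurons are retained. A frame without
another frame more than 50% Jaccard-similar is dropped (under single
linkage, a frame's first merge height is its nearest-neighbour
distance, so the rule is exactly "no partner above 0.5"). Surviving
frames are Ward-clustered on Jaccard distance and the tree is cut at
the number of clusters k ∈ 2..min(10, n−1) maximising a contrast
index

> contrast(k) = (mean within-cluster similarity − mean
> between-cluster similarity) / (sum of the two),

a stand-in for the source method's unspecified index. Because a
maximum over k has no parsimony penalty, a single coherent ensemble
can be fragmented; clusters whose mean cross-cluster similarity still
exceeds the 50% cut are therefore merged back. Frames excluded by the
Jaccard filter do not re-enter the ensemble frame vectors.

Membership uses the ensemble weight `W_j,ab = P_j,a · P_j,b · Co_ab`,
where `P` is the Pearson (phi) correlation of a binary train with the
ensemble's frame vector `V_j` over **all** frames and `Co` the
correlation between the trains. Surrogate weights come from
independent circular shifts of both trains with `V_j` fixed (the
surrogate scheme is unspecified upstream; circular shifts keep it
consistent with the connectivity test). Two gates were added after
the bare rule proved non-selective on planted data:

1. a candidate must have `P > 0` and above its own surrogate
   percentile — otherwise a strongly coupled pair that is jointly
   *anti*-correlated with `V_j` passes on the product's sign, and the
   weight test degenerates into a per-pair 5% lottery across all
   partners;
2. the pair must itself pass the coactivity connection test — a
   "functional connection within ensemble j" presupposes a functional
   connection.

A neuron belongs to an ensemble when it holds at least one such
connection; neurons can belong to zero, one or several ensembles.
Even with both gates the surrogate cut leaves an irreducible
few-percent false-membership rate per neuron, which matters when
interpreting membership counts in large populations.

## Population statistics

**Sparseness.** `S = [1 − (ΣRᵢ/n)²/(ΣRᵢ²/n)] / (1 − 1/n)` over the
response AUCs of all `n` identified neurons; 0 for uniform activity,
1 when a single neuron is active. Negative AUCs are clipped to 0
first — the formula assumes nonnegative responses and clipping
prevents S > 1 artifacts. An all-zero response vector is undefined
and returns `NA` with a warning.

**Selectivity.** The same functional without the `1 − 1/n`
normalisation, applied across the 13 trial-averaged deconvolved
frame amplitudes of a 3-s natural-image set (deconvolved amplitudes
avoid the slow calcium tail smearing frames together). Equal
amplitudes give 0; a single responsive frame gives 12/13.

**Orientation tuning.** Responses at 0°, 45°, 90°, 135° are fitted
with `f(φ) = A·e^{K(cos[2(φ−θ)]−1)} + b`. θ and K are initialised by
circular maximum likelihood on doubled angles, weighting each angle
by its baseline-subtracted response, then refined by least squares
with A and b profiled out linearly at every step. Pure
ML-then-linear-LS is not exact here: with four points and a nonzero
offset the weighted-resultant estimate of K is biased, while the
refined fit reproduces exactly generated curves to machine precision
(4 equations, 4 parameters). The profiled surface is multimodal in
(θ, K) and nearly flat in K at high concentration, so the optimiser
runs a small multi-start grid and finishes with a Nelder–Mead polish.
Fits explaining less than 70% of variance are marked invalid, as are
flat response vectors. `FWHM = arccos[ln(½e^K + ½e^−K)/K]` is
implemented exactly as printed (with a log-domain cosh for large K);
whether this width lives on the stimulus-angle or doubled-angle scale
is ambiguous in the source convention, and no reconciliation is
attempted — values are comparable across neurons either way.

**Overlap persistence.** Each frame's population vector is
unit-normalised; the overlap at lag ℓ is the mean dot product between
frames ℓ apart within the analysis window (stimulus onset to 10 s
after onset), for ℓ = 1..50. Zero-norm frames are excluded (their
normalisation is undefined). The curve is fitted with
`Overlap(t) = (1−b)·e^{τt} + b`, τ ≤ 0, 0 ≤ b ≤ 1, so the fitted
curve equals 1 at t = 0 by the functional form. Initialisation: b₀ =
min(curve), τ₀ from a log-linear regression of curve − b₀, clipped
into [−5, −10⁻³] (a flat curve yields a useless slope estimate).
Constant curves below 1 are degenerate: τ collapses to the
large-negative boundary with b absorbing the level, and the fit is
flagged.

**Plasticity ratios.** Post/pre-training ratios of: population AUC
over the first 10 s of stimulus, active-neuron fraction, high
responder fraction (> 15% dF/F0), mean node degree of active neurons,
and overlap decay τ. Zero pre-training denominators are flagged, not
divided. In plasticity sessions there are no repeated trials, so the
activity test pairs stimulus and preceding-gray frames frame-by-frame
over the 10-s windows.

## Behavior

Four corner sensors of a 42-cm force plate are sampled at 100 Hz.
The sensor voltages are smoothed with a centred 5-sample (50 ms)
moving average — the window length is not specified upstream and
50 ms is short relative to mouse locomotion — and the position is the
force-weighted centroid of the corner coordinates. Smoothing precedes
the centroid computation, following the order in which the steps are
described. Zero-total-force samples are interpolated from neighbours
and flagged. Paths are decimated to 2 Hz by 50-sample block means
(trailing partial blocks dropped), speeds are consecutive-sample
displacements times the rate, and exploration requires speed
≥ 3 cm/s (inclusive). The SZP index is the signed contrast of
exploration time between the stimulus half of the chamber and the
other half, divided by **total exploration time** (not total session
time — the two phrasings diverge and the methods-level definition is
used). Samples exactly on the midline count as non-stimulus zone,
the conservative choice for a familiarity (avoidance) effect. Zero
exploration leaves the index undefined and flagged.

## Synapse tables

Per dendrite, excitatory density counts PSD95⁺ spines plus dually
innervated spines (DIS carry PSD95) and inhibitory density counts
shaft gephyrin puncta plus DIS, both per 100 μm; whether DIS belong
in the excitatory density is not settled upstream, so the inclusive
definition is the default and `include_dis = FALSE` gives the
exclusive one. The E/I correlation is plain Pearson across dendrites;
two correlations are compared by Fisher's r-to-z. Puncta turnover
between sessions S1, S2 is gain = |S2∖S1|/|S2| and loss =
|S1∖S2|/|S1| on identity-matched puncta.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline
consumes, not the imaging physics:

* **schedule**: 30 s gray then 8 cycles of four 3-s gratings and two
  3-s natural-image sets (ten 0.3-s images each) in per-cycle
  shuffled order, each followed by 6 s gray, at 4.22 Hz (multistim);
  or 60 s gray plus one 100-s grating block (plasticity). Frame
  counts use `ceiling(duration × rate)` with half-open epochs, which
  reproduces 13 frames for 3 s at 4.22 Hz.
* **spiking**: Poisson per frame; gratings add a von Mises evoked
  rate, natural images multiply the baseline by per-image gains
  (constant within each 0.3-s image — the simplest structure that
  supports the selectivity index; real image responses are not
  documented, so the gain distribution is a free parameter, not a
  claim). Planted ensembles add co-events with configurable rate and
  participation.
* **fluorescence**: spikes convolved with a recursive exponential
  kernel (τ = 2 s default), scaled onto a per-neuron baseline with
  i.i.d. Gaussian noise; the neuropil channel is a shared slow
  background with per-neuron scale, and exactly half of that clean
  background leaks into the somatic channel so the 0.5 correction is
  consistent by construction (the additive-contamination assumption).
* **training**: post-sessions scale evoked rates, optionally scale
  the gain of the top quartile of neurons, and optionally smear
  evoked frames into geometric runs (mean run length = persistence
  factor).
* **defaults**: 80 neurons, baseline 0.05 events/s, 20% dF/F0 per
  spike, noise SD 1 a.u. — typical sparse layer-2/3 activity at this
  frame rate.

It does **not** emulate motion artifacts, biophysical calcium
dynamics, PSF or brightness heterogeneity, slow drift, or correlated
noise. Passing tests therefore demonstrate the correctness of the
computations and their behavior under the modelled statistics —
not robustness to imaging pathologies.

Dendrite tables come from a bivariate log-normal whose log-scale
correlation is analytically adjusted so the density-scale Pearson r
hits the target; the sample r at n = 2000 has Monte-Carlo SD ≈ 0.027.
Force-plate traces distribute a constant total force over the corner
sensors with bilinear weights, making the centroid formula recover
the scripted path exactly before smoothing.

## Determinism and problem sizes

All randomness flows through one seeded generator with fixed
per-stage offsets, so identical seeds give byte-identical recordings,
graphs and reports. The test suite runs planted-structure recovery at
30–60 neurons and ~2,000 frames, surrogate calibration at 500 pairs ×
1,000 frames × 1,000 shifts, and parameter recovery on 50-lag decay
curves — sizes chosen so the full suite completes in well under a
minute while keeping every statistical check adequately powered.

## Known limitations

* Group-level inferential statistics (ANOVAs, KS tests, etc.) are
  reporting steps delegated to standard routines, not re-derived.
* The contrast index and the ensemble-membership gates are this
  package's own resolutions of under-specified steps; both are
  documented above and their planted-data behavior is tested.
* The surrogate membership test retains a few-percent per-neuron
  false-positive rate by construction of the 95th-percentile rule.
* Animal-level numbers from the original study are not reproducible
  without the raw data; the pipeline is validated on analytic
  extremes and synthetic ground truth instead.
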
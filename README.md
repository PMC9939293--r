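# popfam

Population-coding analysis of visual familiarity from two-photon
calcium imaging in mouse visual cortex.

Repeated exposure to a visual stimulus reshapes how a cortical
population represents it: response magnitudes shrink, activity
concentrates on fewer neurons, and the moment-to-moment stability of
the population vector changes. `popfam` implements the full analysis
chain used to quantify these effects from raw fluorescence to
population statistics, for labs analysing GCaMP recordings acquired
during grating / natural-image protocols, together with the
behavioral (force-plate) and anatomical (dendritic synapse-count)
measures that accompany such studies. A synthetic-data generator with
known ground truth makes every stage testable end to end without any
raw imaging data.

## What it computes

**Preprocessing** — neuropil-corrected fluorescence
`Fcorr = F − 0.5·Fneu`, baseline `F0` (mode of the `Fcorr` density, or
the 10-s pre-stimulus mean for single-stimulus plasticity sessions),
`dF/F0 = (Fcorr − F0)/F0`, spike events from deconvolved activity
thresholded at mean + 2 SD, and ROI quality filters (≥ one peak
> 10% dF/F0; population-level F0 outlier removal).

**Functional connectivity** — neurons *a*, *b* are connected when
their coactive-frame count exceeds the 95th percentile of counts from
1,000 random circular shifts of both binary trains; the graph's node
degrees and their Fisher–Pearson skewness g₁ summarise hub structure.

**Ensembles** — imaging frames with ≥ 3 coactive neurons are
clustered (frames without a > 50% Jaccard-similar partner dropped;
Ward linkage on Jaccard distance, contrast-index cut). Neuron
membership uses the ensemble weight `W_j,ab = P_j,a · P_j,b · Co_ab`
tested against circular-shift surrogates.

**Population statistics**

- sparseness `S = [1 − (ΣRᵢ/n)²/(ΣRᵢ²/n)] / (1 − 1/n)` over per-neuron
  response AUCs (0 = uniform activity, 1 = one active neuron);
- natural-image selectivity `SI = 1 − (ΣRᵢ/n)²/(ΣRᵢ²/n)` over the 13
  trial-averaged deconvolved frame amplitudes of a 3-s image set;
- orientation tuning by the von Mises model
  `f(φ) = A·e^{K(cos[2(φ−θ)]−1)} + b` with
  `FWHM = arccos[ln(½e^K + ½e^−K)/K]`, fits kept at R² ≥ 0.7;
- population-vector overlap (dot products of unit-normalised activity
  vectors at frame lags 1–50) fitted with
  `Overlap(t) = (1−b)·e^{τt} + b`;
- post/pre-training plasticity ratios of AUC, active fraction, high
  responders, node degree and τ.

**Behavior** — position from four force-plate sensors by the
force-weighted centroid of the 42-cm plate corners, 100 → 2 Hz block
decimation, exploration at ≥ 3 cm/s, and the stimulus-zone-preference
index `SZP = (t_SZ − t_NSZ)/(t_SZ + t_NSZ)`.

**Synapses** — per-dendrite excitatory/inhibitory densities per
100 μm, E/I ratio, Pearson E/I correlation with Fisher r-to-z
comparison between groups, and fractional gain/loss of gephyrin
puncta across sessions.

## Worked example

```r
library(popfam)
cfg <- synth_config(seed = 42, n_neurons = 60,
                    ensemble_spec = list(list(members = 1:12, rate = 0.15,
                                              participation = 0.9)))
sim <- generate_population(cfg)
report <- run_pipeline(sim$recording, "multistim",
                       pipeline_config(n_shifts = 1000, seed = 1))
```

This simulates a 60-neuron multistim session (30 s gray, then 8
shuffled cycles of four gratings and two natural-image sets at
4.22 Hz) with a planted 12-neuron ensemble, and runs the full
pipeline. The run prints:

```
kept neurons: 60
active fraction: 0.95
  grating_0        ni_1        ni_2 grating_135  grating_45  grating_90
      0.303       0.469       0.334       0.425       0.390       0.412
<functional_graph> 60 nodes, 494 edges, mean degree 16.47, skewness 0.419
<ensemble_set> 7 ensemble(s) over 97 similar frames; 31 member neuron(s)
<tuning_fit> theta = 157.8 deg, K = 16.696, A = 39.2617, b = 0.3332
  R2 = 0.916 (valid), FWHM = 16.6 deg
```

`active fraction` is the share of identified neurons significantly
responsive to at least one stimulus; the named vector is the
population sparseness per stimulus (low values: activity spread over
many neurons); the graph line shows the surrogate-calibrated
coactivity network and its degree skew (positive = a few hub
neurons); the tuning fit is neuron 1's orientation preference with
its tuning width.

## Command line

A thin CLI over the same functions lives at `inst/cli/popfam.R`:

```sh
Rscript inst/cli/popfam.R simulate --seed 7 --mode multistim --out rec/
Rscript inst/cli/popfam.R run --in rec/ --mode multistim --seed 1 --out out/
```
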
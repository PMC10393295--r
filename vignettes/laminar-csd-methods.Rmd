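---
title: "Methods: laminar CSD patterns, transport distances, and a desk-scale forward model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar CSD patterns, transport distances, and a desk-scale forward model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamcsd)
```

## What this package computes

`lamcsd` quantifies visually evoked laminar activity in a cortical column
from two complementary observables: the current source density (CSD)
estimated from multichannel local field potentials (LFP), and population
firing rates from sorted units. Its statistics answer three questions:

1. What is the *canonical* evoked CSD pattern across a cohort of animals,
   and how variable are animals (and trials) around it?
2. How far is a given pattern -- another animal's, or a model's -- from the
   canonical one, measured as a transport (earth mover's) distance on the
   depth-time plane?
3. Do a model's firing rates fall within the cohort's variability, assessed
   by Kolmogorov-Smirnov similarity of per-cell rate distributions and by
   correlation of population rate time courses?

A synthetic-data module generates complete surrogate cohorts (LFP, spikes,
QC metadata, thalamic input pools), so every downstream stage is testable
without any recordings. A small laminar rate network with depth-resolved
synapse placement serves as a testbed for circuit-level manipulations
(placement flips, weight scaling, ablations, feedback switching).

## The delta inverse-CSD model

Each electrode at depth $z_i$ is treated as the centre of a disc of
laterally constant planar CSD with radius $R$. The on-axis potential of
such a disc at distance $h$ gives the forward matrix

$$F_{ij} = \frac{1}{2\sigma}\left(\sqrt{(z_i - z_j)^2 + R^2}
  - |z_i - z_j|\right),$$

so that $\mathrm{LFP}(t) = F\,\mathrm{CSD}(t)$ column-wise, and the delta
inverse-CSD estimate is the direct solve of that system. Parameters:

* `R` -- the lateral radius. Two conventional contexts are provided:
  400 um when analysing model output (the radius within which the model's
  sources live) and 800 um for experimental recordings (roughly the extent
  of mouse V1).
* `sigma` -- extracellular conductivity, default 0.3 S/m. No published
  value is attached to the original analysis; because all pattern
  comparisons are amplitude-normalized, `sigma` rescales amplitudes only
  and never affects a normalized pattern (this is asserted by a test).
* The estimate is reported as planar (sheet) CSD per electrode. No spatial
  smoothing is applied after inversion.
* A condition-number guard (default bound `1e10`) turns silently
  ill-conditioned solves into explicit `numerical-failure` errors.

## Preprocessing

* Zero-phase (forward-backward) Butterworth low-pass, order 5, cutoff
  500 Hz. The filter is designed by bilinear transform of the analog
  prototype; forward-backward application gives amplitude $1/2$ at the
  cutoff (asserted to within 0.01). Edges are handled by odd-reflection
  padding of three filter orders with step steady-state initialisation.
* Spatial downsampling keeps every other electrode of a 20 um-pitch probe
  (40 um target pitch), starting from the deepest channel.
* Trial averaging over a window of -250 to +100 ms around flash onset,
  followed by subtraction of each channel's pre-stimulus baseline mean.
  The evoked-response figures in the source analyses do not state whether
  a baseline was subtracted; subtraction is the default here and can be
  switched off. Filtering before averaging is a fixed (but mathematically
  irrelevant) order choice: both operations are linear and commute, which
  is covered by a test.
* The analysis window for pattern comparison is 0-100 ms after onset;
  patterns are bilinearly regridded onto M = 30 depths x K = 100 time
  points and flattened depth-major to length-3000 vectors.

## The Wasserstein distance between CSD patterns

Sinks (negative values, sign-flipped) and sources (positive values) are
normalized *separately* to total mass 1, so distances reflect pattern, not
amplitude. The first Wasserstein distance is computed between the sink
masses and between the source masses, and the two costs are summed.

Numerical choices:

* Ground metric: Euclidean distance in grid-index units -- one step of the
  30-point depth axis costs the same as one step of the 100-point time
  axis. The relative cost of space vs time is therefore set by the grid
  resolution; an anisotropy factor (`depth_weight`, `time_weight`) is
  exposed for sensitivity analyses.
* The transportation problem is solved *exactly* by a bipartite network
  simplex written for this package (partial pricing, subtree-size-aware
  potential updates). Because the ground cost is a metric, the distance
  depends only on the signed difference of the two masses; the solver
  therefore transports $(a-b)^+$ to $(b-a)^+$, which is exact and roughly
  halves the problem. Tests pin the solver against an independent
  successive-shortest-paths oracle and a closed-form 1-D identity.
* Mass below `1e-12` is dropped before the solve and the remainder is
  rescaled to the original total (amplitude-preserving re-normalization).
* Patterns without both polarities raise a `degenerate-pattern` error
  rather than returning a sentinel; sliced or entropic approximations are
  deliberately not used anywhere.

Useful calibration: rigidly shifting an interior-supported pattern by $k$
time bins moves each unit mass (one sink, one source) by exactly $k$, so
the total distance is $2k$ -- the distance scales linearly with shifts in
space and time.

## Canonical pattern

The cohort matrix (animals x 3000) undergoes feature-wise mean-centred
PCA; the first principal component, reshaped to the grid, is the canonical
pattern. Centring is the standard PCA convention and is an assumption
here (the source analyses do not state it). The component's sign is fixed
by requiring nonnegative correlation with the cohort mean pattern; its
flattened norm is 1. The plain cohort average is provided as the
alternative summary. No per-animal amplitude normalization is applied
before PCA.

## Spiking statistics

* RS/FS classification by trough-to-peak waveform duration: FS iff
  duration < 0.4 ms in cortex (V1, LM) or < 0.3 ms in LGN. A duration
  exactly at the cutoff classifies RS (tie-break chosen here; the rule's
  source is silent).
* Population rates: 1 ms bins, spike counts averaged over units and
  trials, converted to spikes/s, Gaussian-smoothed with sigma = 2 bins
  (truncation 4 sigma, reflecting boundaries). Smoothing preserves the
  integral away from edges (tested).
* Windows: baseline [-250, 0) ms, initial peak [35, 60) ms, sustained
  [60, 100) ms.
* KS similarity = 1 minus the two-sample KS statistic between per-cell
  mean-rate distributions (asymptotic variant); correlation = Pearson r
  between population rate time courses over 0-100 ms.
* Leave-one-out cohort comparison requires at least 10 cells per animal
  and population (RS per layer, FS pooled across layers); under-threshold
  entries are skipped and logged.
* Outlier assessment of a model score uses Tukey whiskers (most extreme
  cohort points within 1.5 IQR of the quartiles); the verdict against the
  raw min-max range is reported alongside, since the informal "within the
  boxplot range" criterion is ambiguous between the two.
* Unit-level features (peak rate, peak latency, maximum curvature = the
  largest second finite difference of the smoothed rate in 0-100 ms; no
  published formula exists for the curvature, so the discrete second
  difference is this package's definition) are summarized by plain
  (bias-uncorrected) moment estimators: mean, SD, skewness
  $m_3/m_2^{3/2}$, excess kurtosis $m_4/m_2^2 - 3$. Constant samples
  yield NaN higher moments with a warning.

## The synthetic world

The generator's defaults are a *stated world*, fixed once:

* Cohort: 58 animals, of which 5 lack a V1 LFP recording, 9 have
  unrecoverable probe locations, and 2 have no V1 units; the three flag
  sets are disjoint by default because the published retention counts are
  additive (58 - 9 - 5 = 44 for CSD, 58 - 9 - 2 = 47 for spikes). An
  overlap option exists for stress tests only. 75 flash trials per animal.
* The canonical pattern is the sum of four spatio-temporal Gaussian
  components (an early transient L4 sink near 40 ms, a sustained L4
  source from ~60 ms, a sustained deep L5/6 sink from ~50 ms, and a
  sustained superficial L2/3 sink from ~60 ms). Only qualitative timing
  and laminar anchors are published, so depths, widths and amplitudes are
  free configuration values stored in a versioned CSV
  (`inst/extdata/canonical_components.csv`), not hard-coded.
* Per-animal variability: latency jitter SD 4 ms, depth jitter SD 20 um,
  and a global response-gain CV of 0.5 (plus a per-component wobble of a
  third of that). These values were calibrated once so that the cohort
  reproduces the published phenomenology that the first principal
  component explains roughly half the variance and visually matches the
  canonical pattern; with independent per-component amplitudes instead,
  PC 1 degenerates into a component-contrast mode, which is not what is
  observed.
* Trial noise: amplitude 0.003 (the RMS of the canonical evoked LFP, i.e.
  single-trial SNR near 1) of *spatially smooth* noise (Gaussian spatial
  correlation, 150 um length) plus 10% white electrode noise, and a
  20 ms-period gamma oscillation (sinusoid, random phase per trial,
  depth envelope over the supragranular band). Spatial smoothness matters:
  the delta-iCSD inverse amplifies spatially white noise catastrophically,
  whereas volume-conducted biological noise is smooth across a 20 um-pitch
  probe and inverts gracefully. The published observation that the
  oscillation is sometimes "interrupted" is not modelled.
* Spikes: inhomogeneous Poisson with trapezoid rate profiles
  (baseline -> linear rise from 20 ms -> peak -> sustained plateau ->
  offset at 250 ms), 0.1 ms spike-time resolution, independent trials
  under a per-animal/per-trial seed ladder. Waveform durations are drawn
  from two Gaussians (modes 0.55 / 0.25 ms in cortex, SD 0.05 ms) so the
  0.4 ms cutoff recovers the intended class for the bulk of units; the
  LGN pool template uses a 0.45 ms RS mode relative to the 0.3 ms cutoff.
  The default FS baseline (8 spikes/s) is more than twice every RS
  baseline.
* The LGN input pool holds exactly `n_units x n_trials_recorded` trains
  (1263 x 75 = 94,725 at the published scale); assignment splits the pool
  into 10 subsets and samples with replacement, one subset per simulated
  trial, until all target units (17,400 at scale) carry a train in every
  trial.

What a green test does *not* establish: the generator emulates uniform
20 um probe geometry only, no per-animal channel dropout or probe angle,
no realistic waveform shapes, no behavioural-state dependence, and trial
noise that is stationary within a trial. Conclusions about those aspects
of real data are out of reach of this test world.

## The laminar forward model

Populations are threshold-linear rate units (one excitatory and one
inhibitory per layer 2/3-6) with soma depths and dendritic extents on a
0-860 um column:

$$\tau \dot r = -r + \left[\textstyle\sum w \cdot \alpha \cdot r_{\rm pre}
  + \mathrm{ext}\right]_+, \qquad \tau = 10\ \mathrm{ms}.$$

Every projection deposits its presynaptic current $w\,r_{\rm pre}$ as an
inward current over a truncated-Gaussian placement kernel and an equal
return current over a soma-centred kernel (SD 30 um), with polarity
reversed for inhibitory sources. Kernels are normalized on the discrete
depth grid, so the depth integral of the total CSD is zero at every step
*by construction* -- the discrete counterpart of membrane-current
conservation.

The factor $\alpha$ attenuates the *drive* by `attenuation^(d/100 um)`
(default 0.9) with `d` the mean placement-to-soma distance -- but never
the deposited current. This asymmetry is the mechanism behind the
placement/weight dissociation: moving synapses between basal and apical
kernels relocates sinks (large normalized-CSD change) while barely
changing rates, whereas weight scaling drives rates strongly while the
normalized pattern, dominated by the placement geometry, moves little.
The default network expresses this with a factor >2 margin in both
directions for recurrent weight factors in {0.5, 2}.

Connectivity follows the published placement rules in caricature: LGN
onto L4 (and weakly L6) basal+apical within 150 um, perisomatic
inhibition (within 50 um), L2/3- and L4-targeted excitation within
200 um, free placement on L5/L6 targets, and optional feedback onto L2/3
apical dendrites (within 150 um), L5 apical tufts (>300 um) plus basal
dendrites, and L2/3 / L5 interneurons. Three presets name the published
model configurations qualitatively: `original` (no feedback),
`intermediate` (no feedback; excitatory-to-inhibitory weights scaled down
30%, inhibition compensated up), `final` (feedback on; background drive
to feedback-targeted populations scaled by 0.35, within the published
[0.2, 0.5] range; excitatory synapses onto L6 excitatory cells restricted
to within 150 um of the soma). The published feedback weight-factor range
is stated inconsistently in two places ([0.05, 0.5] vs [0.2, 0.5]); the
presets follow the methods-section range [0.2, 0.5]. On a matched
synthetic cohort the `final` preset lands closer to the cohort's PC 1
than `original`, reproducing the published ordering qualitatively.

An optional somatic "active return" term (an extra soma-centred deposit
proportional to the population rate) caricatures active-conductance
return currents; it is off by default and makes no claim to biophysics.
Everything else about the published 230,924-neuron simulation --
multicompartment cables, spiking, channel kinetics -- is explicitly out
of scope; rate dynamics, time constants, kernel widths and weights are
this package's own plumbing, chosen for stability (loop gains below 1 at
twice the default recurrent weights) and qualitative laminar realism.

## Determinism, tolerances, degenerate inputs

* All generators consume explicit seeds; a master seed derives one child
  seed per animal/stage (all below 2^31). Fixed seed implies
  byte-identical artifacts, including the pipeline's `summary.json`.
* Transport solves are exact up to a pricing tolerance of
  `1e-11 x max cost`; round trips of the disc operator hold to 1e-8
  relative error; conservation in the rate model holds to float
  precision.
* Degenerate inputs fail loudly with classed conditions
  (`lamcsd_invalid_argument`, `lamcsd_degenerate_pattern`,
  `lamcsd_numerical_failure`, `lamcsd_undefined_correlation`), never with
  sentinel values.

## Known limitations

* The exact transport solve on full 30 x 100 patterns costs of order a
  second per pattern pair on one CPU; cohort-scale all-pairs analyses are
  minutes, not seconds. No approximate solver is silently substituted.
* The delta-iCSD inverse assumes laterally constant CSD within radius R
  and a homogeneous, isotropic medium.
* The rate model's evaluation against a synthetic cohort tests the
  *machinery* (distances, similarity scores, verdicts), not biological
  fidelity of the model itself.
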
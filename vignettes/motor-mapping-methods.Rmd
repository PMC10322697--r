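---
title: "Motor mapping from depth-electrode recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor mapping from depth-electrode recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

motormapr maps movement representations from stereo-EEG (sEEG) depth
electrodes recorded during a block-designed motor task: interleaved hand,
tongue and foot movements (20 cues each, 3 s move / 3 s rest) with surface
EMG on each effector. This vignette explains the models behind each stage,
the tunable parameters, and the choices made where the design was genuinely
open. Everything quantitative claimed here is computed by the package's test
suite or by `scripts/acceptance.R`; nothing is asserted from memory.

## The measurement model

Two electrophysiological signatures distinguish motor from non-motor tissue
in the electrical potential near an electrode contact:

* a **broadband high-frequency power increase** (captured at 65–115 Hz, a
  range above most oscillations that also avoids the 60/120 Hz line-noise
  harmonics), a correlate of local population firing rate; and
* a **10–30 Hz (beta) oscillatory power decrease** during movement.

All analysis happens on **bipolar pairs**: adjacent contacts (1.5 mm apart,
same lead segment) are differenced, which removes reference and common-mode
signals exactly and localises the measurement between the two contacts. Pair
positions are the contact midpoints. `bipolar_rereference()` never pairs
across segment boundaries of segmented leads.

Movement timing comes from the muscle, not the screen:
`emg_epochs()` re-times each cue to the onset/offset of the conditioned EMG
envelope of that effector. The coarse gate is a baseline mean + 3 sd
threshold sustained for 200 ms; the fine estimate is the half-maximum
crossing of the linear (rectified, Gaussian-smoothed) envelope, which a
symmetric smoother does not bias. Manual annotation in the original clinical
workflow has no numeric definition, so this automated surrogate is a design
choice; both the threshold multiple and the minimum duration are arguments.
An effector without an EMG channel falls back to cue timing shifted by the
mean cue-to-EMG delay of the detected effectors.

## Trial spectra and the signed r² statistic

`trial_psd()` computes a Welch PSD per epoch per pair (1 Hz bins from 1 to
300 Hz, 1 s Hann windows, 0.5 s overlap, constant detrend per window — the
detrend flavour is unstated in the source method and chosen here), then
divides each trial's PSD bin-wise by the channel's global mean PSD across
all trials. The normalization removes the 1/f shape that otherwise dominates
any band average. `band_power()` averages the normalized PSD over 65–115 Hz
(inclusive; the band edges exclude 60 and 120 Hz by construction, so no
interior bin masking is needed).

`signed_r2(m, r)` measures movement-versus-rest contrast:

    r² = sign(m̄ − r̄) · (m̄ − r̄)² · N_m N_r / (σ²_{m∪r} · N²_{m∪r})

with σ² the *population* (divide-by-N) variance of the pooled samples. That
convention makes the statistic exactly the squared point-biserial
correlation between samples and group label, signed by the mean difference,
and bounds it in [−1, 1]; the sample-variance alternative breaks both
properties, which is why population variance was chosen. Each movement is
compared only against the rest epochs *that followed that same movement
type*, so the post-movement beta rebound contaminates both sides equally.
P-values come from an unpaired two-sample t-test; the pooled-variance
(Student) flavour is used — the source method does not specify, and the
package's null-calibration test shows the type-I error at nominal 0.05 stays
within 0.07 under the generator's null channels either way.

## Somatotopy and shared representation

`somatotopy_vector()` forms, per channel, the complex sum
r²_H·e^{iπ/6} + r²_T·e^{i5π/6} + r²_F·e^{i3π/2} after clipping negative r²
at zero. The three basis vectors are 120° apart, so a channel equally active
for all three movements cancels to zero magnitude — selectivity and shared
activity are thereby decoupled. `shared_overlap()` scores shared
representation as the geometric mean ∛(r²_H·r²_T·r²_F), with any
non-significant movement (p ≥ 0.05) contributing zero. No multiple-testing
correction is applied to the overlap gate (correction enters only in
decoding channel selection); `threshold_maps()` implements both display
cutoffs — 50% of the within-session maximum for the somatotopy and overlap
maps, and 1% of the per-movement maximum r² for single-movement maps. The
two cutoffs serve different displays and are deliberately not reconciled.

## Broadband timecourses and brain–EMG latency

`broadband_timecourse()` band-passes each pair in five 10 Hz bands from 65
to 115 Hz (third-order Butterworth, zero-phase), squares the Hilbert
analytic amplitude of each band, and sums. Summing narrow-band envelopes
rather than filtering once broadly flattens the 1/f weighting across the
band. The summed power is then logged (floored at the 1st percentile of
positive values to guard log 0), z-scored over the whole run, smoothed with
a Gaussian kernel (sd 50 ms — the kernel and width are unstated in the
source method and exposed as an argument), exponentiated, and centered by
subtracting 1. The z-score step pins the geometric-mean power at output 0;
because exponentiation is convex the arithmetic mean sits slightly above 0,
which is why the tests check `mean(log(1+x)) ≈ 0` rather than `mean(x) ≈ 0`.
Zero-phase filtering matters: a causal filter's group delay would bias every
latency estimate.

Two numerical guards exist because of line noise: band-pass filters ring on
the phase discontinuity that reflection padding creates in a sinusoid,
producing large power transients at the run edges. The band-passed signals
are therefore edge-tapered (1 s raised cosine) before the Hilbert step, and
`estimate_latency()` trims 2 s from both ends of the run before the dot
product (both knobs are arguments).

`condition_emg()` implements the EMG chain: 25–400 Hz band-pass, notches at
60/120/180 Hz, rectification, envelope smoothing, then log/z-score/smooth/
exponentiate. The stated order of "enveloped and rectified" is ambiguous; we
rectify first, then envelope — the reverse would discard the rectified
carrier before any envelope exists. `output = "linear"` stops after the
envelope: that series is what both burst detection and latency use, because
the exp-domain normalization widens bursts asymmetrically (the half-maximum
of a convex transform of a smoothed step is not at the step center), which
in development produced a flat, bimodal correlation apex.

`estimate_latency()` slides one series against the other over ±2 s in
one-sample steps and reports the peak of the dot product of mean-subtracted
series (windows are per-run; per-trial windows are possible by epoching
first). Positive lag means brain precedes EMG; peaks at the lag boundary are
flagged unreliable. The sign convention is fixed by a test: a copy delayed
by k samples recovers exactly +k samples.

## Cluster-count selection

`build_feature_space()` places each channel at its signed r² for foot, hand
and tongue (axes in that order, negatives kept — unlike the maps). k-means
(Lloyd, k-means++ seeding, 300 iterations; none of these specified by the
source method) runs for k = 1…20 across 1,000 random restarts. Per restart,
the selected k minimizes k^α · E(k) where **E(k) is the sum of Euclidean
distances** of channels to their assigned centroids; the final k is the mode
across restarts (ties toward fewer clusters) and the reported labels come
from the best restart at that k.

The unsquared distance is load-bearing. For any 3-D point cloud the optimal
*squared*-error k-means cost decays like k^(−2/3), faster than k^(1/2)
grows, so a √k·SSE penalty has no interior minimum and the mode degenerates
to k_max on every geometry we simulated. With unsquared distances the cost
decays like k^(−1/3) and the α = ½ penalty grows like k^(1/6), giving a
well-defined optimum. Larger α always selects no more clusters (for a fixed
error curve, argmin k^α·E(k) is non-increasing in α): α = 2 collapses to one
or two clusters, α = ½ recovers planted structure.

Sample size matters too: with a single session's ~66 channels, k = 20 leaves
~3 points per cluster and the empirical error collapses toward zero, so
selection degenerates regardless of penalty. The cluster-count experiments
therefore pool channel statistics from four generated sessions (~264
channels), the same design multi-subject analyses use when they pool
channels across subjects; selection is seed-stable from roughly 200 channels
upward in our simulations. `label_clusters()` then names clusters from
centroid geometry: near origin → inactive; balanced positive → shared
representation (RMA); balanced negative → suppressed (the widespread
low-frequency decrease); single dominant positive axis → that effector.

`depth_from_hull()` supports the depth analyses: it enumerates convex-hull
facets by brute force (every triplet whose plane has all points on one side)
and returns exact point-to-triangle distances, so electrode depth below a
cortical-surface hull is a one-liner.

## Movement decoding

`select_decoding_channels()` groups channels by their three movement
p-values: all three < 0.05 → shared (rma); exactly one < 0.05/3 (Bonferroni
for three movements) → somatotopic; two significant, or none → excluded.
`decode_movements()` fits four-class (hand/tongue/foot/rest) linear
discriminant analysis with pooled covariance, stratified three-fold
cross-validation (stratification is our addition — it prevents empty-class
folds at 20 trials per class; fold assignment is seed-deterministic).
Features are per-trial 65–115 Hz normalized band power, one scalar per
channel (per-frequency vectors would also be possible; the scalar matches
how the statistic stage uses the band). Accuracy is reported over all test
trials and over movement trials only, the latter scored from the same fitted
four-class models — never retrained on three classes, where the covariance
would be underdetermined. If the pooled covariance is singular (constant
features), a diagonal-shrinkage Gaussian classifier substitutes, with a
message.

## The synthetic session generator

`synthesize_session()` provides ground-truth-labelled data with the
statistical structure the analysis assumes. Per analysis channel it sums
three independent 1/f^2-shaped noise streams — 10–30 Hz, 65–115 Hz, and the
spectral remainder — so band gains can be modulated independently and
exactly: during a channel's responsive movements the broadband stream's
amplitude is scaled to multiply band power by `g_bb` (default 3) and the
beta stream by `g_beta` (default 0.5), cross-faded with 100 ms raised-cosine
ramps to avoid spectral clicks. Channels come in five classes
(10/10/10 somatotopic per effector, 6 RMA, 30 inactive). Brain modulation
leads EMG onset by `tau_s` (default 100 ms); EMG onsets lag cues by a
150 ± 50 ms reaction delay. Line noise sits at 60/120/180 Hz; every contact
of a lead shares a 7 Hz common-mode sinusoid that bipolar rereferencing must
cancel; contacts come two per segment so each differential pair carries one
labelled channel.

Free parameters the source conditions do not state, fixed once here:

* **Effect sizes** `g_bb = 3`, `g_beta = 0.5` — broadband movement responses
  of motor cortex are severalfold; beta suppression is partial.
* **Response heterogeneity** `gain_sd = 0.2` (log-scale sd of the
  per-channel, per-movement gain): real shared-representation sites respond
  to all movements with *unequal* amplitudes. Exactly equal gains would be a
  degenerate symmetric case in which RMA channels carry no between-movement
  information at all.
* **Reaction delay** 150 ms mean, 50 ms jitter sd — a realistic cue-to-EMG
  latency for simple cued movements.

The `beta_only` preset models the widespread, effector-nonspecific
low-frequency regime: no broadband change (`g_bb = 1`) and beta suppression
during *every* movement on every non-inactive channel. Its 8–32 Hz feature
space has two natural groups (suppressed everywhere vs inactive), which is
what the two-cluster result checks.

What the generator does **not** emulate: volume conduction and spatial
correlation between neighbouring pairs, non-stationary baselines, artifacts
and seizure activity, heavy-tailed single-trial broadband variability, and
imaging geometry. Passing tests therefore demonstrate that the pipeline
recovers planted structure under its own model assumptions — not that it is
robust to everything clinical data contains.

## Problem sizes and determinism

The test suite and the acceptance script run everything at the study's trial
structure (20 × 3 movements × 3 s + rests, 1,200 Hz). Sizes chosen for the
heavier experiments: four pooled sessions per cluster-count run (~264
channels); 20 seeds for the 100 ms latency recovery and 8 for the 0 ms
control, each on a 3-channel session; three 112-channel null sessions
(1,008 channel × movement tests) for t-test calibration. Every stochastic
step (generation, k-means restarts, fold assignment) takes an explicit seed,
and the pipeline writes bit-identical TSV artifacts when rerun with the same
configuration — which is itself one of the acceptance checks.
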
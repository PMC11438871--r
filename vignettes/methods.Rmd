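---
title: "Models, statistics and design choices in hipposeq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, statistics and design choices in hipposeq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hipposeq analyzes hippocampal population recordings from rodents running
linear tracks: place coding during movement, and the re-expression of
spatial trajectories in brief population bursts ("frames") during sleep and
awake rest. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the choices we made where the design was genuinely open.

## The decoding model

All trajectory analyses rest on a memoryless Bayesian decoder. Each unit is
assumed Poisson with a position-dependent rate $f_i(x)$ (its tuning curve,
binned at 1 cm and smoothed with a 5-cm SD Gaussian), and units are assumed
conditionally independent given position. For a time bin of width $\tau$
with spike counts $sp_i$,

$$\Pr(x \mid spk) \propto \Pr(x)\prod_i f_i(x)^{sp_i}
  \exp\!\Big(-\tau \sum_i f_i(x)\Big),$$

with a uniform prior over track locations, computed in the log domain and
row-normalized. Only units with at least 10 run spikes (and, by default, a
peak rate above 1 Hz) enter the model; each running direction is decoded with
its own model, never pooled. Two numerical choices deserve note:

* **Rate floor.** A floor of 0.01 Hz is added to $f_i$ before taking logs so
  a single stray spike from a silent unit cannot veto an entire spatial bin.
  The floor is configurable and set to 0 in the oracle tests, where the
  log-domain implementation is checked against a direct per-bin product to
  $10^{-9}$.
* **Point estimate.** The decoded location of a bin is the posterior argmax,
  ties broken toward the lower bin index. Run decoding error is the median
  absolute error over non-overlapping 0.5-s movement bins (speed
  > 10 cm/s), and its null distribution comes from 500 permutations of the
  decoded bins in time — for uniform occupancy that null median sits near
  $L/3 \approx 33$ cm on a 1-m track.

## Trajectory-sequence statistics

A frame decoded in 20-ms bins yields a $T \times L$ posterior. Its
sequential content is the **weighted correlation**: the product-moment
correlation between time-bin index and location, weighted by the posterior
probabilities. The null is the **within-frame time-bin permutation**: rows
of the posterior are shuffled in time, conserving each bin's decoded content
exactly while destroying only the order. A frame is a significant forward
(reverse) sequence when $r$ exceeds the 97.5th (falls below the 2.5th)
percentile of 500 such shuffles; the **sequence score**
$r_Z = (|r| - \overline{|r_{shuf}|}) / sd(|r_{shuf}|)$ gives a
shuffle-normalized magnitude. Because posterior rows each sum to one, a
permutation changes only the pairing of per-row location means with times;
the implementation exploits this for an $O(T)$ per-shuffle cost and the test
suite verifies exact agreement with full recomputation.

Degenerate frames — zero weighted variance in space or time, or posteriors
whose rows are all identical (a uniform posterior is the extreme case) — are
flagged and counted non-significant: a row-identical posterior is invariant
under every permutation, so no shuffle test exists for it. This is the
conservative resolution.

The **circular-linear** variant treats location as an angle
$2\pi x / L$ and takes the square root of the $R^2$ from the weighted
sine/cosine regression of angle on time (the standard circular-linear
coefficient in weighted form), signed by the fitted direction of angular
drift. The estimator itself was an open choice; we picked the sine/cosine
regression form because it reduces to the linear case away from the wrap
and needs no iterative fitting.

Jump distances divide the absolute displacement of the per-bin posterior
argmax between consecutive bins by the track length; the median and maximum
summarize continuity. The joint threshold grids (sequence score crossed with
median jump; absolute correlation crossed with maximum jump) follow fixed
printed grids, compared by a one-sided pooled two-proportion z-test or by
ranking against surrogate datasets.

For theta, cycles are 400-ms windows on 5–9 Hz troughs while the animal
runs through the middle two-fifths of the track; the decoded matrices are
re-centred on the animal (±30 cm), averaged with equal weight per cycle
(spike-count weighting was an open question; equal weighting keeps
high-rate cycles from dominating), and summarized over a 100-ms window by
the quadrant ratio $(Q1 + Q3 - Q2 - Q4)/\Sigma Q$, tested against the 95th
percentile of time-bin shuffles.

## Event detection

Frames are epochs where the multi-unit rate (1-ms bins convolved with a
15-ms SD Gaussian) exceeds mean + 2 SD of its context epochs, lasts
100–800 ms, and recruits at least five distinct units. The threshold and
duration rules are fixed; the boundary rule is not stated anywhere we could
anchor it, so boundaries are the threshold up/down crossings — the simplest
consistent reading. One consequence, verified in the tests: lowering the
threshold can merge neighbouring bursts, so the *count* of frames is not
monotone in the threshold even though the total supra-threshold time is; the
test asserts the monotone quantity.

NREM is immobility (< 2 cm/s) plus a theta/delta amplitude-envelope ratio
below its session mean (5–9 vs 1–4 Hz, envelopes smoothed with a 10-s
Gaussian). Because a narrow 1–4 Hz band-pass is numerically ill-conditioned
at kHz sampling rates, the trace is decimated to ~100 Hz before filtering —
the bands of interest live an order of magnitude below that. Ripples are
140–250 Hz envelope peaks above 3 SD, with event boundaries at the 1-SD
crossings around each peak.

## Ensembles, assemblies

Frame-pair similarity is the percentile (0..1) of the Pearson correlation
between two frames' per-unit spike-count vectors against 500 cell-ID
permutations of one vector; pairs above 0.95 are significant. Clustering
runs k-means with cosine dissimilarity on the rows of the binarized
similarity matrix, 100 random restarts for every k in 2–30 (2–60 for
shuffled data), selecting k by the mode over restarts of the argmax of the
mean cluster silhouette $(a - w)/\max(w, a)$, with $w$ the mean
within-cluster and $a$ the mean nearest-cluster distance — both in the same
cosine metric as the clustering, which the silhouette's distance was left
open to. Mode ties break toward smaller k (parsimony). No installed
clustering routine offers the cosine metric, so the Lloyd iterations are
implemented in-package; the pairwise distance matrix is fixed across
restarts and computed once.

Assemblies come from PCA of the z-scored 20-ms binned run activity.
Eigenvalues above the Marcenko–Pastur bound $(1 + \sqrt{n/M})^2$ mark
significant co-activation patterns. The bound presumes unit-variance IID
entries, which is the scale of the correlation matrix $(1/M) Z Z^\top$ of
row-z-scored activity; that is therefore the default normalization, with an
`"as_printed"` switch for the $(1/n)$ variant some descriptions use.
Activation in sleep is the quadratic form $A_c(t) = z(t)^\top P_c z(t)$ with
the projection diagonal zeroed so single-unit bursts cannot masquerade as
assembly events; events are contiguous supra-threshold (> 5) runs collapsed
to their peak bin, requiring two active units including a place cell. Mean
activation is taken over events, not over all bins — re-expression strength,
not duty cycle. Assembly "membership", used only for validation, is defined
as units whose absolute pattern weight exceeds 2 SD of the component's
weights.

## Population-vector geometry

PV matrices correlate the population rate vector at every pair of 2-cm
locations. Track-end similarity averages the correlations between all bin
pairs drawn from the two 15%-of-length end zones. The **warp profile** pairs
two-bin segments placed symmetrically about the track middle (terminal
segments excluded) and regresses their PV correlation on separation over
24–88 cm: under linear coding the profile is flat-to-negative, under
mirrored ("warped") coding distant symmetric locations grow *more* similar
and the slope turns positive. Profiles pool across animals and directions by
averaging correlations at matched separations before fitting, which is also
how the group-level statistic is formed in the analysis scripts.

The end-specificity analysis groups frame time bins by their peak decoded
location and averages each group's preceding-bin (T−1) posterior; the ratio
of mass in the correct versus the opposite 15-cm end zone is ≫ 1 for
continuous sequences and ≈ 1 when end depictions swap between consecutive
bins at chance.

## The synthetic-data generator

The generator is first-class, tested code: it embodies the statistical
structure every downstream stage assumes, with ground truth recorded for
every planted feature. Its defaults are the study conditions used throughout
the tests: a 1-m track, 50 units, Gaussian fields with SD 5–12 cm and peak
rates 8–25 Hz, 10% untuned units, 20 out-and-back laps at 30 cm/s with 1-s
end pauses, position sampled at 25 Hz, spikes by thinning a 1-kHz Bernoulli
approximation of the inhomogeneous Poisson process, theta at 7 Hz, a 600-s
sleep with alternating 120-s NREM and 30-s REM-like epochs, about 12 planted
frames per NREM minute, 20% of frames carrying an embedded sequence that
advances a tenth of the track per 20-ms bin, three disjoint
participating-cell clusters among the remaining frames, and two planted
five-unit assemblies. The field-potential trace is sampled at 1250 Hz (video
and field-potential rates are generator choices; no recorded value
constrains them).

Two generator choices were made deliberately and deserve their rationale:

* **Planted frames are bursts by construction.** Frames are *defined* by the
  2-SD population-rate criterion, so planted frames must actually be
  detectable bursts over the background. Cluster frames emit ~5 spikes per
  participating unit per 400 ms (non-members ~0.5) and embedded-sequence
  frames multiply the template rates by a gain of 2 — time compression
  concentrates spiking — which puts planted frames several SD above the
  0.2–1 Hz per-unit background while keeping 30–150 spikes per frame,
  the scale of real population bursts.
* **The mirror component is end-anchored.** `mirror_weight` mixes each
  field with its reflection about the track middle, but the effective
  per-field weight is scaled by the field centre's normalized distance from
  the middle ($|2c/L - 1|$): end fields mirror fully, middle fields not at
  all. A position-independent mirror makes symmetric-pair similarity
  *constant* in separation, which cancels out of the warp-profile slope —
  we verified with 20,000 analytic tuning curves that the slope contrast is
  then ~$10^{-4}$, unmeasurable at realistic cohort sizes. End-anchoring
  matches the phenomenon being modelled (track ends are what become
  confusable; middle coding is preserved) and yields pooled slopes of
  ~+0.007 per cm for warped cohorts versus ~0 for controls.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: theta phase precession (theta cycles carry
rate-coded position only, so theta-sequence power on real data is untested
beyond the quadrant-ratio mechanics on constructed posteriors), behavioural
variability (constant running speed, no mid-track stops), spike-sorting
artifacts and cluster-quality issues, non-Poisson spiking statistics
(bursting, refractoriness), electrode drift, and any 2-D or curved-track
geometry. Calibration results (the ~5% null rate of the sequence test)
transfer to real data only insofar as real frames satisfy the decoder's
Poisson-independence assumptions as well as the synthetic ones do.

## Statistical conventions and problem sizes

Shuffle counts default to 500 everywhere (time-bin, cell-ID, frame-ID and
Poisson-surrogate nulls); percentile scores are the fraction of shuffles
strictly below the observed value. Two-sided tests are the default except
against chance/shuffle references, α = 0.05. All randomness derives from one
root seed through named substreams (`substream_seed`), so every report is
reproducible bin-for-bin; per-frame shuffle seeds derive from the root so
single frames can be recomputed in isolation.

The test suite and the acceptance script run at desk scale, chosen so the
whole suite completes in minutes on one core: 1,000 null frames for the
calibration of the sequence test; single 50-cell sessions for decoder and
power checks; ten seeds for cluster recovery (about 100 detected frames
each); ten IID datasets of 50 × 5000 bins for the Marcenko–Pastur control;
twenty cohort pairs of three animals × two directions for the warp
discrimination; 200 simulations for the regression calibration. The
pipeline's study driver (`run_study`, `analysis/`) uses five animals per
group with 40 units and 300-s sleeps.

## Known limitations

The lap detector assumes clean end-to-end traversals (5%-of-length end
zones); sessions with mid-track turnarounds need manual lap curation.
`segment_nrem` without a field potential degrades to immobility-only
segmentation with a warning. The cosine k-means selects k by silhouette
mode, which can be unstable when planted clusters overlap heavily; the
cluster-recovery tests quantify this at the default noise level only. The
regression stage fits ordinary least squares with likelihood-ratio tests —
no mixed effects across animals — matching the analysis it reproduces.
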
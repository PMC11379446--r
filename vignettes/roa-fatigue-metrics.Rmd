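---
title: "Tracking the region of activation: spatial fatigue metrics for HD-sEMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking the region of activation: spatial fatigue metrics for HD-sEMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During a sustained isometric contraction, a muscle does not fatigue as a
homogeneous unit: the spatial distribution of its electrical activity
redistributes as new motor units and muscle regions are recruited. A
high-density surface EMG (HD-sEMG) grid — here two 13x5 electrode arrays
fused into a single 26x5 matrix spanning 200 x 32 mm at 8 mm pitch —
resolves this redistribution as a moving hotspot on a per-frame amplitude
topography. `roatrack` tracks the centroid of that hotspot over time and
condenses its movement into a small set of scalar metrics whose evolution
from the beginning to the end of a contraction indexes fatigue, and whose
per-subject maxima can be regressed against endurance time.

The coordinate frame follows the muscle architecture: the x axis is the
fiber-transverse (FT) direction (grid columns, 0–32 mm), the y axis the
fiber-parallel (FP) direction (grid rows, 0–200 mm). Row 1 is treated as the
cranial end and column 1 as the medial edge. Which physical grid corner is
cranial/medial is a mounting convention, not something the data can decide;
the package documents its choice and every metric is invariant to it
(translation/rotation invariance is part of the test suite).

## Processing chain

1. **Torque conditioning and segmentation.** The torque trace is low-pass
   filtered (3rd-order Butterworth, 10 Hz, applied forward–backward) and used
   to delimit the contraction. Two transient marks are located: the end of
   the ascending ramp (first attainment of 99.5% of the target, 60% of
   maximum voluntary torque by default) and the failure instant (first
   moment from which torque stays below 50% MVT for at least 3 s — the
   endurance-time criterion). A 4-s *quasi-zero* window (±2 s) is placed
   around each mark, and the analysis region is the interval strictly
   between the two windows. Three 10-s segments are placed inside it: T1 at
   the region start, T3 at its end, T2 centred at the midpoint. In the
   original protocol the transients were marked manually; the automated
   99.5%-of-target surrogate is used here because it is reproducible, and
   manually supplied marks always take precedence. (A plain 50%-of-target
   crossing was considered and rejected: it fires halfway up the ramp, so
   its quasi-zero window would not contain the ramp transient it is supposed
   to bracket.)

2. **EMG conditioning.** Monopolar channels are band-passed 20–450 Hz
   (3rd-order Butterworth) with a 50 Hz power-line notch. The notch is a
   2nd-order IIR biquad with quality factor 30; no established R package
   provides a notch designer, so the coefficients are constructed from the
   standard cookbook form and applied with `signal::filtfilt`. All filters
   are zero-phase (forward–backward): centroid timing must not be skewed by
   group delay, at the documented cost of doubling the effective order.
   Low-SNR channels are flagged automatically (hold-phase vs quiet-phase RMS
   in dB against a 10 dB floor; a robust median/MAD outlier rule is the
   fallback when no quiet reference exists) and excluded from every
   subsequent computation — never zero-filled, which would drag centroids
   toward dead electrodes. Neighbour interpolation of bad cells exists for
   plotting only.

3. **Features.** The RMS envelope is the square root of a 500-ms centred
   moving average of the squared signal, sampled at 10 frames/s. The
   spectral index AIF (average instantaneous frequency) is the power-weighted
   mean frequency (spectral centroid) of a Hann-tapered periodogram on
   non-overlapping 500-ms frames, restricted to 20–450 Hz. The per-frame
   centroid is the conventional surrogate for instantaneous frequency at
   this frame length; an analytic-signal estimator was considered and not
   adopted as default. Channel averaging is frames-first, then channels.

4. **Topography and RoA.** Each envelope frame becomes a 26x5 amplitude map
   (NA at missing/bad positions). The region of activation (RoA) is the
   amplitude-weighted centroid of the cells at or above 70% of the map's
   local maximum; ties at the threshold are included so boundary handling is
   deterministic, and the local maximum is taken over the whole fused grid,
   not per constituent array. With threshold 0 every defined cell is active
   and the RoA reduces to the centre of gravity (CoG). The map rate equals
   the envelope frame rate (10 Hz by default, configurable — the method
   itself does not prescribe a rate).

## The metric suite

All spatial metrics operate on the RoA trajectory (u[n], v[n]) = (FT, FP)
within one segment of N frames and duration T (N times the frame period).
They are the direct analogues of the classical centre-of-pressure (CoP)
posturography measures, applied to the activation centroid: mean distance →
AID, total excursion → AIP, mean velocity → AIV, RMS distance → AIS, 95%
confidence ellipse area → AEZ, 95% confidence circle area → ACZ, swept area
per unit time → AMZ.

* **AID** (mm): mean distance from a reference point; per-direction variants
  are mean absolute deviations. The default reference is the *baseline* —
  the mean RoA over the first second of the analysis region — so AID reads
  as displacement from the initial activation site and grows as activity
  redistributes. The strict posturographic alternative (each segment's own
  mean) is available as `reference_policy = "window_mean"`. The resultant
  mean distance is the default definition of AID; the alternative reading
  as the RMS combination of the two per-direction AIDs differs only by a
  norm exchange and can be derived from the reported components.
* **AIP** (mm): total path length, with per-direction components; missing
  frames are dropped, never interpolated (interpolation across gaps deflates
  or inflates path length arbitrarily), and a gap longer than 1 s
  invalidates the segment's path metrics.
* **AIV** (mm/s): AIP divided by the segment duration, so `aiv * T == aip`
  holds identically.
* **AIS / std / avg**: per-segment means and population standard deviations
  of both coordinates; `ais = sqrt(std_ft^2 + std_fp^2)`.
* **AEZ** (mm²): `2*pi*F(0.95; 2, N-2) * sqrt(s_u^2 s_v^2 - s_uv^2)` with
  sample (co)variances of the mean-centred samples. Degenerate (collinear)
  segments yield area 0 with a warning rather than an error.
* **ACZ** (mm²): `pi * (mean(RD) + 1.645 * sd(RD))^2` with RD the distances
  of mean-centred samples from the origin.
* **AMZ** (mm²/s): `1/(2T) * sum |x[n] y[n-1] - x[n-1] y[n]|` over
  consecutive mean-centred samples — the area swept about the segment mean
  per unit time.
* **Displacement** (mm): Euclidean distance between the mean RoA of T1 and
  of T3, the classical amplitude-map shift measure.

Spread and area metrics are always mean-centred per segment (the CoP
convention); only the AID family uses the configurable reference. Every
metric is computed per segment, and the per-variable maximum across T1–T3 is
the predictor used in endurance-time regression; maxima over sliding windows
rather than segments would be a straightforward extension but segment maxima
are the default.

## Statistics

Per variable: Shapiro–Wilk normality screen per segment; Friedman
repeated-measures test (mid-ranks, standard tie correction) with Kendall's
W = chi2 / (N(k−1)) as effect size, banded small < 0.3, moderate < 0.5,
large ≥ 0.5; when the Friedman test is significant at 0.05, pairwise
Wilcoxon signed-rank tests with Bonferroni correction (factor 3, capped at
1), flagged at 0.05 and 0.01. All tests are two-sided. The signed-rank test
uses the exact distribution for n ≤ 25 without ties (zeros dropped first,
the standard convention); the normal approximation otherwise. When the
permutation space is small enough ((k!)^N ≤ 10^6) an exact permutation
p-value for the Friedman statistic is computed by dynamic programming over
column-sum distributions — at N = 5, k = 3 the chi-square approximation can
be off by ~0.07, which is why the exact value is reported alongside.
Endurance-time association is ordinary least-squares simple regression of
endurance on each metric's per-subject maximum, reported as R² with the
slope F-test p-value.

## The synthetic-data generator

Real validation data for this method would require human fatiguing
contractions; the package instead ships a simulator whose every ground-truth
quantity is known by construction, so each stage of the chain can be tested
as a recovery problem.

Per channel the signal is `gain(t) * carrier(t) + noise`, with:

* a spatial Gaussian hotspot (σ_FT = 10 mm, σ_FP = 12 mm) whose centre
  follows piecewise-linear waypoints plus a small Ornstein–Uhlenbeck wobble
  (sd 0.5 mm, correlation time 2 s) — the wobble is part of the injected
  truth and keeps the dispersion metrics away from degeneracy. The hotspot
  width is chosen so the 70% threshold region spans more than one electrode
  column: a narrower kernel quantizes the FT coordinate to the 8 mm pitch,
  which is a genuine behaviour of thresholded centroids but a degenerate
  regime for validating the metrics;
* a diffuse whole-muscle activity base (15% of the hotspot amplitude) on
  every channel, so distant channels carry muscle signal — not just noise —
  and the grid-level AIF reflects the muscle everywhere;
* carriers synthesized per 1-s block in the frequency domain as a Gaussian
  spectral bump (σ = 35 Hz) whose centre declines linearly (default
  −0.35 Hz/s, reproducing a ≈25 Hz T1→T3 drop over the default 100-s
  contraction). An explicit bump keeps spectral mass away from the 20 and
  450 Hz band edges, where the analysis bandpass would bias the measured
  centroid; a flat band with a re-fitted tilt was considered and rejected
  for exactly that edge-bias reason. The hotspot source is one carrier
  *shared* across channels — nearby electrodes see the same motor units
  through the volume conductor — which is what stabilizes amplitude ratios
  and hence the centroid; base activity and the additive noise floor are
  independent per channel;
* multiplicative amplitude growth (1 + 0.003 t), gated by the normalized
  torque profile (no muscle signal during the 3-s pre-contraction rest);
* a torque trace with linear 2-s ramp, a hold at 60% MVT carrying
  band-limited multiplicative noise whose CoV rises linearly (0.02 +
  8e-4 t), and a linear terminal decline crossing 50% MVT exactly at the
  configured failure time. The noise lives below ~4 Hz so it survives the
  10 Hz low-pass, and is tapered out before the decline so the constructed
  failure time is exact.

What the simulator does **not** emulate: motor-unit discharge trains and
their synchronization, volume-conductor geometry, electrode–skin impedance
drift, movement artifacts, inter-subject anatomical variability. Passing
recovery tests therefore demonstrates that the chain measures what it claims
on signals with the stated spatial/spectral structure — not that the
physiological interpretation of any metric is correct.

## Numerical and design choices

* Zero-phase filtering throughout; effective filter order doubles.
* Population (N-denominator) standard deviation in the torque CoV — a
  descriptive statistic over a fixed window; sample (N−1) (co)variances in
  AEZ, matching the F-distribution derivation.
* RoA threshold ties included (≥); uniform maps fall back to the unweighted
  centroid of the active set when total weight is zero.
* Segment windows are half-open [start, end), so adjacent segments never
  share a frame; at 10 Hz a 10-s segment holds exactly 100 frames.
* Bonferroni factor fixed at 3 (the three pairwise comparisons).
* CSV output at 9 significant digits makes pipeline reruns byte-identical.

## Problem sizes used in validation

The test-suite simulations use a 13x5 grid at 1024 Hz with 45-s records
(50 seeds per recovery property) and one full-scale 26x5, 2048 Hz, 100-s
subject for the spectral-decline recovery; coverage checks use 10^4-sample
Gaussian trajectories over 100 seeds, and the null-calibration of the
statistical battery uses 2000 replicates of a 9x3 table. These sizes were
chosen as the smallest at which the stochastic acceptance bands are
comfortably resolved.

## Known limitations

* A single activity hotspot is assumed; multi-peak topographies yield a
  single compromise centroid (no region splitting).
* The 70% threshold at 8 mm pitch quantizes the centroid when the active
  region is narrower than the inter-electrode distance.
* The automated transient marking assumes a ramp–hold–decline torque
  profile; atypical profiles should supply manual marks.
* Endurance-censored recordings (torque never failing) propagate NA
  endurance into the regression, which then drops those subjects.
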
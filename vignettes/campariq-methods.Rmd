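---
title: "campariq: models, estimators and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{campariq: models, estimators and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(campariq)
```

## What the package models

Photoconvertible calcium integrators are green fluorescent proteins that
convert irreversibly to a red state under violet light, at a rate that grows
with intracellular Ca²⁺. Two readouts coexist in one sensor:

* an **integrating readout** — the per-cell red-to-green fluorescence ratio
  (RGR) after an illumination epoch encodes the cell's activity during that
  epoch; and
* a **dynamic readout** — the green channel is a conventional calcium
  indicator, but a *negative* one: fluorescence *dips* during activity.

`campariq` implements the quantification for both readouts and a synthetic
scene generator that plants every parameter the analysis is supposed to
recover, so each estimator is validated against known ground truth.

## The photoconversion arm

### Corrections and the RGR

Raw two-channel images carry a detector offset and spectral cross-talk.
The **dark current** per channel is estimated as the 0.2 percentile of all
recorded pixels of that channel, pooled over the whole recording — pooling
(rather than per-frame estimation) is a deliberate choice: the lower tail of
a single frame is noisier, and nothing in the acquisition varies the offset
frame to frame. Quantiles interpolate linearly between order statistics
(`stats::quantile` type 7), fixed so results are bit-reproducible.

The green emission of the sensor leaks into the red detection channel.
The **bleed-through fraction** β is estimated from pre-conversion images,
where the red channel contains nothing else: β is the median over cells of
dark-subtracted red/green. The median (rather than a pixel-level or
whole-image regression) is robust to segmentation outliers; the estimator is
a package choice among several defensible readings and is configurable in
spirit — the inputs to `estimateBleedthrough` are any pre-conversion cell
table. Typical planted values are 13.1 % at 1000 nm and 14.6 % at 1040 nm
excitation, and estimates of β ≥ 1 abort with an error since they can only
arise from swapped channels.

Per cell the corrected ratio is

$$RGR = \frac{(R_{raw} - dark_r) - \beta\,(G_{raw} - dark_g)}
             {G_{raw} - dark_g},$$

computed **ratio-of-means**: channel means over the footprint and over
frames come first, the ratio second — lower variance than averaging
per-pixel ratios. Cells whose green mean does not exceed the dark current
are excluded (with a logged count), not clipped: a ratio against a
non-positive denominator is meaningless, and clipping would bias the pooled
median. Since photoconversion acts on every expressing cell simultaneously,
pooling pools *cells*, not fields of view: the group statistic is the median
of all cells piled across FOVs (the tests assert this is not the mean of
per-FOV medians).

### Light dose and the dose-response model

A conversion epoch with power $P$ mW, $n$ pulses of $t$ s over a spot of
diameter $d$ mm delivers $P n t / (\pi (d/2)^2)$ — with these units the
result is in **mJ/mm²**, the package's canonical dose unit. The standard
stimulation block (one 1-s pulse per grating, 8 directions × 5 repetitions)
gives ≈104 mJ/mm² at 100 mW and ≈208 mJ/mm² at 200 mW. Cumulative dose is
additive over events.

Median RGR versus cumulative dose is fit through the origin: the sensor
starts fully green, so zero dose must mean zero ratio. The estimator is the
closed form $\hat s = \sum x_i y_i / \sum x_i^2$ with
$se = \sqrt{RSS/(n-1)/\sum x_i^2}$, a two-tailed t test of $s = 0$ on
$n-1$ df and a 95 % CI from the same distribution. The t-based CI on
$n-1$ df is a package convention (the construction is not otherwise pinned
down). A perfect fit ($se = 0$) reports $p = 1$ when the slope is also zero
and the smallest representable p otherwise, keeping $p \in (0, 1]$.

### Dual-wavelength ratios, brightness, d′ and group tests

Longer excitation wavelengths pump the red species more and the green less,
multiplying the measured RGR; `wavelengthRatio` forms the per-recording
ratio of pooled medians between two wavelengths read sequentially in the
same session, excluding unpaired recordings, and reports mean ± sd across
recordings. Pre-conversion green brightness is compared across recordings
as median somatic green divided by the *square* of the excitation power,
because two-photon excitation scales quadratically with power — the
renderer implements the same law, and a test pins the normalisation to it.

Separation between a stimulated and a reference region is the sensitivity
index

$$d' = \frac{\bar x_{stim} - \bar x_{ref}}
            {\sqrt{0.5\,(s^2_{stim} + s^2_{ref})}}$$

with $n-1$ sample variances over cells pooled per region, computed
per recording. It is antisymmetric under group swap and invariant to common
shifts and positive rescalings — all tested. Group comparisons for report
parity use the Wilcoxon rank-sum test (exact null when the smaller sample
has ≤ 8 observations and no ties — the exact enumeration is cross-checked
against brute force in the tests — and the tie-corrected normal
approximation otherwise) and two-sample/paired t tests; a paired t on
zero-variance differences is flagged degenerate with NaN rather than
silently erroring.

## The dynamic arm

### Bleach correction

Slow photobleaching is removed per cell by fitting a degree-7 polynomial
$p(t)$ to the full trace and dividing: $corrected(t) = raw(t)\,p(t_1)/p(t)$.
The correction is divisive and anchored at the fitted value of the first
sample because ΔF/F₀ is a ratio statistic: a multiplicative envelope then
cancels exactly, and any constant factor the polynomial absorbs (for
example the mean level of stimulus dips) cancels between numerator and
denominator. If the fitted polynomial touches zero inside the recording the
trace is rejected with an error — dividing through a vanishing fit would
manufacture arbitrarily large artifacts. The degree-7 fit is intentionally
retained even though the generator bleaches with a single exponential: the
analysis should be robust to envelope model mismatch, and the recovery
tests (planted dips under half-lives of 2–10× the recording length) hold to
within 5 %.

### Trials, the lowest-quartile statistic and its bias

Trial windows are fixed by the protocol: a baseline of the 0.66 s before
each grating onset and a response window spanning the 4-s grating, with
frame counts `round(seconds × frameRate)` — 20 and 120 frames at 30 Hz.
`F_base` is the plain mean of the baseline window (the minimal reading of
an unqualified "baseline fluorescence"). `F_resp` is the mean of the
$k = round(0.25 L)$ smallest response-window samples ($k = 30$ at 30 Hz),
taken after a stable sort so ties resolve deterministically. For a negative
indicator this statistic targets the dip, and responsive trials have
$\Delta F/F_0 = (F_{resp} - F_{base})/F_{base} < 0$.

The statistic is **biased by construction**: under pure noise the mean of
the lowest quartile sits below the window mean, so null trials also have
negative expected ΔF/F₀ — and because the bias and the noise scale
together, its ANOVA significance does not shrink with the noise level. The
test suite asserts both faces of this: with `lowestFraction = 1` (the
plain-mean diagnostic estimator) the tuned-cell gate holds its nominal
0.01 false-positive rate on 2000 null cells, while with the lowest-quartile
statistic the rate is far above nominal. Consequently the planted
tuned-fraction recovery test runs in diagnostic mode; with the quartile
statistic the classification should be read as "cells with stimulus-locked
*or* noise-revealed dips", and absolute tuned fractions are comparable only
between analyses using the same statistic.

### Classification gates

The tuned gate is a one-way ANOVA over one movie's 80 values. The grouping
of those 80 values admits two readings; the package defaults to **two
groups** (40 `F_base` vs 40 `F_resp`), which directly tests "responds at
all", and exposes the 16-group direction × condition reading as
`mode = "direction_condition"` rather than guessing intent. Tuned cells
(p < 0.01) then pass to an 8-group ANOVA of `F_resp` across directions
(5 values each); p < 0.01 marks them oriented, so `is_oriented` implies
`is_tuned` structurally — an invariant the suite checks on every run. The
preferred direction is the one with the most negative mean ΔF/F₀ and the
per-cell peak amplitude is the mean ΔF/F₀ at that direction — a 5-trial
mean rather than a single-trial extreme, which would inherit the order
statistic's noise. Degenerate ANOVAs (zero within-group variance, as in
constant synthetic traces) return no p-value and classify the cell as not
tuned/oriented, with a flag.

## The synthetic generator

`generatePopulation` places non-overlapping disk cells uniformly in the
frame (uniform disks suffice because every downstream statistic is a
footprint mean — morphology is irrelevant to what is being tested), with
log-normal per-pixel expression and log-normal activity with median 1, so a
planted conversion slope is recovered directly from pooled medians. The
activity distribution is a modelling choice, not something the integrating
readout pins down; it is exposed as a parameter (`activitySdlog`, default
0.5).

`applyPhotoconversion` keeps the cumulative true ratio
$r = (s_b + s_a \cdot activity) \cdot D$ as the state variable and derives
species amounts as $green = E/(1+r)$, $red = E\,r/(1+r)$. This reconciles
two requirements that are otherwise in tension: conversion (not creation —
green + red is exactly conserved, a tested invariant) and exact linearity
of the true ratio in cumulative dose, which makes planted slopes exactly
recoverable.

`renderStack` applies per pixel
$dark + eff(\lambda) P^2 \times density$ plus, in the red channel, the
bleed-through fraction of the green signal. Noise is zero-mean Gaussian
with variance proportional to the fluorescence signal — a shot-noise
approximation with the right mean/variance structure at interactive speed.
The dark offset itself carries no noise (no read-noise model), which makes
the 0.2-percentile dark estimator exact on synthetic background; on real
detectors the estimator sits slightly below the offset's mean, a bias the
generator deliberately does not emulate.

`simulateDynamicTraces` builds per-cell traces: multiplicative dips of
depth `responseAmplitude × tuningProfile` during gratings (profile 1 at the
preferred direction with cosine-squared falloff scaled by the cell's tuning
depth), a single-exponential bleaching envelope, and additive Gaussian
noise expressed as a fraction of each cell's baseline. Default protocol:
8 directions × 5 repetitions, 4-s gratings, 8-s gray (4–12 s is the
realistic range; photoconversion protocols use the long end for tissue
cooling), 30 Hz.

What the generator does **not** emulate — and what passing tests therefore
do not certify about real data: optical point-spread and 3-D structure,
motion artifacts (inputs are assumed registered), neuropil contamination,
spike-train-level calcium kinetics (activity is one scalar per cell),
detector read noise, and segmentation errors (synthetic masks are exact).
The recovery results bound estimator behaviour under the model's
assumptions, not under every failure mode of an experiment.

## Reproducibility conventions

Every stochastic function takes an integer seed; a single run seed is
fanned out to stage-specific child streams by a deterministic hash
(`childSeed`), so stages can be re-run independently and identical
configurations yield byte-identical artifacts (the end-to-end manifest
records md5 checksums, and a test asserts checksum equality across
repeated runs). Generators restore the caller's RNG state.

Problem sizes used by the validation runs — 200 cells for contamination
recovery, six simulated sessions of 120 cells with 1–3 conversion events
each (≥ 10 dose points) per slope recovery, 2000 cells per region for d′,
ten paired dual-wavelength recordings, 160×160 to 256×256-pixel frames
with 2–3 frames per readout stack — were chosen as the smallest scenes
at which the estimators' sampling error sits comfortably inside the
tolerances being asserted; they mirror, at reduced scale, the cell counts
per mouse of a typical cranial-window session.

## Known limitations

* The lowest-quartile response statistic is anticonservative (see above);
  the package documents and reproduces this behaviour rather than
  "fixing" it, because comparability with the established analysis is the
  point. The unbiased diagnostic mode is one argument away.
* Bleed-through is assumed constant across cells and fields of view at a
  given wavelength; depth- or expression-dependent cross-talk is not
  modelled.
* The zero-intercept CI treats dose as fixed; uncertainty in delivered
  dose (lamp calibration, window transmission) is not propagated.
* Dynamic and integrating arms share the population model but are
  simulated independently; no joint session in which the same cells are
  both dynamically recorded and photoconverted is generated.
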
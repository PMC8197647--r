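---
title: "protophot: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{protophot: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protophot)
```

# Overview

`protophot` analyses two-channel fiber photometry recorded during a
nutrient-conditioned two-bottle task: a pretrained rat receives 45
forced-choice sipper presentations (one bottle at a time, casein- or
maltodextrin-paired flavor) followed by 20 free-choice presentations of
both bottles; sippers retract 5 s after the first lick, or after 30 s
without one; intertrial intervals are 10–30 s (mean 20 s). The package
covers the full chain from raw modulated photometry to estimation
statistics, and a synthetic generator that makes each stage verifiable
against injected ground truth. This vignette records the models, the
parameters that matter, and the design decisions that were genuinely open.

# Signal model and processing chain

## Lock-in demodulation

The 470 nm (calcium-dependent) and 405 nm (isosbestic) LEDs are modulated
at distinct carriers (defaults 211 and 539 Hz) and measured by one
photoreceiver sampled at 6.1 kHz. `demodulate()` recovers each LED's
baseband fluorescence by quadrature demodulation: the raw signal is
multiplied by sine and cosine references at the carrier, low-pass filtered,
and combined as $2\sqrt{I^2+Q^2}$, which returns exactly $A$ for a pure
tone $A\sin(2\pi f_c t)$. The low-pass is a 4th-order Butterworth at 20 Hz
applied forward and backward (zero phase), so event latencies measured
downstream are not shifted by filter delay; the first and last 0.5 s are
filter-settling regions and are flagged on the output. Output is resampled
to 1017 Hz by linear interpolation (safe because the passband is far below
the output Nyquist). Carriers must be distinct, above twice the low-pass
cutoff, and below the raw Nyquist.

## Isosbestic correction

`fftSubtractCorrect()` transforms both baseband channels with the FFT,
subtracts the 405 nm spectrum from the 470 nm spectrum bin-wise, and
inverse-transforms. This is mathematically identical to time-domain
subtraction (the test suite asserts equivalence at 1e-9 relative RMS); the
frequency-domain route is kept because it is the method's canonical
formulation and the transform is reused for the F0 trend. Signals are
zero-padded to a 2-3-5-smooth length so the transform stays $O(n\log n)$
for any session length; padding does not change the subtraction (linearity)
and the result is truncated back to the original length.

The default is literal unit-gain subtraction — artifacts are assumed to
enter both channels with equal gain. For recordings where the channel gains
differ, `scale_405 = TRUE` least-squares-fits the isosbestic channel onto
the 470 channel before subtracting; it is off by default because the
unit-gain form is the plain reading of the method and the right null
behavior for the generator's shared artifacts.

## ΔF/F

`deltaFOverF()` divides the corrected trace by a total-fluorescence
baseline $F_0(t)$, defined as the very-low-frequency trend (default
cutoff 0.001 Hz, i.e. session scale) of the 470 nm channel, computed by an
FFT low-pass with reflection padding to avoid wrap-around edge artifacts.
Three candidate definitions of $F_0$ were considered — the 470 trend, the
405 trend, and their sum. The 470 trend is the default because "total
fluorescence" for the calcium channel includes its own bleaching
trajectory, which the 470 trend captures directly; `f0_method = "mean"`
gives a session-mean alternative. $F_0 \le 0$ anywhere is a hard error
("non-physical total fluorescence") rather than a silent clamp. ΔF/F is
invariant under common rescaling of both inputs; downstream z-scoring makes
trial metrics additionally invariant to affine changes of ΔF/F.

# Trial metrics

`segmentTrials()` builds one trial per sipper presentation; extensions on
both sippers within 0.5 s form one free-choice trial whose solution is that
of the first-licked sipper. Traces are binned into 100-ms means on
[−10, +20) s around the first lick and z-scored against the mean and SD of
the 100 pre-lick baseline bins. "z score" is read as the standard
$(x-\mu)/\sigma$ of that baseline — any other reading fails the property
that the baseline bins themselves have mean 0 and SD 1. A zero-variance
baseline is an error, not a NaN. Bin edges carry a 1-ns guard so grid
points that land exactly on a 0.1-s boundary (not representable in binary
floating point) fall in the intended bin.

AUC over a window $[a,b)$ is $0.1\sum_b z_b$ over the bins inside the
window, in z·s. The bin means are unbiased estimates of the within-bin
signal average, so this rectangle rule is an unbiased estimate of the
integral and is exactly additive: AUC[0,5) + AUC[5,10) = AUC[0,10) to 1e-9.
(A trapezoid across bin *values* would clip half a bin at each end — a
constant z of 1 over [0, 5) must integrate to 5.0, and does.) The
consumption window [0, 5) s after the first lick coincides with the
lick-to-retract access window; [5, 10) s is the post-retraction epoch. Some
analysis traditions report the bin *sum* instead (10× larger);
`scale = "z_bins"` provides it, since the absolute scale of published AUCs
is otherwise unverifiable — relative contrasts are the package's contract.

Latency to peak is measured from sipper extension to the maximum z bin
between extension and retraction, ties resolved to the earliest bin. The
search window ends at retraction by default (config-overridable): the peak
of a consumption response belongs to the access period, and extending the
window into the intertrial interval would let baseline fluctuations win on
weak trials.

The pre-session baseline AUC z-scores the epoch from session start to the
first sipper extension against the statistics of the epoch's *first 10 s*
(the same 10-s baseline rule the trial metrics use) and integrates over the
whole epoch. Normalising against the full epoch's own statistics was
rejected: removing the epoch mean forces the integral to zero identically,
which destroys the metric's ability to distinguish sessions.

Lickless trials are kept, flagged non-analyzable, and excluded from neural
metrics and latency summaries (reported as missing, never zero); their
count is reported. Trials whose peri-lick window is not covered by the
recording are flagged truncated and excluded. Baseline windows may overlap
the previous trial's tail (the minimum ITI is 10 s); they are used as-is,
matching the stated 10-s rule, and with the default 1.5-s decay kernel the
previous response has decayed by more than e^{-6} at the next baseline.

# Behavior

A free-choice "choice" is the sipper of the trial's first lick — the
standard two-bottle convention. Preference is casein choices over total
choices; lickless free trials count as no-choice and leave the denominator.
Head position is the centroid of nose and both ears on frames where all
three exceed likelihood 0.9; gaps of at most 5 frames are linearly
interpolated, longer gaps dropped, and a session retaining under half its
frames carries a warning in the result rather than an error. The tail base
is excluded from position (it is a QC landmark; sipper approach is
head-referenced). Distances are Euclidean in mm, calibrated at 1 mm/px by
default from the 30.5-cm chamber width. Distance densities use Scott's-rule
bandwidths and are reporting artifacts, not inferential quantities.

# Estimation statistics

`meanDifference()` computes the mean difference (paired, unpaired, or
one-sample against a null value), a 95% BCa bootstrap CI and a permutation
p-value. Defaults are 5000 bootstrap and 5000 permutation resamples. The
bias correction $z_0$ comes from the bootstrap distribution's position
relative to the observed estimate (with half-weight on ties), the
acceleration $a$ from the leave-one-out jackknife; paired designs bootstrap
the vector of differences. When $z_0 = 0$ and $a = 0$ the interval reduces
to the percentile interval (asserted on symmetric data in the tests). A
zero-variance input yields a degenerate result — CI collapsed at the
effect, p flagged missing — rather than an exception.

The permutation statistic is the t statistic, two-sided via $|t|$:
within-pair sign flips for paired designs (equivalent to relabeling within
pairs for the mean-difference t), group-label reshuffles for unpaired, sign
flips about the null for one-sample. $p = (\mathrm{count}+1)/(n_{perm}+1)$,
the standard finite-sample correction that avoids zero p-values — note its
floor: with $n$ pairs the smallest attainable two-sided p is about
$2/2^{n}$, so paired designs with 5 or fewer subjects cannot reach 0.05.
All resampling is seed-deterministic; the pipeline derives per-analysis
seeds by stable hashing of the analysis label, so adding an analysis never
shifts another's resamples.

Per-rat classification uses the classical pooled-variance unpaired t test
(Welch available via a flag but off — the plain "unpaired t test" is the
reference procedure) at α = 0.05, labelling a rat by the significant
direction or "ns". No multiple-testing correction is applied anywhere —
results are reported per test, as is the convention for these per-rat
pie-chart summaries. Mann–Whitney comparisons use the exact distribution
for combined n ≤ 20 without ties and the tie-corrected normal approximation
otherwise.

**Known limitation — BCa at very small n.** The package's calibration tests
measure BCa coverage directly: for a Normal mean at n = 8 the measured
coverage is ≈ 88–89%, and a null paired contrast at n = 6 retains zero in
≈ 86–88% of simulated cohorts — below the nominal 95%. This is intrinsic
small-sample behavior of the BCa construction (reference implementations
in other ecosystems measure the same rates on identical data), not an
implementation artifact; two acceptance-level assertions that demand
near-nominal small-n coverage are accordingly expected to fail and are kept
as honest documentation of the gap. Effect directions and permutation
p-values are unaffected.

# The synthetic generator

`generateSession()` emulates what the analysis assumes, with ground truth:

* **Schedule** — 45 forced + 20 free trials, uniform ITI on [10, 30] s
  (the stated minimum/mean/maximum identify the uniform distribution, which
  is the natural choice absent a stated form), 5-s access after the first
  lick, 30-s timeout, a 60-s quiet pre-session epoch. First-lick latency is
  log-normal per solution (default median 2 s, σ_log 0.5 — typical
  approach latencies; no quantitative distribution is published, so these
  are config-exposed stand-ins); licking is a 6-Hz Poisson bout (typical
  rat lick rate). Free-choice behavior follows a softmax over per-solution
  values, so preference regimes from 0.5 to ~0.85 map to value gaps of 0 to
  ~1.75.
* **Response** — a peak-normalised difference of exponentials (default rise
  0.2 s, decay 1.5 s, a slow-indicator-like transient), onset locked to the
  first lick with a log-normal delay (median 0.15 s). Amplitude is
  expressed in z-equivalent units: the generator converts it to raw volts
  using one binned-baseline noise SD of the corrected trace, so an
  amplitude-3 kernel produces a peak z of ≈ 3 and
  `expectedResponseAuc()` gives the analytic AUC the trial metrics
  estimate. Bleaching multiplies baseline fluorescence but not transients
  or noise, which keeps this mapping exact at any session time.
* **Artifacts** — slow sinusoidal drift and boxcar-smoothed Poisson motion
  impulses added to both channels with unit gain (so correction cancels
  them), multiplicative exponential bleaching (default τ 2400 s), and
  independent white measurement noise per channel (default 0.02 V on a 2-V
  baseline). Both channels share one baseline level, which is what makes
  unit-gain subtraction the correct null.
* **Cohorts** — `generateCohort()` derives per-rat session seeds
  deterministically from the master seed and test day (the same master
  seed retested gives the same animals on a fresh recording day),
  counterbalances sipper sides and flavor maps across rats, and draws one
  shared per-rat response *gain* (log-normal, mean 1, σ_log 0.3) that
  multiplies both solutions' amplitudes. A shared gain — not independent
  per-solution offsets — matches the physical sources of between-rat
  variability (indicator expression, fiber placement) and preserves the
  null: a rat with equal injected amplitudes has no within-rat contrast at
  any gain.

What the generator does **not** emulate: spontaneous calcium transients in
the baseline (real baselines carry structured activity; the generated
baseline is white after correction), hemodynamic or wavelength-dependent
artifact gains, lick-bout microstructure beyond a constant rate, slow
satiety trends across a session, and any coupling between movement and the
motion artifact. Passing tests therefore certify the chain's correctness on
signals obeying the stated model, not performance on every pathology of
real recordings.

# Problem sizes

Real analyses use the 1017 Hz baseband rate and 5000/5000 resamples.
Simulation-heavy tests and the acceptance script generate sessions at
20 Hz — for 0.1-s bins every property of the chain is preserved while a
full 65-trial session costs ~0.1 s — and use 999–1999 resamples inside
calibration loops, whose targets (type-I rate, coverage) do not depend on
the resample count. Cohort recovery runs 100 master seeds of an
8-rat protein-restricted cohort and a 6-rat control cohort; calibration
runs 1000 null permutation tests and 500 coverage replicates.

# Limitations

* The absolute AUC scale depends on the z·s vs z·bins convention (toggle
  provided); only contrasts are contractual.
* Whether free-choice trials should contribute to neural summaries is left
  to the caller; the pipeline's neural contrasts use forced trials only.
* The access-duration tolerance in `validateEvents()` (0.25 s) absorbs
  unspecified hardware retraction latency; real rigs may need a different
  value.
* Native acquisition-system formats (behavioral control files, DAQ tanks)
  are out of scope; the session bundle (CSV + JSON) is the interchange
  format, and pose tracking is consumed in the standard 3-row CSV export
  dialect.
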
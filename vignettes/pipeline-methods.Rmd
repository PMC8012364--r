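---
title: "Methods: photometry, behavior and ephys analysis for the 5-CSRTT"
author: "csrttpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photometry, behavior and ephys analysis for the 5-CSRTT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csrttpipe)
```

This vignette is the package's account of its own methods: the signal
model, the statistical procedures, the tunable parameters, and the design
decisions taken where more than one reasonable reading existed. It states
no empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## The experimental setting

In the self-paced 5-choice serial reaction time task a rat initiates a
trial, waits through a delay (5, 7.5 or 12.5 s in the challenge sessions
this package models), and must respond to a brief light cue in one of five
apertures within the cue plus a 2 s limited hold. Outcomes are *correct*,
*incorrect*, *omission* (no response; an attentional lapse) and *premature*
(a poke during the delay; the operational measure of failed inhibitory
control). Errors trigger a 5 s timeout. Fiber photometry of GCaMP-
expressing projection populations during these sessions asks whether
delay-period population activity is elevated, for how long, and how it
differs between outcomes and between projection targets; slice
electrophysiology characterizes the same circuits synaptically.

## Photometry signal model and motion correction

The two-channel model assumed by the correction — and implemented literally
by the simulator — is

* 405 nm: `F405 * bleach(t) * motion(t) + sensor noise`
* 470 nm: `F470 * bleach(t) * motion(t) * (1 + ca(t) + slow noise) + sensor noise`

where `bleach` is a slow multiplicative exponential, `motion` is a shared
band-limited multiplicative process, and `ca(t)` is the calcium-dependent
term of interest. Because the isosbestic channel carries every calcium-
*independent* component, an affine fit of the 405 channel to the 470
channel (`fit = a * F405 + b`, ordinary least squares over the whole
session; Huber M-estimation available via `robust = TRUE`) followed by

```
dF/F = (F470 - fit) / fit
```

cancels shared multiplicative structure. Two decisions here:

* **Difference-over-fit rather than ratio.** `(F470 - fit)/fit` and
  `F470/fit` differ by the constant 1; the difference form maps a null
  signal to 0, which is the baseline convention every downstream z-score
  and bootstrap readout assumes.
* **OLS over the whole session.** With transient duty cycles around 10% or
  below, the slope bias from the calcium term is small (the test suite
  checks a scattered-transient construction at ~4% duty stays within 5% of
  the true gain). Sessions with heavier signal loads should use the robust
  fit.

## Filtering, detrending, decimation

The cleanup stage applies, in order:

1. **Zero-phase FIR lowpass**, default 1 Hz, a Hamming-windowed sinc
   normalized to exact unit DC gain, applied as a single centered
   convolution (symmetric kernel, so no phase shift and no latency bias in
   time-to-event metrics). Convolutions run via FFT at 2-3-5-smooth padded
   lengths, so arbitrary (prime-ish) trace lengths stay fast.
2. **Spectral detrend**, default cutoff 0.005 Hz: the trace is mirror-
   extended (even extension, so the edges stay continuous), Fourier
   transformed, components at or below the cutoff zeroed with a raised-
   cosine transition up to twice the cutoff, and inverted. DC is removed
   exactly; the 0.05-0.5 Hz band that task transients occupy is untouched.
3. **Decimation by 64** after an anti-alias FIR at 80% of the new Nyquist,
   taking a ~1017 Hz acquisition to ~15.9 Hz frames.

The smoothing/detrending cutoffs are deliberately exposed as a configurable
pair. Published pipeline descriptions in this area sometimes quote filter
corner pairs that cannot both be meant literally (a lowpass below a
highpass); this implementation reads them as *smoothing* plus *slow-drift
removal*, records both cutoffs in the trace provenance, and leaves them
configurable rather than asserting one reconstruction as the original
intent. The raw rate default of 1017.25 Hz is likewise an inference: it is
the rate at which division by 64 lands on the quoted ~16 Hz frame grid.
A related ambiguity — a "~16 Hz" frame rate versus a "~125 ms" frame
duration quoted elsewhere — is resolved by always treating frame duration
as `1/fs`.

## Epoching and baseline z-scoring

Epochs are cut on a nominal frame grid `k/fs` over a half-open window
(default -5 to +15 s) around the alignment event (trial start, cue, or
response); the alignment frame is the first frame at or after the event,
with no sub-frame interpolation. Trials whose window (including baseline)
leaves the recording are dropped and counted. Whatever the alignment, the
baseline is always the -5 to -1 s window *before trial start* — the task's
enforced inter-trial quiet period — and each trial is z-scored by its own
baseline mean and SD. Sample SD (denominator n-1) is the default since a
4 s baseline holds only ~64 frames at 16 Hz. Zero-SD baselines exclude the
trial explicitly rather than silently zeroing it. Two consequences the
tests verify: metrics become invariant to affine rescaling of the raw
trace, and the "baseline + 2 SD" threshold is exactly `z > 2`.

## Delay-period metrics

All metrics operate on z-scored, trial-start-aligned epochs, within each
trial's own delay (a fixed [0, 12.5 s] window is available for cross-delay
AUC comparisons, restricting analysis to the signal before the longest
delay's cue):

* **AUC**: trapezoidal integral over the *closed* interval [0, delay] —
  closed so a constant z = 1 across a 5 s delay integrates to exactly
  5 z·s; the event-timing metrics keep half-open [0, delay).
* **Rise fraction at 1 s**: z at the frame nearest 1 s over the delay peak;
  undefined (NA) when the peak is non-positive.
* **Threshold events** (`z > 2`): first-crossing time and total
  suprathreshold time at frame resolution (1/fs); trials that never cross
  are flagged NA, and NA propagates out of per-subject means with counts.
* **Peak metrics**: the peak z, and time-to-peak defined as the first local
  maximum exceeding 20% of the peak — capturing onset speed rather than
  absolute argmax. A local maximum is a run of equal values strictly above
  both neighboring values (plateaus resolve to their earliest frame;
  boundary runs qualify on their single neighbor, so a monotone rise to the
  cue peaks at the cue). "Overall peak" is read per trial; whether the
  published figure-level statistics used per-trial or per-animal-mean
  traces is not determinable from the text, so per-trial is the default and
  per-animal aggregation is provided alongside.

## Bootstrap elevated windows

`bootstrapMeanCI` resamples *subjects* (per-subject mean traces) with
replacement, `nIter = 5000` times, and takes per-frame empirical quantiles
at `alpha/2` and `1 - alpha/2` (default alpha 0.001). A frame is elevated
when the lower bound exceeds 0 — the one-direction readout of a two-sided
band on zero-baselined traces. The published description of this procedure
contains two internal inconsistencies (alpha quoted as both 0.001 and 0.01;
a sentence about averaging per-rat bounds that conflicts with rat-level
resampling). The implementation follows rat-level resampling with a single
group-level interval and alpha 0.001, matching the figure-caption
parameters; the per-subject-then-average construction is available as
`bootstrapSubjectCI` on trial-level data for comparison.

Known behavior, quantified in the tests rather than hidden: at n = 6
subjects the percentile bootstrap is anti-conservative — its true coverage
at nominal 95% is `2*pt(qnorm(.975)*sqrt(5/6), 5) - 1` (about 0.87), and
the suite asserts coverage against that closed form. Window *recovery* is
what the procedure is used for, and that is calibrated directly: with a
+1 z plateau and 0.3 z between-subject noise, detected windows overlap
truth at Jaccard >= 0.8 in >= 90% of replicates.

## Frame-wise permutation comparisons

`permutationDifferenceMask` compares two groups frame by frame with the
difference of group means as statistic. The null reshuffles the
subject-to-group assignment (unpaired) or randomly swaps the two traces
within each subject (paired — provided because outcome comparisons within a
group are naturally paired, though pairing is not specified in published
descriptions). Monte-Carlo p-values use the +1 correction,
`p = (1 + #{|T*| >= |T|}) / (1 + nIter)`, so p is never zero; frames with
`p < alpha` (default 0.01) are significant. An `exhaustive = TRUE` mode
enumerates all assignments or sign patterns for small groups and drops the
+1 correction; the suite checks Monte-Carlo p against this enumeration.
Tied permutation statistics count as exceedances, with a 1e-9 relative
slack so the count — and therefore p — is invariant to common affine
transforms of both groups.

**Singleton filtering**: both the bootstrap and permutation masks drop
significant runs shorter than 2 frames (a significant frame with no
significant neighbor), suppressing isolated frame-level false positives;
post-filter null rejection rates fall well below the nominal alpha while
pre-filter rates match it.

`bhFdr` wraps `stats::p.adjust(method = "BH")` — the step-up procedure is a
solved problem; the package contributes only the gate around it.

## Behavior quantification

`summarizeSession` applies the magazine-latency rule first — trials
collected more than 10 s after the response are excluded from *all* tallies
(the stricter reading of "excluded from further analysis"; a latency-only
mode is available) — then computes accuracy = 100 C/(C+I) (attentional
performance independent of omissions), premature and omission percentages
of started trials, and mean latencies, with per-delay and per-cue-duration
breakdowns. `splitBlocks` assigns trials to half-open 30-min blocks by
trial start (a trial at exactly 30:00 opens block 2). Premature-latency
distributions are returned as histogram plus empirical CDF.
`doubleLabelPercentage` rounds half-to-even to two decimals, matching the
reporting convention for double-labeled cell counts.

## Electrophysiology features

All formulas operate on labeled sweep sets (`EphysProtocol`):

* **Input resistance**: steady-state deflection (last 200 ms of the step,
  minus pre-step baseline) regressed on current over the negative steps to
  -100 pA; free intercept, so holding offsets cancel.
* **Membrane time constant**: `V(t) = Vinf + A exp(-t/tau)` fit
  (Levenberg-Marquardt) to the first 300 ms of each small negative step
  (|I| <= 50 pA); fits with R^2 <= 0.8 on the fitted window are discarded
  and the median surviving tau is reported.
* **Capacitance**: `C = tau / R` (1000·tau_ms/R_MOhm in pF). The published
  phrase "input resistance over membrane time constant" is dimensionally
  inverted; `tau/R` is the only unit-consistent reading of the RC identity
  and is what the package computes.
* **Sag**: on the negative step whose peak deflection is closest to
  -20 mV, `100 (|dPeak| - |dSS|)/|dPeak|` with steady state from the last
  fifth of the step; the magnitude convention keeps sag in [0, 100) for
  physiological traces.
* **Firing**: spikes are upward 0 mV crossings; burst rate counts spikes in
  the 50 ms from the first spike, steady rate the last 200 ms, on steps
  matched to the 0-200 pA / 50 pA grid within an inclusive 5 pA tolerance
  (so 45/105/195 pA sweeps from 15 pA-increment protocols are usable).
* **Rheobase**: injected current at the first spike on a 0-500 pA ramp.
  The measurement inherits a ramp-rate dependence of order
  `ramp rate x tau`; the simulator documents and the tests bound it.
* **PSC trains** (10 sweeps, 5 pulses at 10 Hz): per sweep, a Huber-robust
  line fit to pre-/inter-stimulus baseline samples removes holding-current
  drift without being pulled by the evoked responses; the pointwise median
  across sweeps then resists outlier sweeps. Per-pulse peaks are signed
  extrema in (onset, onset + 90 ms] — the window length is a package
  decision, configurable — after local 5 ms baseline subtraction; ratios
  are magnitudes `|PSC_n|/|PSC_1|`. PSC_1 below a noise floor (default 5x
  the baseline SD, because an extremum over ~1800 samples sits near 3.9
  sigma under the null) flags all ratios NA. Latency is the linearly
  interpolated 80%-of-peak crossing from light onset.

## The synthetic-data generator

The generator is first-class, tested code. It emulates what the analysis
assumes: variable-delay sessions with delay-conditional outcome
probabilities and task-consistent response times; photometry with shared
multiplicative motion/bleach, per-trial delay-spanning transients
(exponential rise to a plateau, exponential decay after the delay;
premature trials truncate at the response, omissions attenuate by a
configurable factor — defaults chosen to qualitatively mirror the ordering
of outcome traces, never asserted as test truth); RC membranes with
optional sag and integrate-and-fire spiking; Tsodyks-Markram short-term
plasticity for PSC amplitude trains. Ground truth (transient windows,
cell parameters, per-pulse amplitudes) is returned alongside every
simulated object.

Defaults are fixed study conditions, not tuning knobs: delays
{5, 7.5, 12.5} s, 1 s cue, 2 s limited hold, 5 s timeout, 10 s quiet
inter-trial interval; 1017.25 Hz raw rate with decimation 64; 5%
transient amplitude; 2% motion; 0.2% sensor noise; 0.5% slow 470-only
fluctuations (the term that survives the processing chain and sets a
realistic z-score scale); 5000 resampling iterations at alpha 0.001/0.01.
One RNG stream per generator call, seeded explicitly.

What the generator does **not** emulate — and therefore what passing tests
cannot show about real data: hemodynamic contamination, wavelength-
dependent (non-shared) motion, GCaMP nonlinearity and saturation,
spike-to-fluorescence kinetics, electrode access-resistance artifacts, and
session-scale nonstationarity beyond exponential bleaching. Conclusions
about those failure modes require real recordings.

## Numerical choices and degenerate inputs

Half-open `[start, end)` conventions throughout (windows, blocks,
significance intervals); times in seconds from session start. Constant
control channels, non-positive fitted controls, zero-SD baselines, empty
selections, absent spikes/crossings and sub-noise PSCs all produce explicit
errors, warnings or NA flags rather than silent zeros. Exact-tie handling
in permutation counting uses a 1e-9 relative slack; FFTs run at padded
2-3-5-smooth lengths; the trapezoid rule is exact for the linear ramps used
as oracles.

## Problem sizes used by the checks

The test suite runs the full photometry chain at a 128 Hz raw rate with
decimation 8 (the same 16 Hz frame grid as the full-scale settings, which
are themselves exercised in the acceptance checks at 1017.25 Hz/64);
bootstrap recovery uses 200 replicates of 6 subjects at 5000 iterations;
permutation calibration 500 null replicates of 6 vs 6 over 200 frames at
5000 iterations; tau recovery 100 noisy cells; threshold calibration 10^4
null frames. `scripts/acceptance.R` recomputes the same quantities from
scratch (100/200 replicates for the two heaviest checks) and writes them
to JSON; its `--seed` drives every stochastic stage.

## Known limitations

The isosbestic fit is session-global; slow gain drift between channels is
absorbed only insofar as it is shared. The percentile bootstrap's small-n
anti-conservatism is documented rather than corrected (no BCa or
studentized variant). No cluster-mass correction is applied across frames —
singleton filtering is the only multiplicity control inside a window
analysis, faithfully reflecting the procedure it implements. Sub-frame
event timing is not interpolated. Vendor acquisition formats are not read;
the text containers in `?writePhotometryRecording` document the expected
schema for converters.
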
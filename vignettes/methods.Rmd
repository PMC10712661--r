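---
title: "Models and methods behind emophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind emophys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`emophys` implements a complete analysis pipeline for multimodal
physiological recordings acquired during emotion-elicitation experiments
that use standardized affective picture (IAPS) and sound (IADS) libraries:
a protocol scheduler, per-signal preprocessing and feature extraction for
galvanic skin response (GSR), ECG-derived heart rate variability, blood
volume pulse (BVP), EEG and pupillometry, and a nonparametric cross-phase
comparison stage. Because no subject-level data are publicly deposited for
this class of study, the package is driven by a first-class synthetic-data
module with known ground truth: every analysis stage has a recovery test
against the generator that produced its input.

# The protocol timeline

The experiment has three stimulation phases - pictures only, sounds only,
and semantically matched picture+sound pairs - whose order is a uniform
random permutation drawn from a seed. Each phase alternates four arousal
sessions at strictly increasing levels 1-4 with 90 s neutral sessions; an
arousal session delivers six 15 s stimuli, the first three with low
valence and the last three with high valence. The timeline opens with a
5 min grey-screen rest and phases are separated by 2 min rests.

Two design points were genuinely open:

* **Neutral placement.** The design says the session types "alternate"
  without fixing which comes first. We place one neutral session after
  each arousal session (A N A N A N A N), so every arousal session has a
  following baseline.
* **Total duration.** The published figure of 47 minutes cannot be
  reconstructed from the stated element durations under any alternation
  layout (5 min + 3 x 720 s + 2 x 120 s = 45 min). The scheduler derives
  the total from the elements (2700 s) rather than forcing a target; the
  720 s phase block it produces matches the per-phase duration quoted
  elsewhere in the source material.

All coordinates are seconds from experiment start and all windows are
half-open `[t_start, t_end)`, which makes the arousal/neutral windows an
exact partition of each phase block (a tested invariant).

# Signal-processing core

No DSP library providing Butterworth design or zero-phase filtering is
available in the supported environment, so `emophys` carries its own:
poles are placed analytically on the Butterworth circle, warped through
the bilinear transform and paired into second-order sections (numerically
robust even for the 1-3 Hz delta band at 300 Hz). Zero-phase filtering is
the usual forward-backward pass with odd-reflection padding and
steady-state initial conditions. Two passes square the magnitude response,
so a single-pass -3 dB cutoff becomes a gain of 0.5 - the tests pin this
down exactly. The design was cross-checked against an independent
reference implementation during development; the shipped tests rely only
on closed-form oracles (gain at the cutoff, passband transparency,
time-reversal symmetry to 1e-6, Parseval consistency of the Welch
estimator within 10%).

Decimation is nearest-index selection after the caller's anti-aliasing
filter, mirroring the two-step description of the acquisition pipeline
(filter at 2 Hz then "downsample at 5 Hz", etc.); the native-to-target
ratios are not integers, and index selection keeps the operation exact
and stateless. Band powers are trapezoidal integrals over half-open
bands with interpolated edges, so adjacent bands tile the total power
with no double counting.

# Electrodermal chain

The raw conductance is low-pass filtered at 2 Hz (order 4, zero phase)
and decimated to 5 Hz. The tonic level is a running median over +/-4 s
(truncated at the edges - reflection would fabricate tonic spikes), and
the phasic component is the filtered signal minus the tonic, an identity
that holds samplewise to machine precision. Skin conductance responses
(SCRs) are detected as upward crossings of the phasic trace above
0.01 uS; the offset is its return to 0 (clamped to the window end, since
15 s stimulus windows routinely truncate recoveries), the peak is the
maximum of the *filtered* signal between the two, and the amplitude is
the *phasic* value there - the eccrine spike above the tonic level.

The one genuinely ambiguous feature is AVenv, "the envelope of the phasic
component computed as the average of its integral". We read it as the
time-average of the running (cumulative trapezoidal) integral of the
phasic signal over the window: dimensionally conductance-like and
monotone in total SCR mass. This is a documented interpretation, not a
published formula.

**Generator note.** The synthetic SCR kernel is bi-exponential with
default `rise_tau = 0.3 s`, `decay_tau = 1.2 s` - the fast end of
physiological SCR shapes. The choice is deliberate: with the +/-4 s
median window prescribed for the tonic estimate, a slow-recovery SCR
lifts the median at its own peak and the phasic amplitude is biased low
by tens of percent. That attenuation is a property of the published
method itself, not of this implementation; the generator default was
fixed once so that recovery tests measure the detector, not the bias.
A green amplitude-recovery test therefore does *not* establish unbiased
amplitudes for slow real-world SCRs.

# Heartbeat point process

R-peaks are detected with a Pan-Tompkins chain (5-15 Hz band-pass,
derivative, squaring, 150 ms moving-window integration, adaptive
signal/noise thresholds, 200 ms refractory period) on the 250 Hz
anti-aliased ECG, with peak locations refined to the raw-signal maximum.
The manual annotation review of a laboratory workflow is replaced by an
automatic physiologic guard (0.25-3 s intervals) plus a gap re-search at
a lowered threshold; a library has no operator.

Each inter-beat interval is modelled as inverse-Gaussian with shape
`theta_{p+1}` and mean

    mu_RR = theta_0 + sum_{i=1..p} theta_i RR_{k-i},

i.e. an AR(p) on the preceding intervals. (The source material prints
the density without the square on the deviation term; the standard
squared form is implemented - the printed form does not normalize, and
our quadrature tests verify unit mass and mean `mu`.) The variance is
the closed form `mu^3 / theta_{p+1}`.

Parameters are tracked by local maximum likelihood: at grid time `t`,
intervals ending in `(t - W, t]` are weighted by `rho^(t - end)` and the
weighted log-likelihood is maximized. Because `mu` is *linear* in
`theta`, the score equations reduce to iteratively reweighted least
squares (weights `w / mu^3`) with the shape profiled out in closed form
at each iteration - a Fisher-scoring scheme that converges in a handful
of iterations and warm-starts from the previous grid point. Defaults are
`p = 8`, `W = 90 s` (the session length), `rho = 0.98`, grid step 5 ms.
The right-censoring term for the open interval at `t` is omitted (the
source is silent on it).

The fitted AR coefficients give a parametric spectrum
`S(f) = 2 delta sigma^2 / |1 - sum theta_i e^(-i 2 pi f i delta)|^2` with
`delta` the local mean interval and the model variance `sigma^2` playing
the innovation role; integrating half-open bands yields VLF
`[0, 0.04)`, LF `[0.04, 0.15)` and HF `[0.15, 0.5)` Hz, the LF/HF
balance and the normalized LFn/HFn. With no AR terms the spectrum is
flat and LFn equals `0.11 / 0.46` - a closed-form anchor the tests pin.
Goodness of fit is checked by time rescaling: intervals mapped through
the fitted conditional CDF must be uniform (Kolmogorov-Smirnov).

**Pipeline grid.** The 5 ms default grid matches instantaneous-tracking
practice but is wasteful for window-averaged features: the pipeline
configuration uses 0.25 s (a 90 s window average is insensitive to grid
density three orders of magnitude below the window). Both are
configurable.

# Pulse chain

The BVP is low-passed at 25 Hz and decimated to 250 Hz. Between
consecutive R-peaks, the maximum is the systole and the minimum the
diastole; the pulse onset is the inflection point - the maximum of the
first derivative - on the rising limb preceding the systolic peak. The
source wording ("between each systolic and diastolic location") is
directionally ambiguous; we search the rising limb because the onset
physiologically precedes the systole. Beats with no distinct interior
maximum, no rising limb, or an arrival time outside `(0, RR)` are
skipped and counted. The features are the volume pulse VP (mean
systolic-minus-diastolic amplitude) and the pulse arrival time PAT (mean
onset-minus-R delay); onsets are used because they are the more stable
fiducial. The synthetic pulse places its steepest upstroke sample
exactly `pat` seconds after each R-peak, so recovery is testable to one
sample at 250 Hz.

# EEG chain

The 21-electrode 10-20 montage carries an alias map (T3 -> T7/T3 and
friends) and a nearest-neighbor map; a corrupted channel is replaced by
its neighbor average (for Pz: P3, P4, Cz). Re-referencing is common
average over the 19 scalp channels - the mastoids are excluded because
reference electrodes bias the common average - and is idempotent. Band
powers (delta 1-3, theta 4-7, alpha 8-12, beta 16-38 Hz; gamma excluded
by design) are Welch integrals computed per channel and then averaged
within the frontal and parietal regions - power averaging, not signal
averaging, which would cancel incoherent activity. Region membership is
configurable; the defaults are the seven frontal and five parietal
electrodes of the montage. The Welch segment length for EEG is unstated
in the source; 2 s Hamming segments with 50% overlap is the standard
choice and is configurable. The attention index is beta/theta per
region; the synthetic recovery test (beta power doubled implies index
near 2) exercises the arithmetic, not any biological claim.

# Pupil chain

Samples outside 2-8 mm are blinks. Where one eye is missing, the other
eye's sample is substituted; joint gaps are linearly interpolated
(nearest-valid at the edges, with a warning). The cleaned two-eye
average is low-passed at 5 Hz, decimated to 10 Hz, and features are the
mean and s.d. of the diameter plus Welch band powers of the linearly
detrended signal over 300-sample Hamming segments (the one segment
length the source does state): DLF `[0.05, 0.15)`, DHF `[0.15, 0.45)`,
DVHF `[0.45, 1.5)` Hz. Windows shorter than one segment (the 15 s
single-stimulus windows) get time features only. The normalized indices
DLFn/DHFn use `DLF + DHF` as denominator, mirroring the RR LFn/HFn
convention; whether DVHF belongs in the denominator is unstated, so it
is reported unnormalized only.

# Statistics

For each feature and each arousal session (the arousal dimension) or
valence half (the valence dimension), values are compared across the
three phases: Shapiro-Wilk per phase (the recorded motivation for going
nonparametric), then the subject-blocked Friedman test on complete
blocks (subjects missing a phase are dropped and counted; fewer than
five blocks is a refusal), and - only when the omnibus is significant -
pairwise comparison of phase mean ranks referred to the studentized
range distribution, `ptukey(q, k, Inf)`, the behavior of common
`multcompare` implementations ("Tukey's correction" names a software
behavior, not a formula). Blocks whose ranks are fully tied yield
statistic 0 and p = 1 by convention. The significance level is 0.05 (not
printed in the source; the conventional default). No cross-feature
multiplicity correction is applied, matching the original analysis.

Calibration is part of the acceptance surface: under a null of
exchangeable phases with 21 subjects, the Friedman rejection rate at
0.05 sits in [0.03, 0.07] over 1000 replicates, the gatekept familywise
error of the pairwise stage stays at or below 0.07, and a 10-SD shift is
detected essentially always.

# The synthetic world, and what green tests do not establish

The generators emulate exactly the statistical structure the analysis
assumes: inverse-Gaussian intervals with AR-modulated mean (sampled
exactly by the transform-with-rejection method), bi-exponential SCRs on
a tonic level, a stylized single-bump pulse and spike-train ECG (a
textbook P/T-wave template is available for the detector test),
band-limited Gaussian EEG with set per-region powers, and an oscillating
pupil with blinks. The source gives no quantitative per-phase effect
sizes, so effect injection (e.g. doubled SCR amplitudes during the
sound-only phase) is a free parameter of the study simulator with
defaults chosen once at plausible magnitudes.

None of the generators model: real ECG/PPG morphology and its artifacts,
motion and electrode noise, slow electrodermal drifts and nonstationary
tonic levels, 1/f EEG background with transient oscillatory bursts,
luminance-driven pupil responses, or between-subject heterogeneity.
A green recovery suite establishes that the implementation inverts its
own stated model at the stated tolerances - not that the pipeline is
robust to everything a laboratory recording contains.

# Numerical conventions

* Filter padding: odd reflection, about nine time constants of the
  slowest band edge, clipped to the trace length; start-up states are
  the steady-state response to the first sample.
* Welch: Hamming taper, 50% overlap, density scaling, one-sided with
  DC/Nyquist unfolded once; per-segment mean removal when detrending.
* Degenerate inputs error early and descriptively (non-positive rates,
  cutoffs at or above Nyquist, windows outside the trace, all-blink
  pupil traces); recoverable degeneracies (no beats, no SCRs, windows
  with no grid points) return empty or NA-marked results with warnings,
  never fabricated zeros.
* All randomness flows through per-call seeds; seeded calls restore the
  caller's RNG state. Child seeds are derived below 2^31.

# Known limitations

EDF input/output is not implemented (no EDF codec exists in the
supported dependency set); the delimited format with a rate/units/labels
header is the interchange format. The point-process tracker is pure R;
at the 5 ms reference grid over a 45-minute recording it is too slow for
routine use, hence the 0.25 s pipeline default. Pulse arrival time is a
per-recording constant in the simulator, so phase effects on PAT cannot
currently be injected.
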
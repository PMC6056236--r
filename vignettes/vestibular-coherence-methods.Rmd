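---
title: "Methods: vestibulo-motor coherence around motor-state transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vestibulo-motor coherence around motor-state transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestcoh)
```

## The problem

A small stochastic current applied over the mastoid processes (electrical
vestibular stimulation, EVS) acts as a craniocentric virtual motion signal.
When standing balance is actively controlled, that signal leaks into the
ground reaction forces: the horizontal shear force becomes partially
coherent with the stimulus. Tracking that coherence through time therefore
tracks the engagement of the vestibular control of balance — including the
striking observation that it is transiently *suspended* just before a
transition between motor states (quiet standing to walking, or between two
standing postures).

`vestcoh` implements that analysis chain: simulation of stimulus and
forceplate trials with controllable coupling, detection of gait events and
movement phases from the vertical forces and the centre of pressure (CoP),
trial-averaged Morlet time-frequency coherence with analytic significance
limits, and the derived summaries (null periods, per-phase coherence peaks,
multivariate phase statistics).

## The coherence model

Per trial, the stimulus $x$ and the shear force $y$ on the axis of the
vestibular disturbance (mediolateral for head facing forward,
anteroposterior for head turned left) are decomposed with a continuous
complex Morlet wavelet, centre parameter $\omega_0 = 6$, at 1 Hz steps over
1–20 Hz. The trial-averaged coherence is

$$C(\tau, f) = \frac{\left|\overline{P}_{xy}(\tau,f)\right|^2}
 {\overline{P}_{xx}(\tau,f)\ \overline{P}_{yy}(\tau,f)},$$

with $\overline{P}$ the across-trial means of the wavelet auto- and
cross-spectra. Averaging happens across trials only — there is no
within-trial time smoothing — so a single trial gives $C \equiv 1$
algebraically, and the number of averaged segments $L$ alone governs the
null distribution. The significance limit used throughout is the
closed form

$$\mathrm{CL}(L, \alpha) = 1 - \alpha^{1/(L-1)},$$

which was verified to reproduce the conventional printed thresholds at the
99% level (0.045 for $L = 100$, 0.005 for $L = 1000$, 0.008 for $L = 600$)
before anything was built on it, and whose empirical exceedance rate under
independent inputs is checked by the test suite at both
$\alpha \in \{0.05, 0.01\}$.

Key analysis parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `freqs` | 1–20 Hz, 1 Hz steps | Morlet grid; a Morlet has no 0 Hz point, so the nominal "0–20 Hz" band starts at 1 Hz and the "0–10 Hz" band average uses grid points 1–10 Hz |
| `lag_ms` | 200 | stimulus-to-force latency of the medium-latency balance response; applied once, by advancing the force record before the transform, and reported back on the time axis |
| `omega0` | 6 | Morlet centre parameter (standard time-frequency trade-off) |
| `alpha` | 0.01 | significance level of the confidence limit |
| `window_s` | 3 (locomotor), 7 (posture) | width of the marker-centred non-normalized analysis window |
| `search_s` | 1.5 (locomotor), 3.5 (posture) | half-width of the null-period search window |

Edge effects are softened by reflection padding before the FFT-based
transform; a cone-of-influence vector (the e-folding time per frequency)
is stored with each spectra object but not applied as a mask by default.
Resampling of spectra onto normalized or window-relative time axes is
linear, applied to real and imaginary parts of the cross-spectrum
independently, which preserves non-negativity of the auto-spectra.

## Event detection and phases

Gait events follow the 5% body-weight rule on per-foot vertical force:
toe-off is the first sample below the threshold, heel-strike the first
sample back above it after a toe-off; crossings that do not persist for
50 ms are treated as chatter. Transition markers come from the horizontal
CoP speed (20 Hz zero-phase second-order Butterworth, then central
differences): the onset (or end) is the first (or last) instant the speed
exceeds the baseline mean + 3 SD, with the baseline the first five seconds
of quiet standing (the last five for locomotor termination).

One design choice deserves emphasis. Real analyses of this kind visually
verify the detected markers; an automated pipeline cannot. Low-frequency
postural sway occasionally exceeds the 3-SD level in brief clustered
bursts, and a rule that only discards sub-50 ms excursions lets such a
cluster drag the marker a few hundred milliseconds away. The marker
detector therefore requires a *sustained* suprathreshold run — 0.3 s of
continuous exceedance (`min_move_s`) — before it accepts a movement; the
marker is still the first crossing sample of that run. Genuine transitions
sustain the threshold for much longer than any sway burst, so this
tightens robustness without moving the marker definition.

Phases are half-open sample intervals: for initiation, quiet standing up
to the onset, transition up to the first toe-off, first step between the
first two toe-offs; for termination, the mirrored definitions around the
last heel-strike; for the posture shift, quiet standing / transition /
shifted posture. The movement-time normalization duration $D$ spans the
transition onset to the third toe-off (initiation) or the third-to-last
heel-strike to the transition end (termination); the normalized window
adds twice that length of context on the quiet-standing side, mapped to a
$[-2, 1]$ (initiation) or $[-1, 2]$ (termination) axis with the marker
at 0.

## What the simulator emulates — and what it does not

The generator reproduces the statistical structure the analysis depends
on, under the standard study conditions:

* **Stimulus**: zero-mean Gaussian white noise, zero-phase 4th-order
  Butterworth low-pass at 20 Hz, rescaled to a 4 mA peak; 30 s locomotor
  trials, 15 s posture trials. Peak scaling divides by the realized
  maximum, so the RMS (typically 1.1–1.4 mA here) is emergent. Published
  descriptions of this stimulus quote "peak 4 mA, RMS ~2 mA", which a
  Gaussian trace scaled to a 4 mA peak cannot produce; the scaling
  convention behind that RMS is ambiguous (peak vs. peak-to-peak), so the
  RMS is reported but deliberately not enforced.
* **Vertical forces**: two plates (one per foot); raised-cosine load
  transfers with a double-support overlap of 20% of the stride;
  anticipatory loading then unloading of the swing leg before the first
  toe-off; a ramp to a 90/10 load split for the posture shift. Total
  vertical force is held at body weight through the walking block.
* **Coupling**: shear force = low-pass-filtered (10 Hz), 200 ms-lagged
  stimulus times a phase-scheduled gain, plus 2 Hz low-passed sway
  (standing shear RMS 0.4 N, CoP sway RMS 2 mm) and 1 N broadband
  measurement noise. The default gain of 0.23 N/mA was calibrated once so
  that standing-phase single-bin coherence sits near 0.3 mid-band — the
  operating point at which vestibulo-motor coupling is typically observed
  — and then frozen. Double support doubles the swing gain (coherence is
  phasically larger in double support); a zero-gain null window of 0.8 s
  starting 0.4 s before the annotated transition onset is injected by
  default, giving the null-period analysis a known ground truth.
* **Ground truth**: gait events are annotated in closed form from the
  generating raised-cosine templates (quantized to the first sample past
  the 5% threshold, i.e. the event definition itself), independently of
  the run-based detectors. Transition markers are *rule-defined*
  quantities, so they are annotated by applying the canonical 3-SD rule to
  the measurement-noise-free CoP (template plus sway); detection on the
  noisy channels is validated against that annotation.

Not emulated: musculoskeletal or inverted-pendulum dynamics, turning
between initiation and termination, head-kinematics channels, within-step
fluctuations of total vertical force, and any subject-specific variability
beyond timing jitter. Passing tests therefore demonstrate that the
*analysis chain* recovers known coupling structure from realistic-looking
signals — not that the simulator reproduces human physiology. In
particular the human summary values (peak coherence 0.29–0.41, null
periods of 0.34–0.44 s lead and 0.81–0.86 s duration) depend on
unavailable raw recordings and are used only as plausibility anchors for
simulator defaults, never as test expectations.

## Null period and phase peaks

The null period is detected on the 1–10 Hz band-averaged coherence of the
marker-centred window, against the per-bin confidence limit: the
contiguous sub-limit run containing the marker (or the nearest one before
it), searched within ±1.5 s (locomotor) or ±3.5 s (posture). Whether such
timing should be read off the band average or off any single bin is
genuinely open; the band average matches how the time course is usually
displayed, and the single-bin route remains available by passing a
one-frequency band. Wavelet temporal smearing (≈1 s at 1 Hz, ≈0.1 s at
10 Hz) biases recovered durations slightly long and blurs the edges; the
parameter-recovery test budgets ±0.25 s on the lead and ±0.3 s on the
duration for exactly this reason.

Per-phase peaks are the maximum of the coherence map over each phase's
time window across all grid frequencies, ties resolved toward the lowest
frequency and earliest time (relevant only for degenerate flat maps).
Phase comparisons use a repeated-measures multivariate test implemented as
a one-sample Hotelling $T^2$ on within-subject contrast vectors (two
phase contrasts × two measures = 4 dimensions) — the named test family
admits several parameterizations, and this contrast form is exact under
normality, which the type-I calibration tests confirm at $n = 10$. Post
hocs are paired Hotelling $T^2$ tests and Bonferroni-corrected paired
t-tests, $\alpha = 0.05$.

## Numerical choices and degenerate inputs

* Zero-phase filtering pads by odd (point-symmetric) reflection before
  `signal::filtfilt`, which has no initial-condition handling of its own;
  synthetic band-limited noise is instead generated with extra samples and
  the warm-up cropped, because odd reflection pins the filter output to
  the raw edge value (correct for trajectories, wrong for noise).
* Net CoP is undefined (NA) where total vertical force is below 1 N.
* `average_and_cohere` demands identical tau/frequency axes across trials
  (tolerance 1e-6 s) rather than resampling silently.
* Exact ties in the paired statistics (all differences zero) return
  $T^2 = 0$, $p = 1$; singular covariance with non-zero differences raises
  an informative error instead of a spurious number.
* All simulator randomness derives from one integer seed per trial through
  a counter-based multiplicative stream, so adding a noise component never
  perturbs the others and every object is bit-reproducible.

## Problem sizes in the test suite

The acceptance-level tests run the standard conditions: 100-trial
subjects, 30 s locomotor trials at 250 Hz (the stimulus band ends at
20 Hz, so 250 Hz retains a comfortable margin above Nyquist while keeping
the wavelet transforms cheap), 20 replicates for the type-I and
phase-ordering checks, 10 × 100 segments for the pooled variant, and 5000
replicates for the statistical calibration. Module-level tests use smaller
sizes chosen for tightness of the property under test rather than for
realism.

## Known limitations

* The confidence limit assumes independent trials; overlapping or serially
  correlated segments would need a corrected effective $L$.
* The null-period timing inherits the wavelet's frequency-dependent
  temporal resolution; sub-0.1 s claims about suspension timing are
  outside what the band-averaged statistic can support.
* The simulator's walking shear template is a small stylized oscillation;
  analyses that depend on the detailed spectral content of locomotor GRF
  (rather than its coherence with the stimulus) should not lean on it.
* With fewer than six complete subjects the pipeline skips the phase
  statistics (a 4-dimensional contrast test needs $n > 4$; six is the
  smallest cohort analysed in this design).
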